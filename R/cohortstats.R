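# Group-level inference: edgewise permutation tests on residual matrices,
# z-score subgroup maps, effect sizes, univariate group tests, moderation
# regression with simple slopes, and clinical-factor correlations.

#' Edgewise two-sample permutation test
#'
#' For every edge, computes the observed two-sample (pooled-variance) t
#' statistic between patients and controls, and a two-sided permutation p
#' value from `n_perm` random group relabelings. The same permutation
#' sequence is reused across all edges, preserving the cross-edge dependence
#' of the null. `p = (#\{|t_perm| >= |t_obs|\} + 1) / (n_perm + 1)`.
#'
#' @param r_patients,r_controls lists of stage-R `fc_matrix` objects (or
#'   plain symmetric matrices), one per subject.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alpha significance level for the significance mask (uncorrected).
#' @param exhaustive use all distinct group splits instead of random
#'   relabelings (feasible for small cohorts; `n_perm` ignored).
#' @return List of class `edge_stats` with matrices `t`, `p`, `d` (Cohen's
#'   d), `significant`, `direction` (sign of t), the edge count, `n_perm`,
#'   and `seed`.
#' @export
edgewise_permutation_test <- function(r_patients, r_controls, n_perm = 2000L,
                                      seed = 1L, alpha = 0.05,
                                      exhaustive = FALSE) {
  xp <- edge_stack(r_patients)
  xc <- edge_stack(r_controls)
  stopifnot(nrow(xp) >= 2, nrow(xc) >= 2, ncol(xp) == ncol(xc))
  n1 <- nrow(xp); n2 <- nrow(xc)
  X <- rbind(xp, xc)
  n_edge <- ncol(X)

  zero_var <- apply(X, 2, function(v) var(v) == 0)
  t_obs <- edge_t_stat(X, seq_len(n1))

  if (exhaustive) {
    splits <- combn(n1 + n2, n1)
    t_perm <- apply(splits, 2, function(g) edge_t_stat(X, g))
    t_perm <- matrix(t_perm, ncol = n_edge, byrow = TRUE)
    # exact p over all distinct splits (observed split included)
    p <- colMeans(sweep(abs(t_perm), 2, abs(t_obs), ">=") * 1)
    n_used <- ncol(splits)
  } else {
    set.seed(derive_seed(seed, "edge_perm"))
    # one indicator row per permutation; all edges share the permutation
    # sequence, so the t statistics come from two matrix products
    P <- matrix(0, n_perm, n1 + n2)
    for (b in seq_len(n_perm))
      P[b, sample.int(n1 + n2, n1)] <- 1
    S <- colSums(X); Q <- colSums(X^2)
    S1 <- P %*% X                       # per-permutation group-1 sums
    Q1 <- P %*% X^2
    m1 <- S1 / n1
    m2 <- sweep(-S1, 2, S, "+") / n2
    v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
    v2 <- (sweep(-Q1, 2, Q, "+") - n2 * m2^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t_perm <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    t_perm[sp2 <= 0] <- 0
    exceed <- colSums(sweep(abs(t_perm), 2, abs(t_obs), ">="))
    p <- (exceed + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  p[zero_var] <- NA_real_

  sp <- sqrt(((n1 - 1) * apply(xp, 2, var) + (n2 - 1) * apply(xc, 2, var)) /
               (n1 + n2 - 2))
  d <- (colMeans(xp) - colMeans(xc)) / sp
  d[sp == 0] <- NA_real_

  n_nodes <- node_count(r_patients[[1]])
  out <- list(t = edge_matrix(t_obs, n_nodes), p = edge_matrix(p, n_nodes),
              d = edge_matrix(d, n_nodes),
              significant = edge_matrix(!is.na(p) & p < alpha, n_nodes) > 0,
              direction = edge_matrix(sign(t_obs), n_nodes),
              n_edges = n_edge, n_perm = n_used, seed = seed, alpha = alpha)
  class(out) <- "edge_stats"
  out
}

# subjects x edges matrix from a list of symmetric matrices
edge_stack <- function(mats) {
  do.call(rbind, lapply(mats, edge_vector))
}

node_count <- function(m) nrow(if (inherits(m, "fc_matrix")) m$values else m)

# vectorized pooled-variance two-sample t statistic per column;
# `g` indexes group 1 rows
edge_t_stat <- function(X, g) {
  x1 <- X[g, , drop = FALSE]; x2 <- X[-g, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tt[sp2 == 0] <- 0
  tt
}

#' Z-score subgroup maps against the control distribution
#'
#' Transforms each patient's residual matrix into edgewise z-scores using the
#' control group's mean and standard deviation, averages over the subgroup,
#' and derives the +/-2 SD masks.
#'
#' @param r_subgroup list of patient stage-R matrices (the subgroup).
#' @param r_controls list of control stage-R matrices.
#' @param label subgroup label (e.g. `"FLE"`, `"TLE"`, `"left"`, `"right"`).
#' @return List of class `zscore_map` with `z` (mean subgroup z matrix),
#'   `low_mask` (z <= -2), `high_mask` (z >= +2), `label`, and `undefined`
#'   (edges with zero control SD).
#' @export
zscore_subgroup_maps <- function(r_subgroup, r_controls, label = "patients") {
  xc <- edge_stack(r_controls)
  mu <- colMeans(xc)
  sdc <- apply(xc, 2, sd)
  xs <- edge_stack(r_subgroup)
  z <- sweep(sweep(xs, 2, mu), 2, ifelse(sdc > 0, sdc, NA_real_), "/")
  zbar <- colMeans(z)
  n_nodes <- node_count(r_controls[[1]])
  zm <- edge_matrix(zbar, n_nodes)
  list(z = zm, low_mask = edge_matrix(!is.na(zbar) & zbar <= -2, n_nodes) > 0,
       high_mask = edge_matrix(!is.na(zbar) & zbar >= 2, n_nodes) > 0,
       label = label, undefined = edge_matrix(sdc == 0, n_nodes) > 0)
}

#' Cohen's d and Vargha-Delaney A effect sizes
#'
#' @param x,y numeric samples (>= 2 each).
#' @return List with `d` (pooled-SD Cohen's d, `NA` when the pooled SD is
#'   zero) and `A` (probability of superiority with tie correction).
#' @export
effect_sizes <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  d <- if (sp > 0) (mean(x) - mean(y)) / sp else NA_real_
  cmp <- outer(x, y, "-")
  A <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (nx * ny)
  list(d = d, A = A)
}

#' Univariate group comparisons
#'
#' For each continuous variable: a Shapiro-Wilk normality screen (alpha =
#' 0.05, per group) decides between Student's t-test and the Mann-Whitney U
#' test; categorical variables use Fisher's exact test. Effect sizes
#' (Cohen's d, Vargha-Delaney A) are attached for continuous variables.
#'
#' @param data data frame including a `group` column.
#' @param variables character vector of column names to test.
#' @param group_col name of the grouping column (two levels).
#' @return Data frame: variable, test, statistic, p, d, A.
#' @export
univariate_group_tests <- function(data, variables,
                                   group_col = "group") {
  g <- factor(data[[group_col]])
  stopifnot(nlevels(g) == 2)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (all(is.na(x))) return(NULL)
    if (is.numeric(x)) {
      x1 <- x[g == levels(g)[1] & !is.na(x)]
      x2 <- x[g == levels(g)[2] & !is.na(x)]
      normal <- tryCatch(
        shapiro.test(x1)$p.value > 0.05 && shapiro.test(x2)$p.value > 0.05,
        error = function(e) TRUE)
      es <- effect_sizes(x1, x2)
      if (normal) {
        tt <- t.test(x1, x2, var.equal = TRUE)
        data.frame(variable = v, test = "t", statistic = unname(tt$statistic),
                   p = tt$p.value, d = es$d, A = es$A,
                   stringsAsFactors = FALSE)
      } else {
        wt <- suppressWarnings(wilcox.test(x1, x2))
        data.frame(variable = v, test = "mann-whitney",
                   statistic = unname(wt$statistic), p = wt$p.value,
                   d = es$d, A = es$A, stringsAsFactors = FALSE)
      }
    } else {
      tab <- table(x, g)
      ft <- fisher.test(tab)
      data.frame(variable = v, test = "fisher", statistic = NA_real_,
                 p = ft$p.value, d = NA_real_, A = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Moderation (interaction) regression of a network AUC on cognition
#'
#' Fits `auc ~ iq_c * group` by ordinary least squares, with IQ centered on
#' the pooled mean and the group coded 0 = control, 1 = epilepsy, and reports
#' the model F statistic, adjusted R-squared, per-coefficient p values,
#' partial eta-squared (`SS_effect / (SS_effect + SS_residual)` from type-III
#' style single-coefficient tests), and per-group simple slopes.
#'
#' @param auc numeric outcome (network metric AUC).
#' @param iq numeric cognitive score.
#' @param group character/factor with levels including `"control"` and
#'   `"epilepsy"` (or any two levels; the reference is `control` when
#'   present, otherwise the first level).
#' @param iq_scale divisor applied to centered IQ before fitting (default
#'   15, one IQ standard deviation, so slopes are per-SD).
#' @return List of class `moderation_result` with `coefficients` (data frame
#'   with estimate, se, t, p, partial eta-squared), `F`, `df`, `p_model`,
#'   `adj_r_squared`, `simple_slopes`, and the fitted `model`.
#' @export
moderation_regression <- function(auc, iq, group, iq_scale = 15) {
  stopifnot(length(auc) == length(iq), length(iq) == length(group),
            var(iq) > 0)
  g <- as.character(group)
  ref <- if ("control" %in% g) "control" else sort(unique(g))[1]
  gi <- as.numeric(g != ref)
  stopifnot(sum(gi) >= 3, sum(1 - gi) >= 3)
  iq_c <- (iq - mean(iq)) / iq_scale
  fit <- lm(auc ~ iq_c * gi)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  rownames(co) <- c("(Intercept)", "iq", "group", "iq_x_group")
  df_res <- fit$df.residual
  co$partial_eta_sq <- co$t^2 / (co$t^2 + df_res)
  fstat <- sm$fstatistic
  res <- list(coefficients = co,
              F = unname(fstat[1]), df = unname(fstat[2:3]),
              p_model = unname(pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
              adj_r_squared = sm$adj.r.squared,
              model = fit, reference = ref)
  res$simple_slopes <- simple_slopes(res)
  class(res) <- "moderation_result"
  res
}

#' Per-group simple slopes from a moderation fit
#'
#' Under treatment coding the reference-group slope is the IQ coefficient and
#' the focal-group slope is its sum with the interaction coefficient; the
#' standard errors come from the coefficient covariance matrix.
#'
#' @param mod a `moderation_result` (or the list built inside
#'   [moderation_regression()]).
#' @return Data frame with one row per group: slope, se, t, p.
#' @export
simple_slopes <- function(mod) {
  fit <- mod$model
  V <- vcov(fit)
  b <- coef(fit)
  df_res <- fit$df.residual
  s_ref <- b[["iq_c"]]
  se_ref <- sqrt(V["iq_c", "iq_c"])
  s_foc <- b[["iq_c"]] + b[["iq_c:gi"]]
  se_foc <- sqrt(V["iq_c", "iq_c"] + V["iq_c:gi", "iq_c:gi"] +
                   2 * V["iq_c", "iq_c:gi"])
  tt <- c(s_ref / se_ref, s_foc / se_foc)
  data.frame(group = c(mod$reference, "focal"),
             slope = c(s_ref, s_foc), se = c(se_ref, se_foc), t = tt,
             p = 2 * pt(abs(tt), df_res, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Correlations between clinical factors and network AUCs
#'
#' Pearson correlations for continuous clinical factors (age of onset,
#' epilepsy duration) and Spearman rank correlations for coded categorical
#' factors (type FLE=0/TLE=1; lateralization left=0/right=1/bilateral=2;
#' seizure control yes=1/no=0), patients only.
#'
#' @param auc data frame of per-subject AUC values (rows aligned with
#'   `clinical`), columns = metrics.
#' @param clinical data frame with columns among `epilepsy_type`,
#'   `lateralization`, `onset_age`, `epilepsy_duration`, `seizure_control`.
#' @return Data frame factor x metric of correlation coefficients (long
#'   format: factor, metric, method, r, p, n).
#' @export
clinical_correlations <- function(auc, clinical) {
  codings <- list(
    epilepsy_type = function(x) c(FLE = 0, TLE = 1)[x],
    lateralization = function(x) c(left = 0, right = 1, bilateral = 2)[x],
    seizure_control = function(x) c(no = 0, yes = 1)[x],
    onset_age = identity, epilepsy_duration = identity)
  methods <- c(epilepsy_type = "spearman", lateralization = "spearman",
               seizure_control = "spearman", onset_age = "pearson",
               epilepsy_duration = "pearson")
  rows <- list()
  for (f in intersect(names(codings), names(clinical))) {
    x <- codings[[f]](clinical[[f]])
    for (m in names(auc)) {
      y <- auc[[m]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || var(x[ok]) == 0 || var(y[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          factor = f, metric = m, method = methods[[f]], r = NA_real_,
          p = NA_real_, n = sum(ok), stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = methods[[f]]))
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, metric = m, method = methods[[f]],
        r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
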
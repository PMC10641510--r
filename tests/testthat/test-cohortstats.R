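# Cohort statistics: permutation tests, z maps, effect sizes, group tests,
# moderation, clinical correlations.

test_that("exhaustive permutation p equals manual enumeration for 3 vs 3", {
  set.seed(1)
  xs <- lapply(1:3, function(i) random_edge_matrix(5))
  ys <- lapply(1:3, function(i) random_edge_matrix(5, mu = 1))
  res <- edgewise_permutation_test(xs, ys, exhaustive = TRUE)
  expect_equal(res$n_perm, choose(6, 3))
  # independent oracle: enumerate all 20 splits with t.test
  pooled <- rbind(do.call(rbind, lapply(xs, edge_vector)),
                  do.call(rbind, lapply(ys, edge_vector)))
  splits <- combn(6, 3)
  for (e in c(1, 4, 10)) {
    t_obs <- t.test(pooled[1:3, e], pooled[4:6, e],
                    var.equal = TRUE)$statistic
    t_all <- apply(splits, 2, function(g)
      t.test(pooled[g, e], pooled[-g, e], var.equal = TRUE)$statistic)
    p_oracle <- mean(abs(t_all) >= abs(t_obs))
    expect_equal(edge_vector(res$p)[e], p_oracle, tolerance = 1e-12)
  }
})

test_that("random permutation p has the add-one floor and symmetry", {
  set.seed(2)
  # groups large enough that no random relabeling reproduces the separation
  xs <- lapply(1:10, function(i) random_edge_matrix(6, mu = 3, sd = 0.1))
  ys <- lapply(1:10, function(i) random_edge_matrix(6, mu = -3, sd = 0.1))
  res <- edgewise_permutation_test(xs, ys, n_perm = 2000, seed = 5)
  # fully separated groups hit the minimum attainable p = 1/2001
  expect_equal(min(res$p[upper.tri(res$p)]), 1 / 2001)
  expect_equal(res$p, t(res$p))
  expect_equal(res$t, t(res$t))
  # determinism under the same seed
  res2 <- edgewise_permutation_test(xs, ys, n_perm = 2000, seed = 5)
  expect_identical(res$p, res2$p)
})

test_that("permutation test is calibrated under an exchangeable null", {
  set.seed(3)
  xs <- lapply(1:8, function(i) random_edge_matrix(25))
  ys <- lapply(1:12, function(i) random_edge_matrix(25))
  res <- edgewise_permutation_test(xs, ys, n_perm = 500, seed = 11)
  rate <- mean(res$p[upper.tri(res$p)] < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("z-score maps flag deviant edges against the control spread", {
  set.seed(4)
  ctrl <- lapply(1:20, function(i) random_edge_matrix(6, mu = 0, sd = 1))
  xc <- do.call(rbind, lapply(ctrl, edge_vector))
  mu <- colMeans(xc); sdc <- apply(xc, 2, sd)
  # a patient exactly at the control mean -> z = 0
  pat0 <- list(edge_matrix(mu, 6))
  zm0 <- zscore_subgroup_maps(pat0, ctrl)
  expect_lt(max(abs(zm0$z)), 1e-12)
  expect_false(any(zm0$low_mask) || any(zm0$high_mask))
  # a patient at mu + 2 sd has z = 2 (up to rounding); at 2.5 sd the high
  # mask flags every edge
  pat2 <- list(edge_matrix(mu + 2 * sdc, 6))
  zm2 <- zscore_subgroup_maps(pat2, ctrl, label = "FLE")
  expect_equal(max(abs(zm2$z[upper.tri(zm2$z)] - 2)), 0, tolerance = 1e-10)
  pat25 <- list(edge_matrix(mu + 2.5 * sdc, 6))
  zm25 <- zscore_subgroup_maps(pat25, ctrl, label = "FLE")
  expect_true(all(zm25$high_mask[upper.tri(zm25$high_mask)]))
  expect_false(any(zm25$low_mask))
  # masks are disjoint by construction
  expect_false(any(zm25$high_mask & zm25$low_mask))
  # subgroup of one equals that patient's z matrix
  expect_equal(zm2$z, edge_matrix((mu + 2 * sdc - mu) / sdc, 6))
})

test_that("effect sizes satisfy their identities", {
  set.seed(5)
  x <- rnorm(30)
  es_same <- effect_sizes(x, x)
  expect_equal(es_same$d, 0)
  expect_equal(es_same$A, 0.5)
  # shift by a constant: d = c / SD exactly on equal-variance samples
  cshift <- 1.7
  es_shift <- effect_sizes(x + cshift, x)
  expect_equal(es_shift$d, cshift / sd(x), tolerance = 1e-12)
  # fully separated groups: A = 1
  expect_equal(effect_sizes(rnorm(10) + 100, rnorm(10))$A, 1)
  # large-sample consistency: shift of one pooled SD -> d ~ 1
  big <- rnorm(5000)
  expect_lt(abs(effect_sizes(big + sd(big), big)$d - 1), 0.05)
})

test_that("univariate tests choose t / Mann-Whitney / Fisher appropriately", {
  set.seed(6)
  n <- 20
  dat <- data.frame(
    group = rep(c("a", "b"), each = n),
    normal = rnorm(2 * n),
    skewed = c(rexp(n, 0.1)^2, rexp(n, 0.1)^2),
    cat = factor(rep(c("x", "y"), n)))
  res <- univariate_group_tests(dat, c("normal", "skewed", "cat"))
  expect_equal(res$test[res$variable == "normal"], "t")
  expect_equal(res$test[res$variable == "skewed"], "mann-whitney")
  expect_equal(res$test[res$variable == "cat"], "fisher")
  # identical groups -> t = 0, p = 1
  dat2 <- data.frame(group = rep(c("a", "b"), each = 5),
                     v = rep(c(1.2, 0.4, -0.3, 2.2, 0.9), 2))
  res2 <- univariate_group_tests(dat2, "v")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
  # separated 5 vs 5: U statistic maximal (25)
  dat3 <- data.frame(group = rep(c("a", "b"), each = 5),
                     v = c(rexp(5)^3 + 1000, rexp(5)^3))
  res3 <- univariate_group_tests(dat3, "v")
  if (res3$test == "mann-whitney") expect_equal(res3$statistic, 25)
  # Fisher p equals the hypergeometric enumeration for a perfect 2x2 split
  dat4 <- data.frame(group = rep(c("a", "b"), each = 10),
                     cat = factor(rep(c("x", "y"), each = 10)))
  res4 <- univariate_group_tests(dat4, "cat")
  expect_equal(res4$p, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("moderation regression recovers planted group-specific slopes", {
  # identity: focal slope = beta_iq + beta_interaction, exactly
  d <- simulate_moderation_cohort(13, 26, seed = 7)
  fit <- moderation_regression(d$auc, d$estimated_iq, d$group)
  expect_equal(fit$simple_slopes$slope[2],
               fit$coefficients["iq", "estimate"] +
                 fit$coefficients["iq_x_group", "estimate"],
               tolerance = 1e-12)
  # control-group slope equals the IQ coefficient under treatment coding
  expect_equal(fit$simple_slopes$slope[1], fit$coefficients["iq", "estimate"])
  # interaction recovered within 2 SE at the study's cohort size
  expect_lt(abs(fit$coefficients["iq_x_group", "estimate"] - (-1.4)),
            2 * fit$coefficients["iq_x_group", "se"])
  # simple slopes agree with separate per-group OLS fits
  iq_c <- (d$estimated_iq - mean(d$estimated_iq)) / 15
  for (k in 1:2) {
    sel <- d$group == c("control", "epilepsy")[k]
    expect_equal(fit$simple_slopes$slope[k],
                 unname(coef(lm(d$auc[sel] ~ iq_c[sel]))[2]),
                 tolerance = 1e-10)
  }
  # partial eta squared within [0, 1]
  expect_true(all(fit$coefficients$partial_eta_sq >= 0 &
                    fit$coefficients$partial_eta_sq <= 1))
})

test_that("null-interaction coverage of the 95% CI is near nominal", {
  hits <- 0
  n_rep <- 120
  for (s in seq_len(n_rep)) {
    d <- simulate_moderation_cohort(13, 26,
                                    slopes = c(patient = 0.4, control = 0.4),
                                    seed = 1000 + s)
    fit <- moderation_regression(d$auc, d$estimated_iq, d$group)
    est <- fit$coefficients["iq_x_group", "estimate"]
    se <- fit$coefficients["iq_x_group", "se"]
    crit <- qt(0.975, fit$model$df.residual)
    if (abs(est - 0) <= crit * se) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.88)
  expect_lte(hits / n_rep, 1.0)
})

test_that("clinical correlations use the right method per factor", {
  set.seed(8)
  n <- 13
  clin <- data.frame(
    epilepsy_type = sample(c("FLE", "TLE"), n, TRUE),
    lateralization = sample(c("left", "right", "bilateral"), n, TRUE),
    onset_age = runif(n, 2, 12),
    epilepsy_duration = runif(n, 1, 8),
    seizure_control = sample(c("yes", "no"), n, TRUE))
  auc <- data.frame(eloc_L = 2 * clin$onset_age + 1,      # exactly linear
                    sigma = rank(clin$onset_age))
  res <- clinical_correlations(auc, clin)
  expect_equal(res$r[res$factor == "onset_age" & res$metric == "eloc_L"], 1,
               tolerance = 1e-12)
  expect_equal(unique(res$method[res$factor == "epilepsy_type"]), "spearman")
  expect_equal(unique(res$method[res$factor == "onset_age"]), "pearson")
  # perfectly monotone categorical factor -> Spearman r = 1
  clin2 <- clin
  clin2$epilepsy_type <- ifelse(auc$sigma > median(auc$sigma), "TLE", "FLE")
  res2 <- clinical_correlations(auc["sigma"], clin2["epilepsy_type"])
  expect_gt(res2$r, 0.8)
  # constant factor -> undefined entry
  clin3 <- data.frame(seizure_control = rep("yes", n))
  res3 <- clinical_correlations(auc, clin3)
  expect_true(all(is.na(res3$r)))
})
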
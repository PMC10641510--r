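# Weighted graph metrics over a sparsity-threshold range, normalized by
# degree-preserving random references and integrated to AUCs.
# Edges carry absolute connectivity weights; path lengths use the standard
# 1/weight mapping for correlation-weighted graphs.

#' Sparsity threshold grid
#'
#' @param tau1 lower threshold.
#' @param taum upper threshold.
#' @param dtau step.
#' @return Numeric vector covering `[tau1, taum]` inclusive.
#' @export
threshold_grid <- function(tau1 = 0.01, taum = 0.17, dtau = 0.01) {
  stopifnot(tau1 > 0, tau1 < taum, taum < 1, dtau > 0)
  seq(tau1, taum + 1e-12, by = dtau)
}

#' Threshold a connectivity matrix into a weighted graph
#'
#' Edges with `|b| >= tau` keep their absolute value; all others (and the
#' diagonal) are zero.
#'
#' @param b symmetric connectivity matrix (stage-B task values) or
#'   `fc_matrix`.
#' @param tau threshold in `(0, 1)`.
#' @param hemisphere optional character vector of node hemisphere labels.
#' @return List of class `weighted_graph` with `weights`, `tau`,
#'   `hemisphere`.
#' @export
threshold_graph <- function(b, tau, hemisphere = NULL) {
  v <- if (inherits(b, "fc_matrix")) b$values else b
  stopifnot(tau > 0, tau < 1)
  w <- abs(v)
  w[w < tau] <- 0
  diag(w) <- 0
  structure(list(weights = w, tau = tau, hemisphere = hemisphere),
            class = "weighted_graph")
}

#' Degree and connectedness check
#'
#' @param graph a `weighted_graph`.
#' @return List with `degree` (binary degree per node), `min_degree`,
#'   `mean_degree`, and `fully_connected` (`TRUE` when every node has
#'   degree >= 1).
#' @export
degree_check <- function(graph) {
  k <- rowSums(graph$weights > 0)
  list(degree = k, min_degree = min(k), mean_degree = mean(k),
       fully_connected = min(k) >= 1)
}

# all-pairs shortest path lengths (Floyd-Warshall on lengths 1/w; compiled)
shortest_path_lengths <- function(w) {
  cpp_path_lengths(w)
}

# mean of 1/d over ordered node pairs (disconnected pairs contribute 0)
efficiency_from_lengths <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  off <- row(D) != col(D)
  inv <- 1 / D[off]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Weighted segregation and integration metrics
#'
#' Computes, on a thresholded weighted graph:
#' * nodal clustering `gamma` (geometric-mean triangle intensity, weights
#'   scaled by the maximum weight; zero for nodes with degree < 2),
#' * nodal local efficiency `eloc` (global efficiency of the subgraph induced
#'   by each node's neighbors, edge lengths `1/w`),
#' * characteristic path length `lambda` (mean finite shortest path over
#'   ordered pairs; disconnected pairs excluded),
#' * global efficiency `eglob` (mean of `1/d`; disconnected pairs contribute
#'   zero).
#'
#' Hemispheric summaries are means of nodal values over each hemisphere's
#' channels, computed on the full graph.
#'
#' @param graph a `weighted_graph`.
#' @return List with `gamma` (mean nodal clustering), `gamma_nodal`,
#'   `eloc_nodal`, `lambda`, `eglob`, and (when hemisphere labels are
#'   present) `gamma_L`, `gamma_R`, `eloc_L`, `eloc_R`; `valid` is `FALSE`
#'   for an empty graph.
#' @export
weighted_metrics <- function(graph) {
  w <- graph$weights
  n <- nrow(w)
  if (all(w == 0))
    return(list(valid = FALSE, gamma = NA_real_, lambda = NA_real_,
                eglob = NA_real_))
  k <- rowSums(w > 0)
  w_hat <- w / max(w)
  cr <- w_hat^(1 / 3)
  tri <- diag(cr %*% cr %*% cr)              # 2 x sum of triangle intensities
  gamma_nodal <- ifelse(k >= 2, tri / (k * (k - 1)), 0)

  D <- shortest_path_lengths(w)
  off <- row(D) != col(D)
  finite_d <- D[off][is.finite(D[off])]
  lambda <- if (length(finite_d)) mean(finite_d) else NA_real_
  eglob <- efficiency_from_lengths(D)

  eloc_nodal <- cpp_local_efficiency(w)

  out <- list(valid = TRUE, gamma = mean(gamma_nodal),
              gamma_nodal = gamma_nodal, eloc_nodal = eloc_nodal,
              eloc = mean(eloc_nodal), lambda = lambda, eglob = eglob)
  if (!is.null(graph$hemisphere)) {
    for (h in c("L", "R")) {
      sel <- graph$hemisphere == h
      out[[paste0("gamma_", h)]] <- mean(gamma_nodal[sel])
      out[[paste0("eloc_", h)]] <- mean(eloc_nodal[sel])
    }
  }
  out
}

# scalar metric vector used for normalization / pooling
metric_vector <- function(m, hemispheric = TRUE) {
  base <- c(gamma = m$gamma, eloc = m$eloc, lambda = m$lambda,
            eglob = m$eglob)
  if (hemispheric && !is.null(m$gamma_L))
    base <- c(base, gamma_L = m$gamma_L, gamma_R = m$gamma_R,
              eloc_L = m$eloc_L, eloc_R = m$eloc_R)
  base
}

#' Degree-preserving random reference metrics
#'
#' Generates `n` random references by Maslov-Sneppen rewiring of the binary
#' edge skeleton (10 swap attempts per edge) and random reassignment of the
#' original weight multiset to the rewired edges, and computes the weighted
#' metrics of each.
#'
#' @param graph a `weighted_graph`.
#' @param n number of random graphs.
#' @param seed integer seed.
#' @return Matrix (`n` x metrics) of reference metric values, with the list
#'   of reference weight matrices as attribute `graphs` when
#'   `keep_graphs = TRUE`.
#' @param keep_graphs retain the rewired weight matrices.
#' @export
random_reference <- function(graph, n = 100L, seed = 1L, keep_graphs = FALSE) {
  w <- graph$weights
  edges <- which(upper.tri(w) & w > 0)
  if (length(edges) < 1) stop("graph has no edges to rewire")
  set.seed(derive_seed(seed, "rewire"))
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  weights <- w[edges]
  out <- NULL
  kept <- if (keep_graphs) vector("list", n) else NULL
  for (r in seq_len(n)) {
    gr <- if (igraph::ecount(g) >= 2) {
      igraph::rewire(g, igraph::keeping_degseq(niter = 10L * igraph::ecount(g)))
    } else {
      warning("too few edges to rewire; identity graph returned")
      g
    }
    el <- igraph::as_edgelist(gr, names = FALSE)
    wr <- matrix(0, nrow(w), ncol(w))
    shuffled <- sample(weights)
    wr[cbind(el[, 1], el[, 2])] <- shuffled
    wr <- wr + t(wr)
    m <- weighted_metrics(structure(list(weights = wr, tau = graph$tau,
                                         hemisphere = graph$hemisphere),
                                    class = "weighted_graph"))
    out <- rbind(out, metric_vector(m))
    if (keep_graphs) kept[[r]] <- wr
  }
  rownames(out) <- NULL
  if (keep_graphs) attr(out, "graphs") <- kept
  out
}

#' Normalize metrics and form the small-world index
#'
#' Divides raw metrics by the corresponding random-reference means `M_rand`
#' and computes `sigma = gamma_norm / lambda_norm` (whole-graph clustering).
#'
#' @param raw named numeric vector of raw metrics (from [metric_vector()]).
#' @param m_rand named numeric vector of reference means, same names.
#' @return Named vector of normalized metrics plus `sigma`; metrics with
#'   `m_rand <= 0` are `NA`.
#' @export
normalize_and_smallworld <- function(raw, m_rand) {
  common <- intersect(names(raw), names(m_rand))
  norm <- raw[common] / ifelse(m_rand[common] > 0, m_rand[common], NA_real_)
  c(norm, sigma = unname(norm["gamma"] / norm["lambda"]))
}

#' Trapezoidal area under a metric profile
#'
#' @param tau threshold grid values.
#' @param y metric values on the grid (`NA` allowed; at least 2 finite points
#'   required).
#' @return AUC over the contiguous finite portion of the grid, or `NA`.
#' @export
metric_auc <- function(tau, y) {
  ok <- is.finite(y)
  if (sum(ok) < 2) return(NA_real_)
  tau <- tau[ok]; y <- y[ok]
  sum(diff(tau) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Per-cohort network metric profiles and AUC summaries
#'
#' For every subject and threshold: thresholds the stage-B task matrix,
#' computes raw weighted metrics and `n_rand` random-reference metrics. The
#' reference mean `M_rand` is pooled over all random graphs of all subjects
#' of a group, then each subject's raw metrics are divided by their group's
#' `M_rand`, and normalized profiles are integrated over the grid.
#'
#' @param b_mats list of stage-B task matrices (or `fc_matrix` objects).
#' @param hemisphere node hemisphere labels.
#' @param groups character vector of group labels per subject (one pooled
#'   group when `NULL`).
#' @param grid threshold grid.
#' @param n_rand random references per graph and threshold.
#' @param seed integer seed.
#' @return List with `profiles` (long data frame: subject, group, tau,
#'   metric, raw, m_rand, normalized), `auc` (data frame subject x metric),
#'   and `grid`.
#' @export
network_profiles <- function(b_mats, hemisphere, groups = NULL,
                             grid = threshold_grid(), n_rand = 100L,
                             seed = 1L) {
  n_sub <- length(b_mats)
  if (is.null(groups)) groups <- rep("all", n_sub)
  subjects <- names(b_mats) %||% sprintf("sub%02d", seq_len(n_sub))
  raw_list <- list(); rand_list <- list()
  for (i in seq_len(n_sub)) {
    for (ti in seq_along(grid)) {
      g <- threshold_graph(b_mats[[i]], grid[ti], hemisphere)
      m <- weighted_metrics(g)
      key <- paste(i, ti, sep = "_")
      raw_list[[key]] <- c(metric_vector(m),
                           min_degree = degree_check(g)$min_degree)
      rand_list[[key]] <- if (m$valid && any(g$weights > 0)) {
        random_reference(g, n = n_rand,
                         seed = derive_seed(seed, paste0("rr", key)))
      } else NULL
    }
  }
  metric_names <- c("gamma", "eloc", "lambda", "eglob",
                    "gamma_L", "gamma_R", "eloc_L", "eloc_R")
  # M_rand per group and threshold, pooled over graphs and subjects
  m_rand <- array(NA_real_, dim = c(length(unique(groups)), length(grid),
                                    length(metric_names)),
                  dimnames = list(unique(groups), NULL, metric_names))
  for (gname in unique(groups)) {
    for (ti in seq_along(grid)) {
      pool <- do.call(rbind, lapply(which(groups == gname), function(i)
        rand_list[[paste(i, ti, sep = "_")]]))
      if (!is.null(pool))
        m_rand[gname, ti, ] <- colMeans(pool[, metric_names, drop = FALSE],
                                        na.rm = TRUE)
    }
  }
  rows <- list()
  norm_names <- c(metric_names, "sigma")
  norm_store <- array(NA_real_, dim = c(n_sub, length(grid), length(norm_names)),
                      dimnames = list(subjects, NULL, norm_names))
  for (i in seq_len(n_sub)) {
    for (ti in seq_along(grid)) {
      raw <- raw_list[[paste(i, ti, sep = "_")]]
      mr <- m_rand[groups[i], ti, ]
      nm <- normalize_and_smallworld(raw[metric_names], mr)
      norm_store[i, ti, ] <- nm[norm_names]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[i], group = groups[i], tau = grid[ti],
        metric = norm_names,
        raw = c(unname(raw[metric_names]), NA),
        m_rand = c(unname(mr), NA),
        normalized = unname(nm[norm_names]),
        min_degree = unname(raw["min_degree"]),
        stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, rows)
  auc <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
    a <- vapply(norm_names, function(mn) metric_auc(grid, norm_store[i, , mn]),
                numeric(1))
    cbind(data.frame(subject = subjects[i], group = groups[i],
                     stringsAsFactors = FALSE), as.data.frame(t(a)))
  }))
  list(profiles = profiles, auc = auc, grid = grid)
}

#' Validate the sparsity range on a cohort
#'
#' Checks, per threshold, the group-mean minimal degree (>= 1), and the mean
#' normalized clustering and path length criteria (`gamma_norm > 1`,
#' `lambda_norm > 1`; in small networks the clustering criterion
#' `gamma > gamma_rand` substitutes for the path-length requirement). Returns
#' the largest contiguous passing sub-grid.
#'
#' @param profiles profile data frame from [network_profiles()].
#' @param small_network apply the small-network fallback.
#' @return List with `range` (numeric `c(lo, hi)`), `pass` (per-threshold
#'   logical), and `criteria` (data frame of per-criterion values).
#' @export
sparsity_range <- function(profiles, small_network = TRUE) {
  taus <- sort(unique(profiles$tau))
  crit <- do.call(rbind, lapply(taus, function(tv) {
    p <- profiles[profiles$tau == tv, ]
    data.frame(
      tau = tv,
      mean_min_degree = mean(p$min_degree[p$metric == "gamma"], na.rm = TRUE),
      gamma_norm = mean(p$normalized[p$metric == "gamma"], na.rm = TRUE),
      lambda_norm = mean(p$normalized[p$metric == "lambda"], na.rm = TRUE))
  }))
  k_ok <- crit$mean_min_degree >= 1
  g_ok <- is.finite(crit$gamma_norm) & crit$gamma_norm > 1
  l_ok <- is.finite(crit$lambda_norm) & crit$lambda_norm > 1
  pass <- k_ok & g_ok & (l_ok | small_network)
  if (!any(pass)) stop("no threshold satisfies the sparsity criteria")
  r <- true_runs(pass)
  best <- which.max(r[, "end"] - r[, "start"])
  list(range = c(taus[r[best, "start"]], taus[r[best, "end"]]),
       pass = pass, criteria = cbind(crit, k_ok, g_ok, l_ok, pass))
}
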
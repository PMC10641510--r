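# Independent brute-force oracles for graph metrics, built by direct
# enumeration so they share no code path with the package implementation.

# all simple paths between i and j by depth-first enumeration; returns the
# minimum total length over lengths 1/w
oracle_shortest <- function(w, i, j) {
  n <- nrow(w)
  best <- Inf
  visit <- function(node, len, seen) {
    if (len >= best) return(invisible())
    if (node == j) { best <<- len; return(invisible()) }
    for (m in seq_len(n)) {
      if (!seen[m] && w[node, m] > 0) {
        seen[m] <- TRUE
        visit(m, len + 1 / w[node, m], seen)
        seen[m] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n); seen[i] <- TRUE
  visit(i, 0, seen)
  best
}

oracle_all_lengths <- function(w) {
  n <- nrow(w)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) D[i, j] <- oracle_shortest(w, i, j)
  D
}

oracle_eglob <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  D <- oracle_all_lengths(w)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && is.finite(D[i, j]))
    s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

oracle_lambda <- function(w) {
  D <- oracle_all_lengths(w)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

# geometric-mean triangle clustering by direct triple loop
oracle_gamma_nodal <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  vapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    s / (k * (k - 1))
  }, numeric(1))
}

oracle_eloc_nodal <- function(w) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_eglob(w[nb, nb, drop = FALSE])
  }, numeric(1))
}

# random connected weighted graph on n nodes
random_connected_graph <- function(n, density = 0.45) {
  repeat {
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (runif(1) < density) w[i, j] <- w[j, i] <- runif(1, 0.05, 1)
    k <- rowSums(w > 0)
    if (all(k >= 1)) {
      # connectivity via reachability over the binary adjacency
      reach <- (w > 0)
      for (s in seq_len(n)) reach <- reach | (reach %*% reach > 0)
      if (all(reach[1, -1])) return(w)
    }
  }
}

# modular stage-B-like matrix: two dense blocks and a few strong bridges
modular_matrix <- function(n = 50, n_bridges = 8, seed = 1) {
  set.seed(seed)
  b <- matrix(rnorm(n * n, 0, 0.004), n, n)
  blk <- rep(1:2, each = n / 2)
  within <- outer(blk, blk, "==")
  b[within] <- b[within] + 0.35 + rnorm(sum(within), 0, 0.05)
  i <- sample(which(blk == 1), n_bridges)
  j <- sample(which(blk == 2), n_bridges)
  for (k in seq_len(n_bridges))
    b[i[k], j[k]] <- b[j[k], i[k]] <- 0.30 + runif(1, 0, 0.05)
  b <- (b + t(b)) / 2
  diag(b) <- 0
  b
}

# symmetric zero-diagonal matrix with given edge values
random_edge_matrix <- function(n, mu = 0, sd = 1) {
  edge_matrix(rnorm(n * (n - 1) / 2, mu, sd), n)
}
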
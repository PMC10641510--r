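# Trilinear (canonical polyadic) decomposition by alternating least squares,
# used to isolate and subtract movement-artifact signatures from short
# intervals of the time x channel x wavelength intensity tensor.

# Khatri-Rao (column-wise Kronecker) product
khatri_rao <- function(A, B) {
  r <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), r)
  for (k in seq_len(r)) out[, k] <- kronecker(A[, k], B[, k])
  out
}

# mode-n unfolding of a 3-way array (mode fibers as rows)
unfold <- function(X, mode) {
  d <- dim(X)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  matrix(aperm(X, perm), d[mode], prod(d[-mode]))
}

#' Canonical polyadic decomposition via alternating least squares
#'
#' Decomposes a 3-way array into `rank` rank-one components
#' `X ~ sum_k a_k o b_k o c_k`. Factors are normalized (unit-norm time
#' factors, with component scales folded into the last mode).
#'
#' @param X 3-way numeric array.
#' @param rank number of components (>= 1).
#' @param max_iter maximum ALS sweeps.
#' @param tol relative change in fit for convergence.
#' @param seed integer seed for random initialization.
#' @return List with factor matrices `A`, `B`, `C` (modes 1-3), `fit`
#'   (explained variance proportion), `converged`, `iterations`.
#' @export
cp_als <- function(X, rank, max_iter = 500L, tol = 1e-8, seed = 1L) {
  stopifnot(length(dim(X)) == 3L, rank >= 1L)
  set.seed(derive_seed(seed, "cp_als"))
  d <- dim(X)
  X1 <- unfold(X, 1); X2 <- unfold(X, 2); X3 <- unfold(X, 3)
  # leading singular vectors of the unfoldings (padded with noise when the
  # mode dimension is below the rank) make ALS far more reliable than a
  # purely random start
  svd_init <- function(Xn, dn) {
    r_eff <- min(rank, dn, ncol(Xn))
    U <- svd(Xn, nu = r_eff, nv = 0)$u
    if (r_eff < rank)
      U <- cbind(U, matrix(rnorm(dn * (rank - r_eff), sd = 0.1), dn))
    U
  }
  A <- svd_init(X1, d[1])
  B <- svd_init(X2, d[2])
  C <- svd_init(X3, d[3])
  normX2 <- sum(X^2)
  fit_old <- -Inf; converged <- FALSE; it <- 0L
  solve_ls <- function(Xn, U, V) {
    KR <- khatri_rao(U, V)
    G <- crossprod(U) * crossprod(V)
    t(solve(G + diag(1e-12, rank), t(Xn %*% KR)))
  }
  for (it in seq_len(max_iter)) {
    A <- solve_ls(X1, C, B)
    B <- solve_ls(X2, C, A)
    C <- solve_ls(X3, B, A)
    # fit via residual norm identity
    KR <- khatri_rao(B, A)
    res2 <- normX2 - 2 * sum(X3 * (C %*% t(KR))) +
      sum(crossprod(C) * (crossprod(A) * crossprod(B)))
    fit <- 1 - max(res2, 0) / normX2
    if (is.finite(fit_old) && abs(fit - fit_old) < tol) { converged <- TRUE; break }
    fit_old <- fit
  }
  # normalize: unit-norm A and B columns, scale into C
  for (k in seq_len(rank)) {
    na <- sqrt(sum(A[, k]^2)); nb <- sqrt(sum(B[, k]^2))
    if (na > 0) { A[, k] <- A[, k] / na }
    if (nb > 0) { B[, k] <- B[, k] / nb }
    C[, k] <- C[, k] * na * nb
  }
  list(A = A, B = B, C = C, fit = fit, converged = converged, iterations = it)
}

#' PARAFAC correction of an artifact interval
#'
#' Decomposes the time x channel x wavelength tensor of the flagged interval
#' (plus context padding) into `rank` trilinear components, identifies
#' components whose time-course variance concentrates inside the interval
#' relative to the context, and subtracts those components inside the
#' interval; each component is linearly detrended through short boundary
#' averages (`taper_s`) so the corrected signal stays continuous at the
#' interval edges.
#'
#' @param intensity channel x time x wavelength array.
#' @param interval one-row annotation data frame (`onset_s`, `duration_s`).
#' @param fs sampling rate (Hz).
#' @param rank decomposition rank.
#' @param pad_s context padding on each side, seconds.
#' @param var_ratio minimum within/context variance ratio for a component to
#'   count as artifact.
#' @param taper_s blend duration at the interval boundaries.
#' @param seed integer seed.
#' @return List with `series` (corrected array), `converged`, and
#'   `components_removed`.
#' @export
parafac_correct <- function(intensity, interval, fs, rank = 3L, pad_s = 6,
                            var_ratio = 2, taper_s = 1, seed = 1L) {
  stopifnot(rank >= 1L, nrow(interval) == 1L)
  n_time <- dim(intensity)[2]
  a <- max(1L, floor(interval$onset_s[1] * fs) + 1L)
  b <- min(n_time, ceiling((interval$onset_s[1] + interval$duration_s[1]) * fs))
  pa <- max(1L, a - round(pad_s * fs))
  pb <- min(n_time, b + round(pad_s * fs))
  idx <- pa:pb
  inside <- (idx >= a) & (idx <= b)
  if (!any(!inside)) return(list(series = intensity, converged = FALSE,
                                 components_removed = integer()))

  # time x channel x wavelength tensor, per-fiber mean removed
  X <- aperm(intensity[, idx, , drop = FALSE], c(2, 1, 3))
  mu <- apply(X, c(2, 3), mean)
  Xc <- sweep(X, c(2, 3), mu)
  dec <- cp_als(Xc, rank = rank, seed = seed)
  if (!dec$converged) {
    warning("PARAFAC did not converge; interval left for exclusion")
    return(list(series = intensity, converged = FALSE,
                components_removed = integer()))
  }
  v_in <- apply(dec$A[inside, , drop = FALSE], 2, var)
  v_out <- apply(dec$A[!inside, , drop = FALSE], 2, var)
  art <- which(v_in / pmax(v_out, 1e-30) > var_ratio)
  if (!length(art)) return(list(series = intensity, converged = TRUE,
                                components_removed = integer()))

  # subtract inside the interval only; each component's time course is
  # linearly detrended through short context averages taken just outside the
  # interval (where the artifact is absent), so the corrected signal stays
  # continuous at the interval edges
  ins <- which(inside)
  n_tap <- max(1L, round(taper_s * fs))
  before <- which(!inside & seq_along(idx) < ins[1])
  after <- which(!inside & seq_along(idx) > ins[length(ins)])
  lo <- if (length(before)) rev(before)[seq_len(min(n_tap, length(before)))] else
    ins[seq_len(min(n_tap, length(ins)))]
  hi <- if (length(after)) after[seq_len(min(n_tap, length(after)))] else
    rev(ins)[seq_len(min(n_tap, length(ins)))]
  out <- intensity
  for (k in art) {
    a_k <- dec$A[, k]
    v_lo <- mean(a_k[lo]); v_hi <- mean(a_k[hi])
    u <- (ins - ins[1]) / max(1L, ins[length(ins)] - ins[1])
    a_adj <- a_k[ins] - (v_lo + u * (v_hi - v_lo))
    comp <- outer(a_adj, dec$B[, k])                    # time x channel
    for (lam in seq_len(dim(intensity)[3]))
      out[, idx[ins], lam] <- out[, idx[ins], lam] - t(comp) * dec$C[lam, k]
  }
  list(series = out, converged = TRUE, components_removed = art)
}
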
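# Subject-level functional connectivity: circular-bootstrap windowed Pearson
# correlation (stage A), Fisher transformation, age regression (stage B), and
# task - rest residual matrices (stage R).

#' Construct an FC matrix object
#'
#' @param values symmetric channel x channel matrix, zero diagonal.
#' @param stage `"A"` (averaged correlation), `"B"` (Fisher z, age-regressed)
#'   or `"R"` (task - rest residual).
#' @param condition `"rest"`, `"task"` or `"residual"`.
#' @param subject subject identifier.
#' @param n_samples_used number of bootstrap windows averaged.
#' @return Object of class `fc_matrix`.
#' @export
fc_matrix <- function(values, stage, condition, subject = NA,
                      n_samples_used = NA_integer_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-10)
    stop("FC matrix must be symmetric")
  if (any(diag(values) != 0)) stop("FC matrix must have zero diagonal")
  structure(list(values = values, stage = stage, condition = condition,
                 subject = subject, n_samples_used = n_samples_used),
            class = "fc_matrix")
}

#' Draw circular-bootstrap window start indices
#'
#' Samples `n` random fixed-length windows from the recording treated as a
#' ring (windows may wrap past the end). A window is valid only when it
#' contains no masked sample; draws are repeated until `n` valid windows are
#' collected, up to `100 * n` attempts.
#'
#' @param n_time number of samples in the recording.
#' @param fs sampling rate (Hz).
#' @param n number of windows.
#' @param win_s window length in seconds.
#' @param valid_mask logical validity mask (default all valid).
#' @param seed integer seed.
#' @return List with `starts` (integer vector), `win_len`, and `windows`
#'   (function mapping a start to its index vector).
#' @export
circular_bootstrap_windows <- function(n_time, fs, n = 200L, win_s = 60,
                                       valid_mask = NULL, seed = 1L) {
  win_len <- round(win_s * fs)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n_time)
  if (sum(valid_mask) < win_len)
    stop("total valid time shorter than one window")
  set.seed(derive_seed(seed, "bootstrap"))
  starts <- integer(0)
  draws <- 0L
  window_idx <- function(s) ((s - 1L + seq_len(win_len) - 1L) %% n_time) + 1L
  while (length(starts) < n && draws < 100L * n) {
    cand <- sample.int(n_time, min(4L * n, 100L * n - draws), replace = TRUE)
    draws <- draws + length(cand)
    ok <- vapply(cand, function(s) all(valid_mask[window_idx(s)]), logical(1))
    starts <- c(starts, cand[ok])
  }
  if (length(starts) < n)
    stop("could only draw ", length(starts), " valid windows of ", n,
         " requested within the draw cap")
  list(starts = starts[seq_len(n)], win_len = win_len, windows = window_idx)
}

#' Pairwise Pearson correlation of one window
#'
#' Zero-lag Pearson correlation between all channel pairs of a window;
#' diagonal set to zero. Pairs involving a zero-variance channel are `NA`
#' and excluded from averaging downstream.
#'
#' @param x channel x window-length matrix.
#' @return Symmetric correlation matrix with zero diagonal.
#' @export
window_correlation <- function(x) {
  stopifnot(ncol(x) >= 2, nrow(x) >= 2)
  rho <- suppressWarnings(cor(t(x)))
  diag(rho) <- 0
  rho
}

#' Average windowed correlation matrices (stage A)
#'
#' @param mats list of summand matrices from [window_correlation()].
#' @param subject,condition metadata for the result.
#' @return An [fc_matrix()] at stage `"A"` (element-wise mean over windows;
#'   missing entries averaged over available windows).
#' @export
average_windows <- function(mats, subject = NA, condition = "task") {
  stopifnot(length(mats) >= 1)
  arr <- simplify2array(mats)
  avg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  nan <- !is.finite(avg) & row(avg) != col(avg)
  if (any(nan)) {
    bad <- which(nan, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("channel pair(s) with no valid window: ",
         paste(apply(bad, 1, paste, collapse = "-"), collapse = ", "))
  }
  fc_matrix(avg, stage = "A", condition = condition, subject = subject,
            n_samples_used = length(mats))
}

#' Estimate a stage-A FC matrix from an HbO series
#'
#' Convenience wrapper: draws circular-bootstrap windows, correlates each,
#' and averages.
#'
#' @param hbo channel x time matrix.
#' @param fs sampling rate.
#' @param n_windows,win_s bootstrap parameters.
#' @param valid_mask validity mask.
#' @param subject,condition metadata.
#' @param seed integer seed.
#' @return Stage-A [fc_matrix()].
#' @export
stage_a_matrix <- function(hbo, fs, n_windows = 200L, win_s = 60,
                           valid_mask = NULL, subject = NA,
                           condition = "task", seed = 1L) {
  bw <- circular_bootstrap_windows(ncol(hbo), fs, n = n_windows, win_s = win_s,
                                   valid_mask = valid_mask, seed = seed)
  mats <- lapply(bw$starts, function(s) window_correlation(hbo[, bw$windows(s)]))
  average_windows(mats, subject = subject, condition = condition)
}

#' Fisher transformation of a stage-A matrix
#'
#' `z = atanh(rho)` element-wise; the diagonal stays zero. Off-diagonal
#' magnitudes of exactly 1 are clipped to `1 - 1e-7` with a warning.
#'
#' @param fc stage-A [fc_matrix()] (or plain matrix).
#' @return `fc_matrix` of Fisher-z values (stage label `"A"` retained until
#'   age regression produces stage B).
#' @export
fisher_transform <- function(fc) {
  v <- if (inherits(fc, "fc_matrix")) fc$values else fc
  off <- row(v) != col(v)
  if (any(abs(v[off]) >= 1)) {
    warning("correlation magnitude 1 clipped to 1 - 1e-7")
    v[off] <- pmin(pmax(v[off], -1 + 1e-7), 1 - 1e-7)
  }
  z <- atanh(v)
  diag(z) <- 0
  if (inherits(fc, "fc_matrix"))
    fc_matrix(z, stage = fc$stage, condition = fc$condition,
              subject = fc$subject, n_samples_used = fc$n_samples_used)
  else z
}

#' Regress age from a cohort of Fisher-z matrices
#'
#' Fits, per edge, an ordinary least squares model of the z values on age
#' across all subjects of a condition (patients and controls pooled), and
#' removes the age effect while retaining each subject's grand level:
#' `B_n = z_n - beta1 * (age_n - mean(age))`.
#'
#' @param z_mats list of Fisher-z `fc_matrix` objects (one per subject).
#' @param ages numeric vector of ages (years).
#' @return List with `age_model` (list of `beta0`, `beta1` edge matrices) and
#'   `b_mats` (stage-B `fc_matrix` list). With fewer than 3 subjects or zero
#'   age variance, B = z with a warning.
#' @export
regress_age <- function(z_mats, ages) {
  stopifnot(length(z_mats) == length(ages))
  vals <- lapply(z_mats, function(m) if (inherits(m, "fc_matrix")) m$values else m)
  n <- length(vals)
  if (n < 3 || var(ages) == 0) {
    warning("age regression skipped (need >= 3 subjects and age variance)")
    b <- lapply(seq_len(n), function(i) {
      m <- z_mats[[i]]
      fc_matrix(vals[[i]], "B", m$condition %||% "task", m$subject %||% i,
                m$n_samples_used %||% NA_integer_)
    })
    return(list(age_model = NULL, b_mats = b))
  }
  arr <- simplify2array(vals)                      # ch x ch x subject
  age_c <- ages - mean(ages)
  mean_mat <- apply(arr, c(1, 2), mean)
  beta1 <- apply(sweep(arr, c(1, 2), mean_mat), c(1, 2),
                 function(v) sum(v * age_c)) / sum(age_c^2)
  beta0 <- mean_mat - beta1 * mean(ages)
  b <- lapply(seq_len(n), function(i) {
    m <- z_mats[[i]]
    bv <- vals[[i]] - beta1 * age_c[i]
    diag(bv) <- 0
    fc_matrix(bv, "B", m$condition %||% "task", m$subject %||% i,
              m$n_samples_used %||% NA_integer_)
  })
  list(age_model = list(beta0 = beta0, beta1 = beta1), b_mats = b)
}

#' Task - rest residual matrix (stage R)
#'
#' @param b_task,b_rest stage-B `fc_matrix` objects for the same subject and
#'   channel set.
#' @return Stage-R [fc_matrix()] (element-wise `task - rest`).
#' @export
residual_matrix <- function(b_task, b_rest) {
  vt <- b_task$values; vr <- b_rest$values
  if (!identical(dim(vt), dim(vr)))
    stop("channel sets of task and rest matrices differ")
  if (!is.na(b_task$subject) && !is.na(b_rest$subject) &&
      !identical(b_task$subject, b_rest$subject))
    stop("task and rest matrices belong to different subjects")
  fc_matrix(vt - vr, stage = "R", condition = "residual",
            subject = b_task$subject,
            n_samples_used = min(b_task$n_samples_used, b_rest$n_samples_used))
}

#' Vectorize the upper triangle of a symmetric edge matrix
#' @param m matrix or `fc_matrix`.
#' @return Numeric vector of the `n(n-1)/2` unique edges (column-major upper
#'   triangle).
#' @export
edge_vector <- function(m) {
  v <- if (inherits(m, "fc_matrix")) m$values else m
  v[upper.tri(v)]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#' @param e edge vector as produced by [edge_vector()].
#' @param n number of nodes.
#' @return Symmetric matrix with zero diagonal.
#' @export
edge_matrix <- function(e, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- e
  m + t(m)
}
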
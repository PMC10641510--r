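#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically from
#' the master seed and a stage label, so that a single integer reproduces the
#' whole analysis while stages remain statistically independent.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"bootstrap"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 1977326743  # 7^11, < 2^31
  as.integer((abs(master) + h) %% 2147483629)
}

#' Convert labelled intervals to a per-sample logical mask
#'
#' Intervals use 0-based half-open `[onset, onset + duration)` second
#' conventions; conversion to sample indices uses floor for the start and
#' ceiling for the end, so every sample with any overlap is covered.
#'
#' @param intervals data frame with columns `onset_s`, `duration_s`.
#' @param n_time number of samples.
#' @param fs sampling rate (Hz).
#' @return Logical vector, `TRUE` where any interval covers the sample.
#' @export
intervals_to_mask <- function(intervals, n_time, fs) {
  m <- logical(n_time)
  if (is.null(intervals) || nrow(intervals) == 0L) return(m)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals$onset_s[i] * fs) + 1L)
    b <- min(n_time, ceiling((intervals$onset_s[i] + intervals$duration_s[i]) * fs))
    if (b >= a) m[a:b] <- TRUE
  }
  m
}

#' Merge intervals closer than a gap
#'
#' Sorts intervals by onset and fuses any pair whose gap is smaller than
#' `gap_s`, keeping the union of affected channels.
#'
#' @param intervals data frame with `onset_s`, `duration_s` and optionally a
#'   `channels` list-column.
#' @param gap_s merge gap in seconds.
#' @return Merged data frame.
#' @export
merge_intervals <- function(intervals, gap_s) {
  if (is.null(intervals) || nrow(intervals) <= 1L) return(intervals)
  o <- order(intervals$onset_s)
  intervals <- intervals[o, , drop = FALSE]
  has_ch <- "channels" %in% names(intervals)
  out <- intervals[1, , drop = FALSE]
  for (i in seq_len(nrow(intervals))[-1]) {
    last <- nrow(out)
    end_prev <- out$onset_s[last] + out$duration_s[last]
    if (intervals$onset_s[i] - end_prev < gap_s) {
      new_end <- max(end_prev, intervals$onset_s[i] + intervals$duration_s[i])
      out$duration_s[last] <- new_end - out$onset_s[last]
      if (has_ch) {
        out$channels[[last]] <- sort(union(out$channels[[last]],
                                           intervals$channels[[i]]))
      }
    } else {
      out <- rbind(out, intervals[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Construct an annotation set
#'
#' @param onset_s,duration_s numeric vectors (seconds).
#' @param label character vector; one of `"artifact"`, `"exclusion"`,
#'   `"stimulus"`.
#' @param channels list of integer channel indices per interval, or `NULL`
#'   meaning all channels.
#' @return A data frame of class `nirs_annotations`.
#' @export
annotation_set <- function(onset_s = numeric(), duration_s = numeric(),
                           label = character(), channels = NULL) {
  stopifnot(length(onset_s) == length(duration_s),
            length(onset_s) == length(label))
  if (length(onset_s) && (any(onset_s < 0) || any(duration_s <= 0)))
    stop("annotation intervals must have onset >= 0 and duration > 0")
  bad <- setdiff(unique(label), c("artifact", "exclusion", "stimulus"))
  if (length(bad)) stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
  if (is.null(channels)) channels <- replicate(length(onset_s), NA_integer_,
                                               simplify = FALSE)
  ann <- data.frame(onset_s = as.numeric(onset_s),
                    duration_s = as.numeric(duration_s),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  ann$channels <- channels
  class(ann) <- c("nirs_annotations", "data.frame")
  ann
}

#' Subset annotations by label
#' @param ann annotation set.
#' @param label label to keep.
#' @return Annotation subset.
#' @export
annotations_with_label <- function(ann, label) {
  a <- ann[ann$label == label, , drop = FALSE]
  rownames(a) <- NULL
  a
}

# moving average with edge-shrunk windows (centred); x is a vector
moving_average <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  cs <- cumsum(c(0, x))
  half <- width %/% 2
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# trailing (causal) moving average over the preceding `width` samples
causal_moving_average <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - width + 1L)
  (cs[seq_len(n) + 1L] - cs[lo]) / (seq_len(n) - lo + 1L)
}

# contiguous runs of TRUE; returns matrix with columns start, end (inclusive)
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
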
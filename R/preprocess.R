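# Preprocessing: raw two-wavelength intensity -> artifact-corrected HbO/HbR
# concentration-change series with a per-sample validity mask.
# Stage order: cardiac-coherence QC -> artifact detection -> PARAFAC correction
# or exclusion -> delta optical density -> zero-phase band-pass ->
# modified Beer-Lambert law -> global signal regression.

#' Cardiac-coherence channel quality control
#'
#' Channels with poor optode-to-scalp coupling lack the cardiac oscillation
#' that all well-coupled channels share. For each channel the median
#' magnitude-squared coherence with every other channel, evaluated at the
#' recording's cardiac peak frequency (the largest average-spectrum peak in
#' `band`), is compared against `threshold`.
#'
#' @param raw a `nirs_recording`.
#' @param band cardiac frequency band in Hz (within `(0, fs/2)`).
#' @param threshold minimum median coherence for retention.
#' @param nperseg Welch segment length in samples.
#' @param wavelength which wavelength slice to use (cardiac power is present
#'   in both; 1 = first).
#' @return Logical vector `retained_channels`, with attributes
#'   `cardiac_freq_hz` and `median_coherence`.
#' @export
cardiac_coherence_qc <- function(raw, band = c(0.8, 2.3), threshold = 0.1,
                                 nperseg = 256L, wavelength = 1L) {
  fs <- raw$fs
  stopifnot(band[1] > 0, band[2] < fs / 2)
  x <- raw$intensity[, , wavelength]
  n_time <- ncol(x)
  hop <- nperseg %/% 2L
  if (n_time < 2L * nperseg)
    stop("recording shorter than two coherence windows")
  starts <- seq(1L, n_time - nperseg + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  freqs <- (seq_len(nperseg) - 1L) * fs / nperseg
  bidx <- which(freqs >= band[1] & freqs <= band[2])

  n_ch <- nrow(x)
  # per-segment FFTs, all channels: list over segments of (channel x freq)
  psd_sum <- matrix(0, n_ch, length(bidx))
  coefs <- array(0i, dim = c(n_ch, length(bidx), length(starts)))
  for (s in seq_along(starts)) {
    seg <- x[, starts[s] + seq_len(nperseg) - 1L, drop = FALSE]
    seg <- seg - rowMeans(seg)
    ft <- t(mvfft(t(seg * rep(win, each = n_ch))))
    coefs[, , s] <- ft[, bidx, drop = FALSE]
    psd_sum <- psd_sum + abs(ft[, bidx, drop = FALSE])^2
  }
  peak <- bidx[which.max(colMeans(psd_sum))]
  k <- match(peak, bidx)
  C <- coefs[, k, ]                                  # channel x segment
  S <- C %*% Conj(t(C)) / length(starts)             # cross-spectral matrix
  p <- Re(diag(S))
  msc <- abs(S)^2 / outer(p, p)
  diag(msc) <- NA
  med <- apply(msc, 1, median, na.rm = TRUE)
  retained <- med >= threshold
  attr(retained, "cardiac_freq_hz") <- freqs[peak]
  attr(retained, "median_coherence") <- med
  retained
}

#' Detect motion-artifact intervals
#'
#' Implements a moving-average criterion on light intensity: a sample is a
#' candidate when the deviation from the trailing `window_s`-second moving
#' average exceeds `sd_k` robust standard deviations (1.4826 x MAD of the
#' deviation signal over the whole recording, so artifacts do not inflate
#' their own threshold). Per channel, candidate runs separated by less than
#' `merge_gap_s` are fused, runs shorter than `min_dur_s` dropped. Runs are
#' pooled across channels into events; an event is an artifact when at least
#' `min_frac` of channels carry a qualifying run. Within an event, channels
#' whose segment correlates above `corr_thr` with a flagged channel's segment
#' are added, and events closer than `merge_gap_s` are reported as one.
#'
#' @param series channel x time numeric matrix (typically raw intensity of one
#'   wavelength) or a `nirs_recording`.
#' @param fs sampling rate (taken from the recording when one is supplied).
#' @param window_s moving-average window, seconds.
#' @param sd_k threshold in robust standard deviations.
#' @param min_dur_s minimum artifact duration, seconds.
#' @param min_frac minimum fraction of affected channels.
#' @param corr_thr correlation threshold for channel augmentation.
#' @param merge_gap_s events closer than this are one event.
#' @return Artifact [annotation_set()] with per-event affected channels.
#' @export
detect_artifacts <- function(series, fs = NULL, window_s = 6, sd_k = 3,
                             min_dur_s = 3, min_frac = 0.05, corr_thr = 0.8,
                             merge_gap_s = 2) {
  if (inherits(series, "nirs_recording")) {
    fs <- series$fs
    series <- series$intensity[, , 1]
  }
  stopifnot(!is.null(fs), window_s > 0, sd_k > 0, min_dur_s > 0)
  n_ch <- nrow(series); n_time <- ncol(series)
  win <- round(window_s * fs)
  if (n_time <= win) stop("series shorter than the moving-average window")
  gap <- round(merge_gap_s * fs)
  min_len <- round(min_dur_s * fs)

  runs_by_channel <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    dev <- series[i, ] - causal_moving_average(series[i, ], win)
    sdr <- 1.4826 * mad(dev, constant = 1)
    if (sdr == 0) { runs_by_channel[[i]] <- NULL; next }
    cand <- abs(dev) > sd_k * sdr
    r <- true_runs(cand)
    if (nrow(r) == 0) next
    # fuse runs separated by small gaps, then apply the duration rule
    merged <- r[1, , drop = FALSE]
    if (nrow(r) > 1) for (j in 2:nrow(r)) {
      if (r[j, "start"] - merged[nrow(merged), "end"] <= gap) {
        merged[nrow(merged), "end"] <- r[j, "end"]
      } else merged <- rbind(merged, r[j, , drop = FALSE])
    }
    keep <- (merged[, "end"] - merged[, "start"] + 1L) >= min_len
    runs_by_channel[[i]] <- merged[keep, , drop = FALSE]
  }

  all_runs <- do.call(rbind, lapply(seq_len(n_ch), function(i) {
    r <- runs_by_channel[[i]]
    if (is.null(r) || nrow(r) == 0) return(NULL)
    cbind(r, channel = i)
  }))
  if (is.null(all_runs) || nrow(all_runs) == 0) return(annotation_set())

  # pool overlapping channel runs into events
  o <- order(all_runs[, "start"])
  all_runs <- all_runs[o, , drop = FALSE]
  ev_start <- all_runs[1, "start"]; ev_end <- all_runs[1, "end"]
  ev_ch <- list(all_runs[1, "channel"])
  events <- NULL
  flush <- function(events, s, e, ch)
    rbind(events, data.frame(start = s, end = e,
                             channels = I(list(sort(unique(unlist(ch)))))))
  if (nrow(all_runs) > 1) for (j in 2:nrow(all_runs)) {
    if (all_runs[j, "start"] <= ev_end + gap) {
      ev_end <- max(ev_end, all_runs[j, "end"])
      ev_ch <- c(ev_ch, all_runs[j, "channel"])
    } else {
      events <- flush(events, ev_start, ev_end, ev_ch)
      ev_start <- all_runs[j, "start"]; ev_end <- all_runs[j, "end"]
      ev_ch <- list(all_runs[j, "channel"])
    }
  }
  events <- flush(events, ev_start, ev_end, ev_ch)

  keep <- sapply(events$channels, length) >= min_frac * n_ch
  events <- events[keep, , drop = FALSE]
  if (nrow(events) == 0) return(annotation_set())

  # correlated-channel augmentation within each event
  for (j in seq_len(nrow(events))) {
    idx <- events$start[j]:events$end[j]
    flagged <- events$channels[[j]]
    seg <- t(series[, idx, drop = FALSE])
    cc <- suppressWarnings(cor(seg))
    cc[!is.finite(cc)] <- 0
    extra <- which(apply(cc[, flagged, drop = FALSE], 1, max) > corr_thr)
    events$channels[[j]] <- sort(union(flagged, extra))
  }

  ann <- annotation_set(onset_s = (events$start - 1) / fs,
                        duration_s = (events$end - events$start + 1) / fs,
                        label = rep("artifact", nrow(events)),
                        channels = events$channels)
  merge_intervals(ann, merge_gap_s)
}

#' Build the validity mask from annotations
#'
#' Samples under seizure-labeled exclusion intervals, and under artifact
#' intervals that exceed the long-noise duration threshold or failed
#' correction, are marked invalid.
#'
#' @param annotations annotation set (labels `exclusion` and `artifact`).
#' @param n_time number of samples.
#' @param fs sampling rate.
#' @param long_noise_s artifact intervals at least this long are excluded
#'   rather than corrected.
#' @param failed_correction optional logical vector (one per artifact
#'   interval) marking intervals whose correction failed.
#' @return Logical validity mask (`TRUE` = usable sample).
#' @export
mark_exclusions <- function(annotations, n_time, fs, long_noise_s = 10,
                            failed_correction = NULL) {
  mask <- rep(TRUE, n_time)
  if (is.null(annotations) || nrow(annotations) == 0) return(mask)
  excl <- annotations_with_label(annotations, "exclusion")
  mask[intervals_to_mask(excl, n_time, fs)] <- FALSE
  art <- annotations_with_label(annotations, "artifact")
  if (nrow(art)) {
    long <- art$duration_s >= long_noise_s
    if (!is.null(failed_correction)) long <- long | failed_correction
    mask[intervals_to_mask(art[long, , drop = FALSE], n_time, fs)] <- FALSE
  }
  mask
}

#' Delta optical density
#'
#' `dOD(t) = -log10(I(t) / I_ref)` with `I_ref` the mean intensity over valid
#' samples of the segment, yielding a zero-baseline normalized signal per
#' channel and wavelength.
#'
#' @param intensity channel x time matrix (one wavelength), strictly positive.
#' @param valid_mask logical mask used for the reference mean (default all).
#' @return Matrix of delta optical density, same shape.
#' @export
to_delta_od <- function(intensity, valid_mask = NULL) {
  if (any(intensity <= 0)) stop("intensity must be strictly positive")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, ncol(intensity))
  i_ref <- rowMeans(intensity[, valid_mask, drop = FALSE])
  -log10(intensity / i_ref)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward application of a Butterworth band-pass (4th-order
#' low-pass prototype), so the magnitude response is squared and the phase
#' response cancels. When a validity mask is given, each contiguous valid
#' segment is filtered independently; data are never interpolated across
#' exclusions. Segments too short to filter are dropped from the mask with a
#' warning.
#'
#' @param series channel x time matrix.
#' @param fs sampling rate (Hz).
#' @param band cut-off frequencies in Hz.
#' @param order filter prototype order.
#' @param valid_mask optional logical mask.
#' @return List with `series` (filtered; invalid samples set to 0) and
#'   `valid_mask` (possibly reduced).
#' @export
bandpass <- function(series, fs, band = c(0.001, 0.5), order = 4L,
                     valid_mask = NULL) {
  stopifnot(band[1] > 0, band[2] < fs / 2, band[1] < band[2])
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, ncol(series))
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  out <- series * 0
  min_len <- 3L * (2L * order + 1L) * 3L  # filtfilt padding requirement
  runs <- true_runs(valid_mask)
  new_mask <- rep(FALSE, ncol(series))
  if (nrow(runs)) for (j in seq_len(nrow(runs))) {
    idx <- runs[j, "start"]:runs[j, "end"]
    if (length(idx) < min_len) {
      warning("valid segment of ", length(idx),
              " samples too short to filter; dropped from mask")
      next
    }
    for (i in seq_len(nrow(series)))
      out[i, idx] <- signal::filtfilt(bf, series[i, idx])
    new_mask[idx] <- TRUE
  }
  list(series = out, valid_mask = new_mask)
}

#' Hemoglobin extinction coefficients
#'
#' Standard compiled base-10 molar extinction coefficients of oxy- and
#' deoxyhemoglobin (cm^-1 per mol/L); override via the `extinction` argument
#' of [beer_lambert()] to use a different table.
#'
#' @param wavelengths wavelengths in nm (760 and/or 850 supported built-in).
#' @return Matrix with rows per wavelength, columns `HbO`, `HbR`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- rbind(`760` = c(HbO = 586.0, HbR = 1548.52),
               `850` = c(HbO = 1058.0, HbR = 691.32))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stop("no built-in extinction values for wavelengths ",
         paste(setdiff(key, rownames(tab)), collapse = ", "),
         "; supply a custom table")
  tab[key, , drop = FALSE]
}

#' Age-dependent differential pathlength factor
#'
#' General wavelength- and age-dependent DPF equation
#' (`223.3 + 0.05624 A^0.8493 - 5.723e-7 l^3 + 1.245e-3 l^2 - 0.9025 l`).
#'
#' @param wavelength_nm wavelength in nm.
#' @param age_years age in years.
#' @return DPF value (dimensionless).
#' @export
dpf_age <- function(wavelength_nm, age_years) {
  223.3 + 0.05624 * age_years^0.8493 - 5.723e-7 * wavelength_nm^3 +
    0.001245 * wavelength_nm^2 - 0.9025 * wavelength_nm
}

#' Modified Beer-Lambert forward model
#'
#' Projects known concentration changes (micromolar) to delta optical density
#' at each wavelength: `dOD = (e_HbO dHbO + e_HbR dHbR) * d * DPF`, with the
#' source-detector distance `d` in cm and concentrations converted to mol/L.
#'
#' @param hbo,hbr channel x time matrices (micromolar).
#' @param age age in years (for the DPF).
#' @param montage montage data frame with `distance_mm`.
#' @param wavelengths pair of wavelengths (nm).
#' @param extinction optional extinction table (see
#'   [extinction_coefficients()]).
#' @param dpf optional length-2 DPF override.
#' @return List of two channel x time dOD matrices (one per wavelength).
#' @export
beer_lambert_forward <- function(hbo, hbr, age, montage,
                                 wavelengths = c(760, 850), extinction = NULL,
                                 dpf = NULL) {
  ext <- extinction %||% extinction_coefficients(wavelengths)
  if (is.null(dpf)) dpf <- dpf_age(wavelengths, age)
  d_cm <- montage$distance_mm / 10
  d_cm[is.na(d_cm)] <- 3
  lapply(1:2, function(w) {
    (ext[w, "HbO"] * hbo + ext[w, "HbR"] * hbr) * 1e-6 * d_cm * dpf[w]
  })
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and time point, the 2x2 linear system relating delta
#' optical density at both wavelengths to oxy-/deoxyhemoglobin concentration
#' changes, using age-appropriate differential pathlength factors.
#'
#' @param dod list of two channel x time dOD matrices.
#' @param age age in years.
#' @param montage montage data frame (`distance_mm`; missing distances default
#'   to 30 mm).
#' @param wavelengths pair of wavelengths (nm).
#' @param extinction optional extinction table override.
#' @param dpf optional length-2 DPF override.
#' @return List with `hbo`, `hbr` (channel x time, micromolar) and `dpf`.
#' @export
beer_lambert <- function(dod, age, montage, wavelengths = c(760, 850),
                         extinction = NULL, dpf = NULL) {
  ext <- extinction %||% extinction_coefficients(wavelengths)
  if (abs(det(ext)) < 1e-12) stop("singular extinction matrix")
  if (is.null(dpf)) dpf <- dpf_age(wavelengths, age)
  d_cm <- montage$distance_mm / 10
  d_cm[is.na(d_cm)] <- 3
  n_ch <- nrow(dod[[1]]); n_time <- ncol(dod[[1]])
  hbo <- matrix(0, n_ch, n_time); hbr <- matrix(0, n_ch, n_time)
  inv <- solve(ext)
  for (i in seq_len(n_ch)) {
    # scale out pathlength per wavelength, then invert the extinction matrix
    y1 <- dod[[1]][i, ] / (d_cm[i] * dpf[1])
    y2 <- dod[[2]][i, ] / (d_cm[i] * dpf[2])
    hbo[i, ] <- (inv[1, 1] * y1 + inv[1, 2] * y2) * 1e6
    hbr[i, ] <- (inv[2, 1] * y1 + inv[2, 2] * y2) * 1e6
  }
  list(hbo = hbo, hbr = hbr, dpf = dpf)
}

#' Global signal regression
#'
#' Regresses the mean time course of all retained channels out of every
#' channel (ordinary least squares with intercept); residuals are orthogonal
#' to the global mean, suppressing remaining systemic physiology.
#'
#' @param series channel x time matrix.
#' @param retained logical vector of channels entering the global mean.
#' @param valid_mask optional sample mask; regression is fitted on valid
#'   samples only (residuals are still returned everywhere).
#' @return Matrix of residuals, same shape.
#' @export
global_signal_regression <- function(series, retained = NULL,
                                     valid_mask = NULL) {
  if (is.null(retained)) retained <- rep(TRUE, nrow(series))
  if (sum(retained) < 2) stop("need at least two retained channels")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, ncol(series))
  g <- colMeans(series[retained, , drop = FALSE])
  X <- cbind(1, g[valid_mask])
  beta <- solve(crossprod(X), crossprod(X, t(series[, valid_mask, drop = FALSE])))
  series - t(cbind(1, g) %*% beta)
}

#' Run the full preprocessing chain on a recording
#'
#' Applies, in order: cardiac-coherence QC, artifact detection, PARAFAC
#' correction of isolated artifact intervals (long or uncorrectable intervals
#' are excluded instead), delta optical density, zero-phase band-pass
#' filtering, the modified Beer-Lambert law, and global signal regression.
#' Externally supplied exclusion annotations (e.g. EEG-identified subclinical
#' seizures) are honored throughout.
#'
#' @param raw a `nirs_recording`.
#' @param annotations optional extra [annotation_set()] (exclusions).
#' @param qc_band,qc_threshold cardiac QC parameters.
#' @param band band-pass cut-offs (Hz).
#' @param long_noise_s artifact intervals at least this long are excluded.
#' @param parafac_rank rank for artifact decomposition.
#' @param seed integer seed (PARAFAC initialization).
#' @param gsr apply global signal regression (default `TRUE`).
#' @return List of class `hemo_series`: `hbo`, `hbr` (channel x time,
#'   micromolar), `fs`, `valid_mask`, `retained_channels`, `dpf`,
#'   `artifacts` (detected annotation set), `qc` (report list).
#' @export
preprocess_recording <- function(raw, annotations = NULL,
                                 qc_band = c(0.8, 2.3), qc_threshold = 0.1,
                                 band = c(0.001, 0.5), long_noise_s = 10,
                                 parafac_rank = 3L, seed = 1L, gsr = TRUE) {
  n_time <- dim(raw$intensity)[2]
  retained <- cardiac_coherence_qc(raw, band = qc_band,
                                   threshold = qc_threshold)

  artifacts <- detect_artifacts(raw$intensity[, , 1], fs = raw$fs)
  ann <- artifacts
  if (!is.null(annotations) && nrow(annotations))
    ann <- rbind(ann, annotations)

  # PARAFAC-correct isolated (short) artifact intervals on intensity
  intensity <- raw$intensity
  failed <- rep(FALSE, nrow(artifacts))
  if (nrow(artifacts)) for (j in seq_len(nrow(artifacts))) {
    if (artifacts$duration_s[j] >= long_noise_s) { failed[j] <- TRUE; next }
    res <- parafac_correct(intensity, artifacts[j, , drop = FALSE], raw$fs,
                           rank = parafac_rank,
                           seed = derive_seed(seed, paste0("parafac", j)))
    if (isTRUE(res$converged)) intensity <- res$series else failed[j] <- TRUE
  }
  n_art_rows <- sum(ann$label == "artifact")
  valid <- mark_exclusions(ann, n_time, raw$fs, long_noise_s = long_noise_s,
                           failed_correction = c(failed, rep(FALSE, n_art_rows - length(failed))))

  dod <- lapply(1:2, function(w) to_delta_od(intensity[, , w], valid))
  f1 <- bandpass(dod[[1]], raw$fs, band = band, valid_mask = valid)
  f2 <- bandpass(dod[[2]], raw$fs, band = band, valid_mask = valid)
  valid <- f1$valid_mask & f2$valid_mask

  bl <- beer_lambert(list(f1$series, f2$series), age = raw$subject$age,
                     montage = raw$montage, wavelengths = raw$wavelengths)
  hbo <- bl$hbo; hbr <- bl$hbr
  if (gsr) {
    hbo <- global_signal_regression(hbo, retained, valid)
    hbr <- global_signal_regression(hbr, retained, valid)
  }
  out <- list(hbo = hbo, hbr = hbr, fs = raw$fs, valid_mask = valid,
              retained_channels = retained, dpf = bl$dpf,
              artifacts = artifacts,
              qc = list(excluded_channels = raw$montage$channel[!retained],
                        cardiac_freq_hz = attr(retained, "cardiac_freq_hz"),
                        n_artifact_intervals = nrow(artifacts),
                        pct_valid_time = 100 * mean(valid)))
  class(out) <- "hemo_series"
  out
}
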
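# Synthetic cohort generator: continuous-wave fNIRS recordings with known
# ground truth, emulating a two-condition (rest / story-listening) pediatric
# language study. Signals are built bottom-up from a latent-factor hemodynamic
# model so that every planted inter-channel correlation is known exactly.

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic recording generator.
#' Defaults mirror a typical pediatric language protocol: 50 measurement
#' channels at 7.8 Hz and two wavelengths (760/850 nm), 12-minute conditions,
#' and an 18-block story-listening paradigm (~20 s stimuli, 15-20 s
#' inter-stimulus intervals).
#'
#' @param n_channels number of measurement channels.
#' @param fs sampling rate in Hz.
#' @param wavelengths pair of wavelengths in nm.
#' @param duration_s recording duration per condition, seconds (>= 60).
#' @param n_blocks number of stimulus blocks in the task condition.
#' @param stim_dur_s stimulus duration, seconds.
#' @param isi_range_s inter-stimulus interval range `(lo, hi)`, seconds.
#' @param latent_structure function `(montage, condition, offsets)` returning a
#'   target correlation matrix, or `NULL` for the built-in language-network
#'   structure (see [target_correlation()]).
#' @param artifact_spec list of artifact descriptors, each a list with fields
#'   `kind` (`"spike"`, `"step"` or `"drift"`), `amplitude` (in robust-SD units
#'   of the detail signal), `duration_s`, `frac_channels`, and `n` events.
#' @param bad_channel_frac fraction of channels with poor optode coupling
#'   (attenuated cardiac power, inflated noise).
#' @param hbo_sd_uM standard deviation of the clean HbO fluctuation (micromolar).
#' @param hbr_ratio HbR is `-hbr_ratio` times HbO (sign-flipped, scaled).
#' @param evoked_weight proportion of variance of the leading latent factor
#'   carried by the stimulus-locked response during the task condition.
#' @param cardiac_od amplitude (optical density) of the shared cardiac
#'   oscillation.
#' @param drift_od standard deviation (optical density) of the low-frequency
#'   drift component.
#' @param noise_od standard deviation (optical density) of white measurement
#'   noise.
#' @param baseline_intensity raw intensity baseline (arbitrary units; only
#'   ratios matter to optical density).
#' @param seed default integer seed for generators that are not handed one.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 50L, fs = 7.8, wavelengths = c(760, 850),
                       duration_s = 720, n_blocks = 18L, stim_dur_s = 20,
                       isi_range_s = c(15, 20), latent_structure = NULL,
                       artifact_spec = list(list(kind = "spike", amplitude = 5,
                                                 duration_s = 5,
                                                 frac_channels = 0.1, n = 2L)),
                       bad_channel_frac = 0, hbo_sd_uM = 0.5, hbr_ratio = 0.3,
                       evoked_weight = 0.6, cardiac_od = 0.002,
                       drift_od = 0.003, noise_od = 5e-4,
                       baseline_intensity = 1, seed = 1L) {
  stopifnot(fs > 0, duration_s >= 60, length(wavelengths) == 2L,
            length(isi_range_s) == 2L, isi_range_s[1] <= isi_range_s[2],
            bad_channel_frac >= 0, bad_channel_frac <= 1,
            n_channels >= 2L, stim_dur_s > 0, n_blocks >= 1L)
  for (a in artifact_spec) {
    stopifnot(a$kind %in% c("spike", "step", "drift"),
              a$frac_channels >= 0, a$frac_channels <= 1)
  }
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              wavelengths = wavelengths, duration_s = duration_s,
              n_blocks = as.integer(n_blocks), stim_dur_s = stim_dur_s,
              isi_range_s = isi_range_s, latent_structure = latent_structure,
              artifact_spec = artifact_spec,
              bad_channel_frac = bad_channel_frac, hbo_sd_uM = hbo_sd_uM,
              hbr_ratio = hbr_ratio, evoked_weight = evoked_weight,
              cardiac_od = cardiac_od, drift_od = drift_od,
              noise_od = noise_od, baseline_intensity = baseline_intensity,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default bilateral montage
#'
#' Builds a channel table covering frontal, temporal, temporoparietal and
#' temporooccipital regions of both hemispheres, with source/detector indices
#' and a uniform 30 mm source-detector separation.
#'
#' @param n_channels number of channels (split evenly across hemispheres).
#' @return Data frame with columns `channel`, `source`, `detector`,
#'   `hemisphere` (`"L"`/`"R"`), `region`, `distance_mm`.
#' @export
default_montage <- function(n_channels = 50L) {
  n_channels <- as.integer(n_channels)
  per_hemi <- ceiling(n_channels / 2)
  region_of <- function(i) {
    # proportions roughly matching a frontotemporal language montage
    cut(i / per_hemi, breaks = c(0, 0.28, 0.56, 0.80, 1),
        labels = c("frontal", "temporal", "temporoparietal",
                   "temporooccipital"))
  }
  idx <- seq_len(n_channels)
  within <- ifelse(idx <= per_hemi, idx, idx - per_hemi)
  data.frame(
    channel = sprintf("ch%02d", idx),
    source = ((idx - 1L) %% 16L) + 1L,
    detector = ((idx + 2L) %% 16L) + 1L,
    hemisphere = ifelse(idx <= per_hemi, "L", "R"),
    region = as.character(region_of(within)),
    distance_mm = 30,
    stringsAsFactors = FALSE
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t_s time points in seconds.
#' @param peak_s time to peak of the positive lobe.
#' @param undershoot_s time to peak of the undershoot.
#' @param ratio undershoot amplitude relative to the peak.
#' @return HRF values (unit peak amplitude is not enforced; shapes are
#'   standardized downstream).
#' @export
canonical_hrf <- function(t_s, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  a1 <- peak_s; a2 <- undershoot_s  # shape parameters with rate 1
  h <- dgamma(t_s, shape = a1, rate = 1) - ratio * dgamma(t_s, shape = a2, rate = 1)
  h
}

#' Build a pseudo-randomized block design
#'
#' Lays out `n_blocks` stimulus intervals of `stim_dur_s` seconds separated by
#' gaps drawn uniformly from `isi_range_s`. Blocks that would end after
#' `duration_s` are truncated from the schedule.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return Stimulus [annotation_set()].
#' @export
build_block_design <- function(cfg, seed = cfg$seed) {
  set.seed(derive_seed(seed, "block_design"))
  gaps <- runif(cfg$n_blocks, cfg$isi_range_s[1], cfg$isi_range_s[2])
  onsets <- cumsum(gaps + c(0, rep(cfg$stim_dur_s, cfg$n_blocks - 1L)))
  keep <- (onsets + cfg$stim_dur_s) <= cfg$duration_s
  if (!any(keep))
    stop("recording too short for a single stimulus block")
  onsets <- onsets[keep]
  annotation_set(onset_s = onsets,
                 duration_s = rep(cfg$stim_dur_s, length(onsets)),
                 label = rep("stimulus", length(onsets)))
}

#' Built-in target correlation structure
#'
#' Region-block correlation structure of a bilateral language network:
#' channels within the same region and hemisphere are most strongly coupled,
#' followed by within-hemisphere, homologous inter-hemispheric, and remaining
#' inter-hemispheric pairs. The task condition strengthens frontotemporal
#' coupling within each hemisphere. Group/subject `offsets` are added to
#' left-intra-hemispheric, right-intra-hemispheric and inter-hemispheric edges
#' respectively; the result is clamped to (-0.95, 0.95) and repaired to the
#' nearest positive-definite correlation matrix.
#'
#' @param montage montage data frame.
#' @param condition `"rest"` or `"task"`.
#' @param offsets list with numeric fields `left_intra`, `right_intra`,
#'   `inter` (defaults 0).
#' @return Positive-definite correlation matrix.
#' @export
target_correlation <- function(montage, condition = c("rest", "task"),
                               offsets = list()) {
  condition <- match.arg(condition)
  n <- nrow(montage)
  hemi <- montage$hemisphere
  region <- montage$region
  same_hemi <- outer(hemi, hemi, "==")
  same_region <- outer(region, region, "==")
  R <- matrix(0.06, n, n)                      # baseline inter-hemispheric
  R[same_hemi & !same_region] <- 0.18
  R[same_hemi & same_region] <- 0.35
  R[!same_hemi & same_region] <- 0.12          # homologous regions
  if (condition == "task") {
    lang <- (region %in% c("frontal", "temporal", "temporoparietal"))
    ft <- outer(lang, lang, "&") & same_hemi
    R[ft] <- R[ft] + 0.12
  }
  off <- function(nm) offsets[[nm]] %||% 0
  left <- hemi == "L"
  li <- outer(left, left, "&")
  ri <- outer(!left, !left, "&")
  ih <- !same_hemi
  R[li] <- R[li] + off("left_intra")
  R[ri] <- R[ri] + off("right_intra")
  R[ih] <- R[ih] + off("inter")
  R <- pmin(pmax(R, -0.95), 0.95)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- NULL
  }
  R
}

# unit-variance, zero-mean standardization of a time course
standardize <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

# One latent stochastic factor: HRF-smoothed white noise mixed with a faster
# lightly smoothed component (equal variance split). The fast component keeps
# the effective sample size of 60-s windows high enough for near-unbiased
# windowed correlation estimates, emulating the broadband low-frequency
# content of real hemodynamic recordings.
latent_factor <- function(n_time, fs, hrf_kernel) {
  slow <- standardize(stats::filter(rnorm(n_time + length(hrf_kernel)),
                                    hrf_kernel, sides = 1)[
                        seq_len(n_time) + length(hrf_kernel) - 1])
  fast <- standardize(moving_average(rnorm(n_time), max(2L, round(fs / 3))))
  standardize(sqrt(0.5) * slow + sqrt(0.5) * fast)
}

# 1/f-like slow drift: standardized random walk
slow_drift <- function(n_time) standardize(cumsum(rnorm(n_time)))

# symmetric matrix square root
sym_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate one synthetic subject recording
#'
#' Builds two-wavelength raw intensity for the requested condition from a
#' latent-factor hemodynamic model: clean HbO is `L %*% F` where `L` is the
#' symmetric square root of the planted correlation matrix and the rows of `F`
#' are independent unit-variance processes; during the task the leading factor
#' carries the stimulus-locked canonical-HRF response. HbR is sign-flipped,
#' scaled HbO. Concentrations are projected to optical density through the
#' modified Beer-Lambert forward model, then cardiac, drift, noise and
#' artifact components are added before exponentiation to intensity.
#'
#' @param cfg a [sim_config()].
#' @param subject list with at least `id`, `group` (`"epilepsy"`/`"control"`)
#'   and `age` (years); may carry `fc_offsets` (see [target_correlation()]).
#' @param seed integer seed; all randomness flows from it.
#' @param condition `"task"` or `"rest"`.
#' @return List of class `nirs_recording` with fields `intensity`
#'   (channel x time x wavelength array), `fs`, `wavelengths`, `montage`,
#'   `subject`, `condition`, `stimuli` (annotation set, task only), `clean`
#'   (list `hbo`, `hbr`, micromolar), `annotations` (artifact truth) and
#'   `ground_truth`.
#' @export
generate_subject <- function(cfg, subject, seed, condition = c("task", "rest")) {
  condition <- match.arg(condition)
  stopifnot(inherits(cfg, "sim_config"), !is.null(subject$age))
  montage <- default_montage(cfg$n_channels)
  n_time <- round(cfg$duration_s * cfg$fs)
  set.seed(derive_seed(seed, paste0("subject_", condition)))

  struct_fun <- cfg$latent_structure %||% target_correlation
  R <- struct_fun(montage, condition, subject$fc_offsets %||% list())
  L <- sym_sqrt(R)

  hrf_k <- canonical_hrf(seq(0, 30, by = 1 / cfg$fs))
  FF <- matrix(0, cfg$n_channels, n_time)
  for (k in seq_len(cfg$n_channels)) FF[k, ] <- latent_factor(n_time, cfg$fs, hrf_k)
  stimuli <- NULL
  if (condition == "task") {
    stimuli <- build_block_design(cfg, seed)
    box <- as.numeric(intervals_to_mask(stimuli, n_time, cfg$fs))
    evoked <- stats::filter(c(rep(0, length(hrf_k)), box), hrf_k,
                            sides = 1)[seq_len(n_time) + length(hrf_k)]
    if (sd(evoked) > 0) {
      w <- cfg$evoked_weight
      FF[1, ] <- standardize(sqrt(w) * standardize(evoked) +
                               sqrt(1 - w) * FF[1, ])
    }
  }
  hbo <- cfg$hbo_sd_uM * (L %*% FF)
  hbr <- -cfg$hbr_ratio * hbo

  dod <- beer_lambert_forward(hbo, hbr, age = subject$age, montage = montage,
                              wavelengths = cfg$wavelengths)

  # shared cardiac oscillation; poorly coupled channels carry almost none
  n_bad <- floor(cfg$bad_channel_frac * cfg$n_channels)
  bad <- if (n_bad > 0) sort(sample.int(cfg$n_channels, n_bad)) else integer()
  f_card <- runif(1, 0.9, 1.5)
  tt <- seq_len(n_time) / cfg$fs
  card_base <- sin(2 * pi * f_card * tt)
  amp <- cfg$cardiac_od * runif(cfg$n_channels, 0.5, 1.5)
  noise_sd <- rep(cfg$noise_od, cfg$n_channels)
  if (n_bad > 0) {
    amp[bad] <- amp[bad] * 0.05
    noise_sd[bad] <- noise_sd[bad] * 10
  }
  phase <- runif(cfg$n_channels, -0.3, 0.3)
  for (w in 1:2) {
    scale_w <- if (w == 1) 1 else 0.8   # cardiac slightly weaker at 850 nm
    for (i in seq_len(cfg$n_channels)) {
      dod[[w]][i, ] <- dod[[w]][i, ] +
        scale_w * amp[i] * sin(2 * pi * f_card * tt + phase[i]) +
        cfg$drift_od * slow_drift(n_time) +
        rnorm(n_time, sd = noise_sd[i])
    }
  }

  inj <- inject_artifacts(dod, cfg, n_time)
  dod <- inj$dod

  intensity <- array(0, dim = c(cfg$n_channels, n_time, 2L))
  for (w in 1:2) intensity[, , w] <- cfg$baseline_intensity * 10^(-dod[[w]])

  gt <- list(true_edge_corr = R, artifact_intervals = inj$annotations,
             excluded_intervals = annotation_set(), bad_channels = bad,
             cohort_effects = subject$fc_offsets %||% list(),
             cardiac_freq = f_card)
  rec <- list(intensity = intensity, fs = cfg$fs,
              wavelengths = cfg$wavelengths, montage = montage,
              subject = subject, condition = condition, stimuli = stimuli,
              clean = list(hbo = hbo, hbr = hbr),
              annotations = inj$annotations, ground_truth = gt)
  class(rec) <- "nirs_recording"
  rec
}

# Inject artifacts specified in cfg$artifact_spec into both wavelength dOD
# matrices. Amplitudes are expressed in robust-SD units of the detail signal
# (dOD minus its trailing 6-s moving average), the scale the artifact detector
# operates on.
inject_artifacts <- function(dod, cfg, n_time) {
  ann <- annotation_set()
  if (!length(cfg$artifact_spec))
    return(list(dod = dod, annotations = ann))
  win <- round(6 * cfg$fs)
  detail_sd <- sapply(seq_len(cfg$n_channels), function(i) {
    1.4826 * mad(dod[[1]][i, ] - causal_moving_average(dod[[1]][i, ], win),
                 constant = 1)
  })
  onsets <- c(); durs <- c(); chans <- list()
  used <- annotation_set()
  for (spec in cfg$artifact_spec) {
    n_ev <- spec$n %||% 1L
    for (e in seq_len(n_ev)) {
      # rejection sampling for non-overlapping placement
      ok <- FALSE
      for (try in 1:200) {
        onset <- runif(1, 10, cfg$duration_s - spec$duration_s - 10)
        if (nrow(used) == 0 ||
            all(onset + spec$duration_s + 4 < used$onset_s |
                onset > used$onset_s + used$duration_s + 4)) { ok <- TRUE; break }
      }
      if (!ok) next
      used <- rbind(used, data.frame(onset_s = onset,
                                     duration_s = spec$duration_s,
                                     label = "artifact",
                                     channels = I(list(NA_integer_))))
      n_aff <- max(1L, round(spec$frac_channels * cfg$n_channels))
      aff <- sort(sample.int(cfg$n_channels, n_aff))
      a <- max(1L, floor(onset * cfg$fs) + 1L)
      b <- min(n_time, ceiling((onset + spec$duration_s) * cfg$fs))
      len <- b - a + 1L
      u <- seq_len(len) / len
      taper <- pmin(1, pmin(u, 1 - u) / 0.15)           # flat-top envelope
      shape <- switch(spec$kind,
        spike = sin(2 * pi * 1.6 * (seq_len(len) / cfg$fs)) * taper,
        step  = as.numeric(u >= 0),                    # boxcar offset
        drift = 2 * pmin(u, 1 - u))                    # up-and-back ramp
      for (i in aff) {
        bump <- spec$amplitude * detail_sd[i] * shape
        for (w in 1:2) dod[[w]][i, a:b] <- dod[[w]][i, a:b] + bump
      }
      onsets <- c(onsets, onset); durs <- c(durs, spec$duration_s)
      chans <- c(chans, list(aff))
    }
  }
  if (length(onsets))
    ann <- annotation_set(onsets, durs, rep("artifact", length(onsets)),
                          channels = chans)
  list(dod = dod, annotations = ann)
}

#' Inject seizure-exclusion intervals
#'
#' Draws `k` non-overlapping exclusion intervals (emulating EEG-identified
#' subclinical seizures whose fNIRS samples must be discarded) and returns
#' them as an annotation set.
#'
#' @param recording a `nirs_recording` (only duration and sampling rate used).
#' @param k number of intervals (>= 0).
#' @param duration_s interval duration in seconds.
#' @param seed integer seed.
#' @return Exclusion [annotation_set()]; also recorded in the returned
#'   attribute-free copy of the recording's ground truth by the caller.
#' @export
inject_seizure_intervals <- function(recording, k, duration_s = 30, seed = 1L) {
  stopifnot(k >= 0)
  if (k == 0) return(annotation_set())
  total_s <- dim(recording$intensity)[2] / recording$fs
  if (k * duration_s > total_s)
    stop("exclusion intervals cannot fit in the recording")
  set.seed(derive_seed(seed, "seizure"))
  onsets <- numeric(0)
  for (i in seq_len(k)) {
    ok <- FALSE
    for (try in 1:500) {
      o <- runif(1, 0, total_s - duration_s)
      if (all(abs(o - onsets) >= duration_s + 1)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place non-overlapping exclusion intervals")
    onsets <- c(onsets, o)
  }
  annotation_set(sort(onsets), rep(duration_s, k),
                 rep("exclusion", k))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject covariates (age uniform on 6-18 years, sex, cognitive
#' scores, clinical factors for patients) and the group-level connectivity
#' effects, optionally generating the full two-condition recordings.
#'
#' Patients receive the connectivity offsets in `effects` (by default a left
#' intra-hemispheric decrement, right intra-hemispheric increment and
#' inter-hemispheric decrement); every subject's structure additionally drifts
#' with age (`age_slope` per year on within-hemisphere edges), and for
#' patients the left-hemisphere coupling is modulated by centered IQ with
#' slope `moderation["patient"]` (scaled), planting a group-moderated
#' association between network topology and cognition.
#'
#' @param n_patients,n_controls group sizes (>= 2 each).
#' @param cfg a [sim_config()].
#' @param effects list with `left_intra`, `right_intra`, `inter`, `age_slope`,
#'   `moderation` (named vector `patient`, `control`), `iq_deficit`.
#' @param seed integer seed.
#' @param signals if `TRUE`, generate recordings for both conditions per
#'   subject (memory-heavy); if `FALSE`, return the cohort table and ground
#'   truth only.
#' @return List with `cohort` (data frame), `subjects` (list of per-subject
#'   recording pairs, or `NULL`), `ground_truth`.
#' @export
generate_cohort <- function(n_patients, n_controls, cfg = sim_config(),
                            effects = cohort_effects(), seed = 1L,
                            signals = FALSE) {
  stopifnot(n_patients >= 2, n_controls >= 2)
  set.seed(derive_seed(seed, "cohort"))
  n <- n_patients + n_controls
  group <- rep(c("epilepsy", "control"), c(n_patients, n_controls))
  age <- runif(n, 6, 18)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  iq <- rnorm(n, 100, 15) - effects$iq_deficit * (group == "epilepsy")
  receptive <- 0.8 * (iq - 100) * 10 / 15 / 10 + rnorm(n, 50, 6) -
    3 * (group == "epilepsy")
  expressive <- 0.7 * (iq - 100) * 10 / 15 / 10 + rnorm(n, 50, 6) -
    3 * (group == "epilepsy")
  type <- ifelse(group == "epilepsy",
                 sample(c("FLE", "TLE"), n, replace = TRUE, prob = c(0.4, 0.6)),
                 NA_character_)
  lateralization <- ifelse(group == "epilepsy",
                           sample(c("left", "right", "bilateral"), n, TRUE,
                                  prob = c(0.25, 0.5, 0.25)), NA_character_)
  onset_age <- ifelse(group == "epilepsy", pmax(1, age - abs(rnorm(n, 5, 3))),
                      NA_real_)
  duration_y <- ifelse(group == "epilepsy", age - onset_age, NA_real_)
  asm_count <- ifelse(group == "epilepsy", sample(1:2, n, TRUE, c(0.7, 0.3)),
                      NA_integer_)
  seizure_control <- ifelse(group == "epilepsy",
                            sample(c("yes", "no"), n, TRUE, c(0.7, 0.3)),
                            NA_character_)
  cohort <- data.frame(
    id = sprintf("sub%02d", seq_len(n)), group = group, age = age, sex = sex,
    family_income = sample(1:5, n, TRUE, prob = c(.05, .1, .2, .3, .35)),
    parental_education = sample(1:6, n, TRUE, prob = c(.02, .05, .13, .2, .3, .3)),
    estimated_iq = iq, receptive_language = receptive,
    expressive_language = expressive, epilepsy_type = type,
    lateralization = lateralization, onset_age = onset_age,
    epilepsy_duration = duration_y, asm_count = asm_count,
    seizure_control = seizure_control, stringsAsFactors = FALSE)

  iq_c <- iq - mean(iq)
  fc_offsets <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- group[i] == "epilepsy"
    slope <- if (pat) effects$moderation[["patient"]] else effects$moderation[["control"]]
    fc_offsets[[i]] <- list(
      left_intra = (if (pat) effects$left_intra else 0) +
        effects$age_slope * (age[i] - 12) +
        effects$moderation_scale * slope * iq_c[i] / 15,
      right_intra = (if (pat) effects$right_intra else 0) +
        effects$age_slope * (age[i] - 12),
      inter = if (pat) effects$inter else 0)
  }

  subjects <- NULL
  if (signals) {
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      subj <- list(id = cohort$id[i], group = group[i], age = age[i],
                   fc_offsets = fc_offsets[[i]])
      s_i <- derive_seed(seed, paste0("cohort_subject_", i))
      subjects[[i]] <- list(
        task = generate_subject(cfg, subj, seed = s_i, condition = "task"),
        rest = generate_subject(cfg, subj, seed = s_i, condition = "rest"))
    }
    names(subjects) <- cohort$id
  }
  gt <- list(effects = effects, fc_offsets = fc_offsets, seed = seed)
  list(cohort = cohort, subjects = subjects, ground_truth = gt)
}

#' Default cohort-level effect sizes
#'
#' @param left_intra,right_intra,inter group FC offsets (correlation scale)
#'   applied to patients.
#' @param age_slope per-year drift of within-hemisphere coupling.
#' @param moderation named numeric vector of IQ-network slopes per group.
#' @param moderation_scale scale factor converting slope units to correlation
#'   offsets per IQ standard deviation.
#' @param iq_deficit mean IQ-point deficit of the patient group.
#' @return List of effect parameters.
#' @export
cohort_effects <- function(left_intra = -0.06, right_intra = 0.06,
                           inter = -0.04, age_slope = 0.004,
                           moderation = c(patient = -1.4, control = 0),
                           moderation_scale = 0.03, iq_deficit = 20) {
  list(left_intra = left_intra, right_intra = right_intra, inter = inter,
       age_slope = age_slope, moderation = moderation,
       moderation_scale = moderation_scale, iq_deficit = iq_deficit)
}

#' Simulate a cohort table for moderation analysis
#'
#' Table-level generator used to study the moderation (interaction) model
#' directly: IQ is drawn exogenously and the network AUC outcome follows
#' `auc = b0 + slope_g * iq_c + b_group * group + noise` with a group-specific
#' slope, so fitted interaction coefficients can be compared with planted ones.
#'
#' @param n_patients,n_controls group sizes.
#' @param slopes named numeric vector `c(patient = , control = )` of AUC-on-IQ
#'   slopes (per IQ standard deviation).
#' @param b0 intercept; `b_group` group main effect; `noise_sd` residual SD.
#' @param seed integer seed.
#' @return Data frame with `group`, `estimated_iq`, `auc`.
#' @export
simulate_moderation_cohort <- function(n_patients = 13, n_controls = 26,
                                       slopes = c(patient = -1.4, control = 0),
                                       b0 = 10, b_group = 0.5, noise_sd = 1,
                                       seed = 1L) {
  set.seed(derive_seed(seed, "moderation"))
  n <- n_patients + n_controls
  group <- rep(c("epilepsy", "control"), c(n_patients, n_controls))
  iq <- rnorm(n, 100, 15)
  iq_c <- (iq - mean(iq)) / 15
  slope <- ifelse(group == "epilepsy", slopes[["patient"]], slopes[["control"]])
  auc <- b0 + slope * iq_c + b_group * (group == "epilepsy") +
    rnorm(n, sd = noise_sd)
  data.frame(group = group, estimated_iq = iq, auc = auc,
             stringsAsFactors = FALSE)
}
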
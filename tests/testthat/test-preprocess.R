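# Preprocessing: QC, artifact detection, masking, dOD, filtering,
# Beer-Lambert, global signal regression.

make_rec <- function(x, fs = 7.8) {
  n_ch <- nrow(x)
  structure(list(intensity = array(rep(x, 2), c(n_ch, ncol(x), 2)), fs = fs,
                 wavelengths = c(760, 850), montage = default_montage(n_ch),
                 subject = list(id = "t", group = "control", age = 10)),
            class = "nirs_recording")
}

test_that("cardiac coherence QC separates coupled from uncoupled channels", {
  set.seed(1)
  fs <- 7.8; n_t <- round(300 * fs); n_ch <- 12
  tt <- seq_len(n_t) / fs
  tone <- sin(2 * pi * 1.2 * tt)
  x <- t(sapply(seq_len(n_ch), function(i) 1 + 0.01 * tone + rnorm(n_t, sd = 0.002)))
  # all channels share the tone -> all retained
  ret <- cardiac_coherence_qc(make_rec(x))
  expect_true(all(ret))
  expect_lt(abs(attr(ret, "cardiac_freq_hz") - 1.2), 0.1)
  # one pure-noise channel -> excluded
  x2 <- x
  x2[5, ] <- 1 + rnorm(n_t, sd = 0.01)
  ret2 <- cardiac_coherence_qc(make_rec(x2))
  expect_false(ret2[5])
  expect_true(all(ret2[-5]))
  # identical channels -> coherence 1, all retained
  x3 <- matrix(rep(1 + 0.01 * tone, 4), 4, byrow = TRUE)
  expect_true(all(cardiac_coherence_qc(make_rec(x3))))
  # too-short recording errors
  expect_error(cardiac_coherence_qc(make_rec(x[, 1:300])), "shorter")
})

test_that("artifact detector applies the amplitude/duration/extent rules", {
  set.seed(2)
  fs <- 7.8; n_t <- round(400 * fs); n_ch <- 50
  x <- matrix(rnorm(n_ch * n_t, sd = 1), n_ch, n_t)
  dev <- x[1, ] - nirsnet:::causal_moving_average(x[1, ], round(6 * fs))
  sd_r <- 1.4826 * mad(dev, constant = 1)
  a <- round(200 * fs); b <- a + round(4 * fs) - 1
  # 5 SD step lasting 4 s on 10% of channels -> one interval covering it
  x_step <- x
  x_step[1:5, a:b] <- x_step[1:5, a:b] + 5 * sd_r
  ann <- detect_artifacts(x_step, fs = fs)
  expect_equal(nrow(ann), 1)
  expect_lte(ann$onset_s, 200)
  expect_gte(ann$onset_s + ann$duration_s, 204)
  # same step on 1 of 50 channels (2%) fails the extent rule
  x_one <- x
  x_one[1, a:b] <- x_one[1, a:b] + 5 * sd_r
  expect_equal(nrow(detect_artifacts(x_one, fs = fs)), 0)
  # two qualifying events 1 s apart merge into one
  x_two <- x
  a2 <- b + round(1 * fs)
  b2 <- a2 + round(4 * fs) - 1
  x_two[1:5, a:b] <- x_two[1:5, a:b] + 5 * sd_r
  x_two[1:5, a2:b2] <- x_two[1:5, a2:b2] - 5 * sd_r
  ann2 <- detect_artifacts(x_two, fs = fs)
  expect_equal(nrow(ann2), 1)
  # correlated channels within the interval are added to the event
  expect_true(all(1:5 %in% ann$channels[[1]]))
  expect_error(detect_artifacts(x[, 1:10], fs = fs), "shorter")
})

test_that("exclusion masking counts samples and unions overlaps", {
  fs <- 7.8; n_t <- round(720 * fs)
  expect_true(all(mark_exclusions(annotation_set(), n_t, fs)))
  ex <- annotation_set(100, 30, "exclusion")
  m <- mark_exclusions(ex, n_t, fs)
  expect_equal(sum(!m), ceiling(130 * fs) - floor(100 * fs))  # 30 s ~ 234
  expect_equal(sum(!m), 234)
  # overlapping artifact and exclusion: union, no double counting
  both <- annotation_set(c(100, 110), c(30, 30), c("exclusion", "artifact"))
  m2 <- mark_exclusions(both, n_t, fs, long_noise_s = 10)
  union_mask <- intervals_to_mask(data.frame(onset_s = 100, duration_s = 40),
                                  n_t, fs)
  expect_equal(!m2, union_mask)
})

test_that("delta optical density definition and round trip", {
  x <- matrix(2, 3, 100)
  expect_true(all(to_delta_od(x) == 0))
  x2 <- matrix(10, 1, 50)
  x2[1, 25] <- 1  # one-sample dip alters I_ref slightly; use explicit ref
  dod <- to_delta_od(x2)
  i_ref <- mean(x2)
  expect_equal(dod[1, 25], -log10(1 / i_ref))
  # round trip
  expect_equal(i_ref * 10^(-dod), x2, tolerance = 1e-12)
  expect_error(to_delta_od(matrix(c(1, -1), 1)), "positive")
})

test_that("band-pass filter has the expected gain and zero phase", {
  fs <- 7.8
  tt <- seq(0, 720, by = 1 / fs)
  mid <- seq(round(length(tt) * 0.2), round(length(tt) * 0.8))
  # passband tone: gain in [0.95, 1], zero lag
  x <- sin(2 * pi * 0.1 * tt)
  y <- bandpass(matrix(x, 1), fs)$series[1, ]
  gain <- sd(y[mid]) / sd(x[mid])
  expect_gte(gain, 0.95); expect_lte(gain, 1.0 + 1e-6)
  cc <- ccf(y[mid], x[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # stopband tone at 1.5 Hz: forward-backward squares the magnitude response;
  # measure the tone amplitude by projection so startup transients of the
  # very-low-frequency high-pass pole do not contaminate the estimate
  x2 <- sin(2 * pi * 1.5 * tt)
  y2 <- bandpass(matrix(x2, 1), fs)$series[1, ]
  proj_amp <- function(v, f, t) {
    2 * sqrt(mean(v * sin(2 * pi * f * t))^2 + mean(v * cos(2 * pi * f * t))^2)
  }
  gain2 <- proj_amp(y2[mid], 1.5, tt[mid]) / proj_amp(x2[mid], 1.5, tt[mid])
  # analytic 4th-order Butterworth band-pass magnitude with bilinear warping
  warp <- function(f) tan(pi * f / fs) * fs / pi
  f1 <- warp(0.001); f2 <- warp(0.5); f <- warp(1.5)
  Q <- (f^2 - f1 * f2) / (f * (f2 - f1))
  expect_lt(abs(gain2 - 1 / (1 + Q^8)), 0.25 / (1 + Q^8))
  expect_lt(gain2, 1e-3)
  # DC is strongly rejected (zero of the band-pass at z = 1; the
  # transfer-function evaluation there is ill-conditioned, so allow slack)
  bf <- signal::butter(4, c(0.001, 0.5) / (fs / 2), type = "pass")
  expect_lt(abs(sum(bf$b) / sum(bf$a)), 1e-3)
  # masked gaps are filtered independently and never interpolated across
  vm <- rep(TRUE, length(tt)); vm[3000:3500] <- FALSE
  out <- bandpass(matrix(x, 1), fs, valid_mask = vm)
  expect_true(all(out$series[1, 3000:3500] == 0))
  expect_false(any(out$valid_mask[3000:3500]))
})

test_that("Beer-Lambert forward/inverse round trip is exact", {
  set.seed(3)
  mont <- default_montage(6)
  hbo <- matrix(rnorm(6 * 200), 6); hbr <- matrix(rnorm(6 * 200), 6)
  dod <- beer_lambert_forward(hbo, hbr, age = 12, montage = mont)
  inv <- beer_lambert(dod, age = 12, montage = mont)
  expect_lt(max(abs(inv$hbo - hbo)) / max(abs(hbo)), 1e-10)
  expect_lt(max(abs(inv$hbr - hbr)) / max(abs(hbr)), 1e-10)
  # zero in -> zero out
  z <- beer_lambert(list(hbo * 0, hbr * 0), age = 12, montage = mont)
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
  # doubling the DPF halves both concentrations
  dpf <- dpf_age(c(760, 850), 12)
  half <- beer_lambert(dod, age = 12, montage = mont, dpf = 2 * dpf)
  expect_equal(half$hbo, hbo / 2, tolerance = 1e-10)
  expect_equal(half$hbr, hbr / 2, tolerance = 1e-10)
  # singular extinction matrix errors
  expect_error(beer_lambert(dod, age = 12, montage = mont,
                            extinction = matrix(1, 2, 2,
                                                dimnames = list(NULL, c("HbO", "HbR")))),
               "singular")
})

test_that("global signal regression removes the global mean component", {
  set.seed(4)
  x <- matrix(rnorm(5 * 400), 5)
  res <- global_signal_regression(x)
  g <- colMeans(x)
  for (i in 1:5) expect_lt(abs(cor(res[i, ], g)), 1e-10)
  # identical channels -> residuals identically zero
  same <- matrix(rep(rnorm(300), 4), 4, byrow = TRUE)
  expect_lt(max(abs(global_signal_regression(same))), 1e-12)
  # channel orthogonal to the global mean is returned unchanged up to its mean
  n <- 400
  g0 <- rnorm(n)
  ortho <- rnorm(n)
  ortho <- ortho - as.numeric(lm(ortho ~ g0)$fitted.values)  # exact orthogonality
  x3 <- rbind(g0 + ortho, g0 - ortho)   # global mean = g0, channel1 - mean = ortho
  res3 <- global_signal_regression(x3)
  expect_equal(res3[1, ], ortho - mean(ortho), tolerance = 1e-10)
  expect_error(global_signal_regression(x[1, , drop = FALSE]), "two")
})

test_that("full preprocessing chain yields a valid hemodynamic series", {
  cfg <- sim_config(n_channels = 16, duration_s = 480, bad_channel_frac = 0.15)
  rec <- generate_subject(cfg, list(id = "s", group = "epilepsy", age = 9),
                          seed = 31)
  excl <- inject_seizure_intervals(rec, k = 1, duration_s = 20, seed = 2)
  h <- suppressWarnings(preprocess_recording(rec, annotations = excl, seed = 5))
  expect_s3_class(h, "hemo_series")
  expect_equal(dim(h$hbo), dim(rec$clean$hbo))
  expect_true(all(is.finite(h$hbo[, h$valid_mask])))
  # seizure samples are masked out
  expect_true(all(!h$valid_mask[intervals_to_mask(excl, ncol(h$hbo), rec$fs)]))
  # poorly coupled channels flagged
  expect_true(all(rec$ground_truth$bad_channels %in%
                    which(!h$retained_channels)))
})
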
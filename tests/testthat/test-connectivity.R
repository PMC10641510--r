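# Circular-bootstrap connectivity, Fisher transform, age regression,
# residual matrices.

test_that("bootstrap windows have the right length, wrap, and honor masks", {
  fs <- 7.8; n_t <- round(720 * fs)
  bw <- circular_bootstrap_windows(n_t, fs, n = 50, seed = 3)
  expect_equal(bw$win_len, 468)
  # a window starting at 690 s wraps into the start of the recording
  s <- floor(690 * fs) + 1
  idx <- bw$windows(s)
  expect_equal(length(idx), 468)
  expect_true(any(idx < s) && any(idx >= s))
  expect_true(all(idx >= 1 & idx <= n_t))
  # masked region is never touched
  vm <- rep(TRUE, n_t)
  vm[(floor(100 * fs) + 1):ceiling(200 * fs)] <- FALSE
  bw2 <- circular_bootstrap_windows(n_t, fs, n = 100, valid_mask = vm,
                                    seed = 4)
  for (s in bw2$starts) expect_true(all(vm[bw2$windows(s)]))
  # infeasible request errors with the achievable count
  vm3 <- rep(FALSE, n_t); vm3[1:100] <- TRUE
  expect_error(circular_bootstrap_windows(n_t, fs, n = 10, valid_mask = vm3),
               "valid")
  # determinism
  expect_identical(circular_bootstrap_windows(n_t, fs, n = 20, seed = 9)$starts,
                   circular_bootstrap_windows(n_t, fs, n = 20, seed = 9)$starts)
})

test_that("window correlation handles duplicates, sign flips and noise", {
  set.seed(5)
  x <- matrix(rnorm(4 * 468), 4)
  x[2, ] <- x[1, ]            # duplicated channel
  x[4, ] <- -x[3, ]           # anti-correlated pair
  rho <- window_correlation(x)
  expect_equal(rho[1, 2], 1)
  expect_equal(rho[3, 4], -1)
  expect_true(all(diag(rho) == 0))
  expect_equal(rho, t(rho))
  # independent white noise: mean ~ 0, SD ~ 1/sqrt(n)
  y <- matrix(rnorm(30 * 468), 30)
  r <- window_correlation(y)
  vals <- r[upper.tri(r)]
  expect_lt(abs(mean(vals)), 0.01)
  expect_lt(abs(sd(vals) - 1 / sqrt(468)), 0.01)
  # zero-variance channel yields NA pairs
  y[1, ] <- 1
  r2 <- suppressWarnings(window_correlation(y))
  expect_true(all(is.na(r2[1, -1])))
})

test_that("window averaging is an element-wise mean with missing handling", {
  set.seed(6)
  m1 <- window_correlation(matrix(rnorm(3 * 100), 3))
  m2 <- window_correlation(matrix(rnorm(3 * 100), 3))
  avg <- average_windows(list(m1, m2), condition = "rest")
  expect_equal(avg$values, (m1 + m2) / 2)
  expect_equal(avg$n_samples_used, 2)
  # identical windows average to any single window
  same <- average_windows(list(m1, m1, m1))
  expect_equal(same$values, m1)
  # a pair missing in all windows is an error naming it
  bad <- m1; bad[1, 2] <- bad[2, 1] <- NA
  expect_error(average_windows(list(bad, bad)), "pair")
})

test_that("Fisher transform matches atanh and clips |rho| = 1", {
  m <- edge_matrix(c(0, 0.5, -0.3), 3)
  z <- fisher_transform(m)
  expect_equal(z[1, 2], 0)
  expect_equal(z[1, 3], atanh(0.5))
  expect_equal(atanh(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(tanh(z), m, tolerance = 1e-12)
  m1 <- edge_matrix(c(1, 0, 0), 3)
  expect_warning(z1 <- fisher_transform(m1), "clip")
  expect_true(is.finite(z1[1, 2]))
})

test_that("age regression removes planted age effects and keeps levels", {
  set.seed(7)
  n_sub <- 24
  ages <- runif(n_sub, 6, 18)
  beta1_true <- edge_matrix(rnorm(6, 0, 0.02), 4)
  base <- edge_matrix(rnorm(6, 0.3, 0.05), 4)
  z <- lapply(seq_len(n_sub), function(i) {
    v <- base + beta1_true * ages[i] + edge_matrix(rnorm(6, 0, 0.01), 4)
    fc_matrix(v, "A", "task", paste0("s", i))
  })
  fit <- regress_age(z, ages)
  # recovered slope close to truth
  expect_lt(max(abs(fit$age_model$beta1 - beta1_true)), 0.005)
  # edge exactly linear in age -> stage-B values constant across subjects
  z2 <- lapply(seq_len(n_sub), function(i)
    fc_matrix(base + beta1_true * ages[i], "A", "task", i))
  fit2 <- regress_age(z2, ages)
  b_edge <- sapply(fit2$b_mats, function(m) m$values[1, 2])
  expect_lt(diff(range(b_edge)), 1e-10)
  # grand level retained (centered-age convention)
  expect_equal(mean(b_edge), base[1, 2] + beta1_true[1, 2] * mean(ages),
               tolerance = 1e-10)
  # degenerate ages fall back to B = A with a warning
  expect_warning(fit3 <- regress_age(z[1:5], rep(10, 5)), "variance")
  expect_equal(fit3$b_mats[[1]]$values, z[[1]]$values)
})

test_that("residual matrices subtract rest from task", {
  vt <- edge_matrix(c(0.5, 0.2, 0.1), 3)
  vr <- edge_matrix(c(0.3, 0.2, -0.1), 3)
  bt <- fc_matrix(vt, "B", "task", "s1", 10L)
  br <- fc_matrix(vr, "B", "rest", "s1", 10L)
  r <- residual_matrix(bt, br)
  expect_equal(r$values, vt - vr)
  expect_equal(r$stage, "R")
  # task = rest -> identically zero
  expect_true(all(residual_matrix(bt, bt)$values == 0))
  # antisymmetry
  expect_equal(residual_matrix(br, bt)$values, -r$values)
  # channel-set mismatch errors
  b4 <- fc_matrix(edge_matrix(rnorm(6), 4), "B", "rest", "s1", 10L)
  expect_error(residual_matrix(bt, b4), "channel")
})

test_that("stage-A estimation is deterministic and symmetric", {
  set.seed(8)
  hbo <- matrix(rnorm(6 * 2000), 6)
  a1 <- stage_a_matrix(hbo, fs = 7.8, n_windows = 30, seed = 5)
  a2 <- stage_a_matrix(hbo, fs = 7.8, n_windows = 30, seed = 5)
  expect_identical(a1$values, a2$values)
  expect_equal(a1$values, t(a1$values))
  expect_true(all(diag(a1$values) == 0))
  expect_true(all(abs(a1$values[upper.tri(a1$values)]) < 1))
})
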
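test_that("segmentation cuts TR-length epochs and drops the partial tail", {
  x <- matrix(rnorm(2 * 2500), 2)  # 10 s at 250 Hz
  segs <- segment(x, fs = 250, segment_len_s = 3.6)
  expect_length(segs, 2)           # floor(2500 / 900)
  expect_equal(ncol(segs[[1]]), 900)

  x <- matrix(rnorm(300 * 1000), nrow = 1, ncol = 300 * 1000)  # 300 s at 1 kHz
  expect_length(segment(x, 1000, 2.0), 150)

  expect_error(segment(matrix(rnorm(100), 1), 250, 3.6), "shorter than one segment")
  expect_error(segment(matrix(rnorm(100), 1), 20, 2), "< 64")
})

test_that("segment rejection implements the 4-SD and +/-300 uV policies", {
  set.seed(4)
  segs <- lapply(1:10, function(k) matrix(rnorm(3 * 200), 3, 200))
  expect_length(reject_segments(segs, "none")$segments, 10)

  zeros <- lapply(1:5, function(k) matrix(0, 2, 100))
  expect_length(reject_segments(zeros, "amp300", units = "uV")$segments, 5)

  spiked <- segs
  whole_sd <- apply(do.call(cbind, segs), 1, sd)
  spiked[[4]][2, 50] <- 10 * whole_sd[2]  # ~10-SD spike
  out <- reject_segments(spiked, "sd4")
  expect_equal(out$rejected, 4L)

  segs_uv <- lapply(segs, function(s) s * 50)
  segs_uv[[7]][1, 3] <- 400
  segs_uv[[2]][1, 3] <- -400
  out <- reject_segments(segs_uv, "amp300", units = "uV")
  expect_equal(out$rejected, c(2L, 7L))
  # brute-force threshold scan oracle
  oracle <- which(sapply(segs_uv, function(s) min(s) < -300 || max(s) > 300))
  expect_equal(out$rejected, oracle)
  expect_error(reject_segments(segs, "amp300", units = "au"), "microvolts")
})

test_that("Welch coherency is 1 for identical signals and ~0 for independent noise", {
  set.seed(9)
  x <- rnorm(2000)
  sp <- segment_coherency(rbind(x, x), fs = 250)
  expect_true(all(abs(Mod(sp$coherency[1, 2, ]) - 1) < 1e-9))
  expect_true(all(abs(Im(sp$coherency[1, 2, ])) < 1e-9))
  expect_equal(sp$dof, 2L * sp$n_windows)

  # |C| of independent noise decays with the number of averaged windows
  co_short <- mean(Mod(segment_coherency(matrix(rnorm(2 * 400), 2), 250)$coherency[1, 2, ]))
  co_long <- mean(sapply(1:20, function(k) {
    mean(Mod(segment_coherency(matrix(rnorm(2 * 8000), 2), 250)$coherency[1, 2, ]))
  }))
  expect_lt(co_long, co_short)
  expect_error(segment_coherency(matrix(rnorm(2 * 150), 2), 250), "2 Welch")
})

test_that("a 90-degree lagged sinusoid pair yields purely imaginary coherency in its bin", {
  fs <- 250
  t_s <- (0:1999) / fs
  x <- cos(2 * pi * 10 * t_s)
  y <- cos(2 * pi * 10 * t_s - pi / 2)
  sp <- segment_coherency(rbind(x, y), fs)
  bin <- which.min(abs(sp$centers - 9))  # 10 Hz falls in the 8-10 Hz bin
  C <- sp$coherency[1, 2, bin]
  expect_lt(abs(Re(C)), 0.05)
  expect_gt(abs(Im(C)), 0.95)
})

test_that("ciCoh suppresses real coherency and follows its closed form", {
  expect_equal(cicoh(0.7 + 0i), 0)       # purely real, any magnitude < 1
  expect_equal(cicoh(0.8i + 0), 0.8)     # Re = 0: ciCoh = |Im|
  expect_equal(cicoh(0.6 + 0.6i), sqrt(0.36 / 0.64))
  expect_equal(sqrt(0.36 / 0.64), 0.75)  # hand arithmetic of the formula
  expect_equal(cicoh(1 + 0i), 0)         # Re^2 = 1 defined as 0
  co <- array(c(1 + 0i, 0.6 + 0.6i, 0.6 - 0.6i, 1 + 0i), c(2, 2, 1))
  ci <- cicoh(co)
  expect_equal(ci[1, 2, 1], 0.75)
  expect_equal(ci[1, 1, 1], 0)           # diagonal excluded
})

test_that("the analytic significance mask follows p = (1 - |C|^2)^((dof-2)/2)", {
  sp <- structure(list(coherency = array(c(0, 0.9i, -0.9i, 0), c(2, 2, 1)),
                       centers = 9, dof = 8L, n_windows = 4L),
                  class = "segment_spectra")
  # |C| = 0.9, dof = 8: p = (1 - 0.81)^3 = 0.006859 <= 0.05 -> kept
  expect_true(significance_mask(sp)[1, 2, 1])
  sp$coherency[1, 2, 1] <- 0.1i + 0
  sp$coherency[2, 1, 1] <- -0.1i + 0
  # p = (1 - 0.01)^3 = 0.970 -> masked
  expect_false(significance_mask(sp)[1, 2, 1])
  sp$dof <- 2L
  expect_error(significance_mask(sp), "dof")
})

test_that("eeg_connectome averages masked bins per band and is duplication-invariant", {
  set.seed(12)
  # all-noise recording: nearly everything masked to zero
  noise <- matrix(rnorm(3 * 250 * 3.6 * 6), 3)
  conn <- eeg_connectome(noise, fs = 250, segment_len_s = 3.6)
  for (b in names(conn)) {
    # null floor of masked ciCoh at this dof is ~alpha * E[ciCoh | kept] ~ 0.02
    expect_lt(mean(vectorize_upper(conn[[b]]$values)), 0.05)
  }
  expect_equal(conn$eeg.alpha$n_samples_used, 6L)

  # persistent lagged alpha driver: alpha edge high, other bands far below
  fs <- 250
  t_s <- (0:(fs * 3.6 * 4 - 1)) / fs
  x <- cos(2 * pi * 10 * t_s) + 0.3 * rnorm(length(t_s))
  y <- cos(2 * pi * 10 * t_s - pi / 2) + 0.3 * rnorm(length(t_s))
  z <- rnorm(length(t_s))
  conn <- eeg_connectome(rbind(x, y, z), fs = fs, segment_len_s = 3.6)
  expect_gt(conn$eeg.alpha$values[1, 2], 0.8)
  expect_lt(conn$eeg.beta$values[1, 2], conn$eeg.alpha$values[1, 2] / 3)
  expect_lt(conn$eeg.delta$values[1, 2], conn$eeg.alpha$values[1, 2] / 3)

  # duplicating every segment leaves the result unchanged
  seg_dup <- cbind(rbind(x, y, z), rbind(x, y, z))
  conn2 <- eeg_connectome(seg_dup, fs = fs, segment_len_s = 3.6)
  expect_equal(conn2$eeg.alpha$values, conn$eeg.alpha$values, tolerance = 1e-12)
})

test_that("band assignment partitions all 2-Hz bins with centers in [0.3, 60]", {
  centers <- seq(1, 59, by = 2)
  bands <- crossconn:::assign_band(centers)
  expect_false(anyNA(bands))
  expect_equal(as.integer(table(bands)[c("delta", "theta", "alpha", "beta", "gamma")]),
               c(2L, 2L, 2L, 9L, 15L))
  bd <- band_definitions()
  expect_equal(bd$f_lo, c(0.3, 4, 8, 12, 30))
  expect_equal(bd$f_hi, c(4, 8, 12, 30, 60))
})

test_that("instantaneous orthogonal mixing leaves ciCoh at the noise floor", {
  set.seed(21)
  R <- 4
  # long segments (28 sub-windows, dof 56) so the masked-null floor is small
  # and a suppression failure would stand out clearly
  N <- 250 * 14.4 * 4
  Z <- matrix(rnorm(R * N), R)
  M <- qr.Q(qr(matrix(rnorm(R * R), R)))  # orthogonal instantaneous mix
  conn_raw <- eeg_connectome(Z, fs = 250, segment_len_s = 14.4)
  conn_mix <- eeg_connectome(M %*% Z, fs = 250, segment_len_s = 14.4)
  for (b in names(conn_mix)) {
    # mixing is instantaneous, so edges stay at/below the suppression floor
    expect_lt(mean(vectorize_upper(conn_mix[[b]]$values)), 0.05)
    expect_lt(abs(mean(vectorize_upper(conn_mix[[b]]$values)) -
                  mean(vectorize_upper(conn_raw[[b]]$values))), 0.05)
  }
})
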
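test_that("latent topology decays with distance and respects lambda = 0", {
  at <- tiny_atlas(20, seed = 2)
  w0 <- latent_topology(at, lambda = 0, perturb_sd = 0)
  expect_true(all(w0 == w0[1]))
  expect_error(latent_topology(at, lambda = -1), "non-negative")

  w <- latent_topology(at, lambda = 0.03, seed = 4)
  d <- edge_distances(at)
  expect_lt(cor(w, d), 0)
  expect_true(all(w >= 0 & w <= 1))
  # monotone decay before perturbation: doubling distances cannot raise weights
  wd <- exp(-0.03 * d)
  expect_true(all(exp(-0.03 * (2 * d)) <= wd))
})

test_that("degenerate design with target 1 and no noise gives rank-identical patterns", {
  d <- tiny_design(R = 12, n = c(control = 2, lTLE = 2, rTLE = 2), noise_sd = 0)
  d$coupling_target[] <- 1
  d$dmn_decoupling <- NULL
  gt <- make_ground_truth(d, synthetic_atlas(12, 1))
  conn <- sample_subject_connectomes(d, gt, "control", seed = 3)
  e <- vectorize_upper(conn$eeg.alpha$values)
  f <- vectorize_upper(conn$fmri$values)
  expect_equal(rank(e), rank(f))
  expect_equal(cor(e, f, method = "spearman"), 1)
})

test_that("unreachable coupling targets raise a calibration failure", {
  expect_error(calibrate_mixture(0.97, noise_sd = 2, n = 10), "calibration failure")
  expect_equal(calibrate_mixture(0.5, 0, 10), 0.5)
})

test_that("realized group-mean coupling recovers targets within 0.05", {
  # calibration property at study scale: R = 68, n >= 15 per group
  targets <- c(0, 0.40, 0.55, 0.7)
  reps <- 12
  for (rho in targets) {
    got <- vapply(seq_len(reps), function(k) {
      d <- simulation_design(R = 68,
                             groups = list(siteA = c(control = 16, lTLE = 1,
                                                     rTLE = 1)),
                             site_params = list(siteA = list(tr_s = 2,
                                                             n_volumes = 100,
                                                             eeg_fs = 250,
                                                             n_segments = 10)),
                             dmn_decoupling = NULL, seed = 5000 + k)
      d$coupling_target["control", "alpha"] <- rho
      sim <- simulate_cohort(d, band_set = "alpha")
      sim$ground_truth$realized$group_mean["control", "alpha"]
    }, numeric(1))
    expect_lt(abs(mean(got) - rho), 0.05)
  }
})

test_that("cohorts regenerate bit-identically from (design, seed)", {
  d <- tiny_design(R = 10, n = c(control = 3, lTLE = 2, rTLE = 2), seed = 77)
  at <- synthetic_atlas(10, 4)
  s1 <- simulate_cohort(d, at, band_set = c("alpha", "beta"))
  s2 <- simulate_cohort(d, at, band_set = c("alpha", "beta"))
  expect_identical(s1$ground_truth$latent, s2$ground_truth$latent)
  expect_identical(s1$stack$subjects[[5]]$connectomes$fmri$values,
                   s2$stack$subjects[[5]]$connectomes$fmri$values)
  expect_identical(s1$stack$subjects[[3]]$age, s2$stack$subjects[[3]]$age)

  ts1 <- sample_region_timeseries(d, s1$stack$subjects[[1]], seed = 9)
  ts2 <- sample_region_timeseries(d, s1$stack$subjects[[1]], seed = 9)
  expect_identical(ts1$eeg$data, ts2$eeg$data)
  expect_identical(ts1$motion, ts2$motion)
})

test_that("generate_cohort writes a reloadable cohort with ground truth", {
  dir <- withr::local_tempdir()
  d <- tiny_design(R = 10, n = c(control = 5, lTLE = 5, rTLE = 5), seed = 21)
  sim <- generate_cohort(d, dir, band_set = "beta")
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(meta), 15)  # 3 groups x 5 subjects, one site
  files <- list.files(file.path(dir, "connectomes"), pattern = "\\.tsv$")
  expect_equal(length(files), 15 * 2)  # fmri + one band each
  back <- read_connectome(file.path(dir, "connectomes", "sub-001_fmri.tsv"))
  expect_equal(back$values, sim$stack$subjects[[1]]$connectomes$fmri$values,
               tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$latent, sim$ground_truth$latent, tolerance = 1e-12)
  expect_equal(gt$seed, d$seed)
})

test_that("lagged drivers and zero-lag mixing shape the simulated EEG as designed", {
  d <- tiny_design(R = 6, n = c(control = 1, lTLE = 1, rTLE = 1), seed = 3)
  d$site_params$siteA$n_segments <- 12
  sim <- simulate_cohort(d, synthetic_atlas(6, 8), band_set = "alpha")
  s <- sim$stack$subjects[[1]]
  # zero-lag mixing only: lagged coherency indistinguishable from noise floor
  ts0 <- sample_region_timeseries(d, s, seed = 10,
                                  lagged_edges = data.frame(i = integer(),
                                                            j = integer(),
                                                            band = character(),
                                                            lag_deg = numeric(),
                                                            amplitude = numeric()))
  conn0 <- eeg_connectome(ts0$eeg)
  for (b in names(conn0)) {
    expect_lt(mean(vectorize_upper(conn0[[b]]$values)), 0.05)
  }
  # a 90-degree lagged 10 Hz driver between regions 1-2 dominates alpha there
  ts1 <- sample_region_timeseries(d, s, seed = 10,
                                  lagged_edges = data.frame(i = 1, j = 2,
                                                            band = "alpha",
                                                            lag_deg = 90,
                                                            amplitude = 8),
                                  noise_amplitude = 0.05)
  conn1 <- eeg_connectome(ts1$eeg)
  expect_gt(conn1$eeg.alpha$values[1, 2], 0.9)
})
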
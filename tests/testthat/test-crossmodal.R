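test_that("cross-modal correlation matches the z-score identity and handles masks", {
  m <- random_symmetric(10, 1, lo = 0, hi = 1)
  expect_equal(crossmodal_correlation(m, m), 1)
  expect_equal(crossmodal_correlation(m, -m), -1)

  x <- random_symmetric(68, 2)
  y <- random_symmetric(68, 3)
  r <- crossmodal_correlation(x, y)
  sc <- spatial_contribution(vectorize_upper(x), vectorize_upper(y))
  expect_equal(r, sum(sc$z_x * sc$z_y), tolerance = 1e-12)

  mask <- vectorize_upper(x) > 0
  expect_equal(crossmodal_correlation(x, y, mask),
               cor(vectorize_upper(x)[mask], vectorize_upper(y)[mask]))
  expect_error(crossmodal_correlation(devectorize(rep(0.5, 3), 3), m[1:3, 1:3]),
               "constant")
  expect_error(crossmodal_correlation(x, y, c(TRUE, TRUE, rep(FALSE, n_edges(68) - 2))),
               "fewer than 3")
})

test_that("contribution decomposition is exact: sum(c) = 1 and c_i * r = z_x z_y", {
  # printed 3-edge toy, checked against direct arithmetic
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  sc <- spatial_contribution(x, y)
  zx <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(sum((y - mean(y))^2))
  expect_equal(sc$r, sum(zx * zy))
  expect_equal(sc$c, zx * zy / sum(zx * zy))
  expect_equal(sum(sc$c), 1, tolerance = 1e-12)

  set.seed(33)
  for (k in 1:50) {
    E <- sample(10:500, 1)
    x <- rnorm(E); y <- rnorm(E) + 0.3 * x
    sc <- spatial_contribution(x, y)
    expect_lt(abs(sum(sc$c) - 1), 1e-9)
    expect_lt(max(abs(sc$c * sc$r - sc$z_x * sc$z_y)), 1e-9)
  }
  expect_error(spatial_contribution(1:5, rep(1, 5)), "constant")
})

test_that("split-half consistency enumerates small even groups and rewards group size", {
  R <- 12
  m <- random_symmetric(R, 5, lo = 0, hi = 1)
  st <- stack_from_matrices(list(m, m))
  sh <- split_half_consistency(st, "control")
  expect_equal(sh$mean_r, 1)
  expect_equal(sh$n_splits, 1)

  st4 <- stack_from_matrices(lapply(1:4, function(i) random_symmetric(R, i)))
  sh4 <- split_half_consistency(st4, "control")
  expect_equal(sh4$n_splits, 3)  # C(4,2)/2 complementary-deduplicated splits

  # homogeneous synthetic group: reliability grows with n (SNR of the mean)
  base <- vectorize_upper(random_symmetric(R, 9, lo = 0, hi = 1))
  noisy <- function(n, seed) {
    set.seed(seed)
    lapply(1:n, function(i) {
      devectorize(tanh(base + rnorm(length(base), 0, 0.5)), R)
    })
  }
  r10 <- split_half_consistency(stack_from_matrices(noisy(10, 1)), "control",
                                n_iter = 200, seed = 2)$mean_r
  r20 <- split_half_consistency(stack_from_matrices(noisy(20, 1)), "control",
                                n_iter = 200, seed = 2)$mean_r
  expect_gt(r20, r10)
  # odd group sizes drop one subject per split
  r9 <- split_half_consistency(stack_from_matrices(noisy(9, 1)), "control",
                               n_iter = 50, seed = 3)
  expect_equal(r9$n_splits, 50)
  expect_error(split_half_consistency(stack_from_matrices(noisy(1, 1)), "control"),
               "group size")
})

test_that("group permutation test recovers a planted coupling difference", {
  d <- tiny_design(R = 30, n = c(control = 12, lTLE = 2, rTLE = 12), seed = 14)
  sim <- simulate_cohort(d, synthetic_atlas(30, 7), band_set = "theta")
  res <- group_permutation_test(sim$stack, "control", "rTLE", "theta",
                                "greater", n_perm = 1000, seed = 5)
  expect_lt(res$p_perm, 0.05)
  expect_gt(res$r_b, res$r_a)
  expect_true(res$p_perm > 0 && res$p_perm <= 1)
  expect_warning(group_permutation_test(sim$stack, "control", "rTLE", "theta",
                                        n_perm = 50, seed = 1), "n_perm")
})

test_that("a degenerate comparison of identical groups gives p near 0.5", {
  st <- null_cohort(R = 16, n_per_group = 10, seed = 8)
  res <- group_permutation_test(st, "control", "rTLE", "alpha", "greater",
                                n_perm = 600, seed = 4)
  expect_gt(res$p_perm, 0.05)
})

test_that("subnetwork battery localizes a planted DMN-beta decoupling", {
  d <- simulation_design(R = 68,
                         groups = list(siteA = c(control = 12, lTLE = 12, rTLE = 2)),
                         site_params = list(siteA = list(tr_s = 2, n_volumes = 100,
                                                         eeg_fs = 250,
                                                         n_segments = 10)),
                         dmn_decoupling = list(group = "lTLE", band = "beta",
                                               factor = 0.6),
                         seed = 91)
  sim <- simulate_cohort(d, band_set = c("alpha", "beta"))
  out <- subnetwork_coupling_tests(sim$stack, "control", "lTLE",
                                   bands = c("alpha", "beta"),
                                   direction = "less", n_perm = 1000, seed = 2)
  expect_equal(attr(out, "bonferroni"), 0.05 / (2 * 7))
  dmn_beta <- out$p_perm[out$icn == "default-mode" & out$band == "beta"]
  expect_equal(min(out$p_perm), dmn_beta)
  # ICN masks plus inter-ICN edges partition the edge set
  at <- sim$stack$atlas
  masks <- sapply(unique(at$icn_assignment), function(nw) edge_mask_icn(at, nw))
  expect_lte(max(rowSums(masks)), 1)
  inter <- sum(rowSums(masks) == 0)
  expect_equal(sum(colSums(masks)) + inter, n_edges(68))
})

test_that("Bonferroni thresholds of the battery reproduce the printed values", {
  th <- analysis_thresholds()
  expect_equal(th$band_bonferroni, 0.01)
  expect_equal(th$subnetwork_bonferroni, 0.05 / 35)
  expect_equal(round(th$subnetwork_bonferroni, 4), 0.0014)
  expect_equal(th$nbs_family, 0.05 / 6)
  expect_equal(round(th$nbs_family, 4), 0.0083)
})

test_that("distance-connectivity correlation is negative under exponential decay", {
  at <- tiny_atlas(20, 3)
  d <- edge_distances(at)
  conn <- devectorize(exp(-d / 50), 20)
  expect_lt(distance_fc_correlation(at, conn), 0)

  set.seed(6)
  conn_rand <- devectorize(runif(n_edges(68)), 68)
  expect_lt(abs(distance_fc_correlation(reference_atlas(), conn_rand)), 0.1)

  degen <- atlas_model(c("a", "b", "c"), c("L", "L", "R"),
                       matrix(1, 3, 3), rep("unassigned", 3))
  expect_error(distance_fc_correlation(degen, random_symmetric(3, 1)),
               "degenerate")
})

test_that("hemisphere masks partition edges and restricted analysis runs", {
  at <- reference_atlas()
  l <- edge_mask_hemisphere(at, "L")
  r <- edge_mask_hemisphere(at, "R")
  expect_equal(sum(l) + sum(r) + sum(!l & !r), n_edges(68))
  expect_equal(sum(l & r), 0)
  one_sided <- atlas_model(c("a", "b", "c"), c("L", "L", "L"),
                           matrix(rnorm(9), 3), rep("unassigned", 3))
  expect_error(edge_mask_hemisphere(one_sided, "R"), "no regions")

  d <- tiny_design(R = 20, n = c(control = 8, lTLE = 2, rTLE = 8), seed = 3)
  sim <- simulate_cohort(d, synthetic_atlas(20, 2), band_set = "beta")
  res <- hemisphere_restricted_analysis(sim$stack, "control", "rTLE", "L",
                                        bands = "beta", n_perm = 300, seed = 1)
  expect_s3_class(res$beta, "coupling_result")
  expect_gt(res$beta$r_b, res$beta$r_a)  # globally planted effect persists
})

test_that("sensitivity filters subset patients as documented", {
  d <- tiny_design(R = 10, n = c(control = 4, lTLE = 4, rTLE = 4), seed = 51)
  sim <- simulate_cohort(d, synthetic_atlas(10, 5), band_set = "alpha")
  st <- sim$stack
  ied <- sapply(st$subjects, function(s) s$ied_per_min)
  high <- sum(ied > 1, na.rm = TRUE)
  filt <- sensitivity_filters(st, "ied_le_1")
  expect_equal(length(filt$subjects), length(st$subjects) - high)

  hs <- sensitivity_filters(st, "hs_only")
  nhs <- sensitivity_filters(st, "non_hs_only")
  n_pat <- sum(sapply(st$subjects, function(s) s$group != "control"))
  n_ctrl <- length(st$subjects) - n_pat
  expect_equal((length(hs$subjects) - n_ctrl) + (length(nhs$subjects) - n_ctrl),
               n_pat)  # HS strata partition the patients
})

test_that("individual-level coupling orders groups like the group-mean analysis", {
  d <- tiny_design(R = 30, n = c(control = 10, lTLE = 2, rTLE = 10), seed = 63)
  sim <- simulate_cohort(d, synthetic_atlas(30, 11), band_set = "theta")
  res <- individual_coupling_test(sim$stack, "control", "rTLE", "theta", "greater")
  expect_gt(mean(res$r_b), mean(res$r_a))
  expect_equal(res$bonferroni_alpha, 0.01)
  # individual coupling is weaker than group-mean coupling (noise not averaged)
  gm <- sim$ground_truth$realized$group_mean
  expect_lt(mean(c(res$r_a, res$r_b)), mean(gm[c("control", "rTLE"), "theta"]))
})

test_that("bootstrap models recover a planted group effect and flag constants", {
  d <- tiny_design(R = 20, n = c(control = 10, lTLE = 10, rTLE = 10), seed = 29)
  sim <- simulate_cohort(d, synthetic_atlas(20, 9), band_set = "theta")
  # single-site cohort: the constant site column is excluded with a warning
  res <- suppressWarnings(
    bootstrap_coupling_models(sim$stack, "II", "theta", n_boot = 200,
                              n_perm_null = 99, direction = "greater",
                              seed = 17))
  expect_gt(res$coefficients["group"], 0)
  expect_lt(res$p_perm, 0.05)
  expect_true(all(c("age", "sex", "group") %in% res$covariates))
  expect_false("site" %in% res$covariates)
  # single-site cohort: the site covariate is constant and must be excluded
  expect_warning(bootstrap_coupling_models(sim$stack, "I", "theta", n_boot = 50,
                                           n_perm_null = 9, seed = 1),
                 "constant covariate")
  # model III uses clinical covariates of the patients
  res3 <- suppressWarnings(
    bootstrap_coupling_models(sim$stack, "III", "theta", n_boot = 100,
                              n_perm_null = 19, direction = "greater", seed = 23))
  expect_true(all(c("duration", "is_hs", "ied") %in% res3$covariates))
})
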
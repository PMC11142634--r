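#' Simulation design for a two-site, three-group multimodal cohort
#'
#' Describes the study geometry the generator emulates: two acquisition sites
#' with different fMRI repetition times and EEG sampling rates, three groups
#' (controls, left and right temporal lobe epilepsy), 68 cortical regions,
#' and per-(group, band) targets for the cross-modal spatial correlation
#' between the group-mean EEG and fMRI connectomes. One group/band pair can
#' additionally have its coupling attenuated on intra-default-mode-network
#' edges only (`dmn_decoupling`), emulating a locally confined decoupling.
#'
#' Defaults encode the reference study conditions: 17 controls, 16 lTLE and
#' 17 rTLE subjects split over the two sites; coupling targets 0.40
#' (controls/lTLE) and 0.55 (rTLE) in delta-beta, 0.33 in gamma for all
#' groups; lTLE-beta intra-DMN coupling attenuated by a factor 0.75.
#'
#' @param R number of regions (68 for the reference atlas).
#' @param groups named list, one element per site, each a named integer
#'   vector of subject counts for `control`, `lTLE`, `rTLE`.
#' @param coupling_target numeric matrix `groups x bands` of target
#'   correlations in \[-1, 1\] (rows `control,lTLE,rTLE`, columns
#'   `delta..gamma`).
#' @param dmn_decoupling list with `group`, `band` and multiplicative
#'   `factor` applied to the coupling of intra-DMN edges, or `NULL`.
#' @param site_params named list per site: `tr_s`, `n_volumes`, `eeg_fs`,
#'   `n_segments`.
#' @param noise_sd subject-level edge noise SD on the latent (pre-squash)
#'   scale, applied to both modalities.
#' @param lambda distance-decay rate of the latent topology (1/mm).
#' @param eeg_mixing instantaneous (zero-lag) mixing strength of the EEG
#'   background noise, the volume-conduction surrogate.
#' @param seed master seed; every random draw in the generator flows from it.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(R = 68,
                              groups = list(
                                site256 = c(control = 11, lTLE = 10, rTLE = 11),
                                site64 = c(control = 6, lTLE = 6, rTLE = 6)),
                              coupling_target = default_coupling_targets(),
                              dmn_decoupling = list(group = "lTLE", band = "beta",
                                                    factor = 0.75),
                              site_params = list(
                                site256 = list(tr_s = 2.0, n_volumes = 150,
                                               eeg_fs = 1000, n_segments = 150),
                                site64 = list(tr_s = 3.6, n_volumes = 350,
                                              eeg_fs = 250, n_segments = 350)),
                              noise_sd = 0.6, lambda = 0.02,
                              eeg_mixing = 0.5, seed = 20240101) {
  stopifnot(all(abs(coupling_target) <= 1), lambda >= 0, noise_sd >= 0)
  if (!identical(sort(names(groups)), sort(names(site_params)))) {
    stop("`groups` and `site_params` must name the same sites", call. = FALSE)
  }
  for (g in groups) {
    if (any(g < 1)) stop("every group needs at least one subject per site", call. = FALSE)
    if (!all(GROUP_LEVELS %in% names(g))) {
      stop("each site must specify control, lTLE and rTLE counts", call. = FALSE)
    }
  }
  for (sp in site_params) {
    if (sp$tr_s <= 0) stop("TR must be positive", call. = FALSE)
  }
  structure(list(R = as.integer(R), groups = groups,
                 coupling_target = coupling_target,
                 dmn_decoupling = dmn_decoupling, site_params = site_params,
                 noise_sd = noise_sd, lambda = lambda,
                 eeg_mixing = eeg_mixing, seed = as.integer(seed)),
            class = "simulation_design")
}

#' @rdname simulation_design
#' @export
default_coupling_targets <- function() {
  m <- rbind(control = c(0.40, 0.40, 0.40, 0.40, 0.33),
             lTLE = c(0.40, 0.40, 0.40, 0.40, 0.33),
             rTLE = c(0.55, 0.55, 0.55, 0.55, 0.33))
  colnames(m) <- EEG_BANDS
  m
}

#' Total subjects per group across sites
#' @param design a [simulation_design()].
#' @keywords internal
group_totals <- function(design) {
  Reduce(`+`, lapply(design$groups, function(g) g[GROUP_LEVELS]))
}

#' Synthetic atlas for arbitrary region counts
#'
#' Random centroids in a 140 mm cube, hemispheres split half/half, ICN tags
#' assigned round-robin over the seven networks. Used when simulating at
#' region counts other than the bundled 68-region atlas.
#'
#' @param R number of regions.
#' @param seed RNG seed.
#' @return an [atlas_model()].
#' @export
synthetic_atlas <- function(R, seed = 1) {
  with_seed(seed, {
    atlas_model(region_labels = sprintf("region%02d", seq_len(R)),
                hemisphere = rep(c("L", "R"), length.out = R),
                centroid_mm = matrix(stats::runif(R * 3, -70, 70), R, 3),
                icn_assignment = rep(ICN_LEVELS[1:7], length.out = R))
  })
}

#' Distance-decaying latent edge topology
#'
#' The shared spatial pattern both modalities' connectomes are built from:
#' `w_ij = exp(-lambda * d_ij)` plus a small Gaussian perturbation, rescaled
#' to \[0, 1\], where `d_ij` is the Euclidean centroid distance. A positive
#' `lambda` gives the negative distance-connectivity correlation real
#' connectomes show.
#'
#' @param atlas an [atlas_model()] with centroids.
#' @param lambda decay rate (1/mm), `>= 0`.
#' @param seed RNG seed for the perturbation.
#' @param perturb_sd SD of the Gaussian perturbation (0 disables it).
#' @return numeric edge vector in canonical order, values in \[0, 1\].
#' @export
latent_topology <- function(atlas, lambda, seed = NULL, perturb_sd = 0.1) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  d <- edge_distances(atlas)
  w <- exp(-lambda * d)
  if (perturb_sd > 0) {
    w <- w + with_seed(seed, stats::rnorm(length(w), 0, perturb_sd))
  }
  rng <- range(w)
  if (rng[2] > rng[1]) w <- (w - rng[1]) / (rng[2] - rng[1])
  w
}

#' Calibrate the latent mixture weight for a coupling target
#'
#' The generator realizes a target correlation `rho` between group-mean EEG
#' and fMRI edge vectors by mixing a shared latent into the EEG pattern with
#' weight `w`. On the pre-squash scale, group averaging shrinks the subject
#' noise variance to `noise_sd^2 / n`, giving
#' `rho = w / (1 + noise_sd^2 / n)`; the routine inverts this. A required
#' weight above 1 (large `|rho|` with high noise) is a calibration failure.
#'
#' @param rho target group-mean coupling in \[-1, 1\].
#' @param noise_sd subject-level edge noise SD.
#' @param n subjects in the group.
#' @return mixture weight in \[-1, 1\].
#' @export
calibrate_mixture <- function(rho, noise_sd, n) {
  stopifnot(abs(rho) <= 1, n >= 1)
  w <- rho * (1 + noise_sd^2 / n)
  if (abs(w) > 1) {
    stop(sprintf(paste0("calibration failure: target rho = %.2f unreachable at ",
                        "noise_sd = %.2f, n = %d (required weight %.3f > 1)"),
                 rho, noise_sd, n, abs(w)), call. = FALSE)
  }
  w
}

#' Ground truth of a simulated cohort
#'
#' Latent topology, band-specific latents and coupling targets fixed by
#' `(design, seed)`; regeneration from the same design is bit-identical.
#'
#' @param design a [simulation_design()].
#' @param atlas the atlas to simulate on; defaults to [reference_atlas()]
#'   when `design$R == 68`, otherwise a [synthetic_atlas()].
#' @return list with `latent`, `band_latents` (E x 5), `targets`, `atlas`,
#'   `dmn_mask`, `seed`.
#' @export
make_ground_truth <- function(design, atlas = NULL) {
  if (is.null(atlas)) {
    atlas <- if (design$R == 68) reference_atlas() else
      synthetic_atlas(design$R, seed = child_seed(design$seed, 1))
  }
  stopifnot(n_regions(atlas) == design$R)
  E <- n_edges(design$R)
  latent <- latent_topology(atlas, design$lambda,
                            seed = child_seed(design$seed, 2), perturb_sd = 0.1)
  band_latents <- with_seed(child_seed(design$seed, 3), {
    matrix(stats::rnorm(E * length(EEG_BANDS)), E, length(EEG_BANDS),
           dimnames = list(NULL, EEG_BANDS))
  })
  list(latent = latent, band_latents = band_latents,
       targets = design$coupling_target, atlas = atlas,
       dmn_mask = edge_mask_icn(atlas, "default-mode"), seed = design$seed)
}

# standardized latent (mean 0, sd 1 over edges)
z_latent <- function(latent) as.vector(scale(latent))

#' Sample one subject's multimodal connectomes
#'
#' fMRI edges are the shared latent plus subject noise, squashed through
#' `tanh(0.2 + 0.3 x)` into the Pearson range; EEG band edges are a
#' calibrated mixture of the same latent and an independent band latent plus
#' subject noise, squashed through `plogis(-1.5 + 0.5 x)` into the ciCoh
#' range. The mixture weight is set by [calibrate_mixture()] so the realized
#' group-mean coupling matches the design target; intra-DMN edges of a
#' flagged (group, band) have their weight multiplied by the decoupling
#' factor.
#'
#' @param design a [simulation_design()].
#' @param ground_truth output of [make_ground_truth()].
#' @param group group label.
#' @param seed per-subject seed.
#' @param subject_id id stored on the connectomes.
#' @param band_set EEG bands to generate.
#' @return named list of [connectome()]s (`fmri`, `eeg.delta`, ...).
#' @export
sample_subject_connectomes <- function(design, ground_truth, group, seed,
                                       subject_id = "synthetic",
                                       band_set = EEG_BANDS) {
  group <- match.arg(group, GROUP_LEVELS)
  zL <- z_latent(ground_truth$latent)
  E <- length(zL)
  n_group <- group_totals(design)[group]
  sd_n <- design$noise_sd
  with_seed(seed, {
    f_pre <- zL + stats::rnorm(E, 0, sd_n)
    fmri <- devectorize(tanh(0.2 + 0.3 * f_pre), design$R)
    out <- list(fmri = connectome(fmri, "fmri", subject_id = subject_id,
                                  n_samples_used = 1L))
    for (b in band_set) {
      w <- calibrate_mixture(ground_truth$targets[group, b], sd_n, n_group)
      wv <- rep(w, E)
      dd <- design$dmn_decoupling
      if (!is.null(dd) && dd$group == group && dd$band == b) {
        wv[ground_truth$dmn_mask] <- w * dd$factor
      }
      e_pre <- wv * zL + sqrt(1 - wv^2) * ground_truth$band_latents[, b] +
        stats::rnorm(E, 0, sd_n)
      eeg <- devectorize(stats::plogis(-1.5 + 0.5 * e_pre), design$R)
      out[[connectome_key("eeg", b)]] <-
        connectome(eeg, "eeg", band = b, subject_id = subject_id,
                   n_samples_used = 1L)
    }
    out
  })
}

#' Simulate an in-memory cohort of connectomes
#'
#' Draws metadata (age ~ Uniform(18, 60); patients: duration ~ Uniform(1, 30)
#' years, hippocampal sclerosis ~ Bernoulli(0.5), interictal-discharge rate ~
#' Exponential(mean 0.3)/min; sex ~ Bernoulli(0.5)) and per-subject
#' connectomes for every site and group in the design.
#'
#' @param design a [simulation_design()].
#' @param atlas optional atlas (see [make_ground_truth()]).
#' @param band_set EEG bands to generate.
#' @return list with `stack` (a [cohort_stack()]) and `ground_truth`; the
#'   ground truth gains a `realized` element with the per-(group, band)
#'   group-mean coupling and per-subject couplings actually attained.
#' @export
simulate_cohort <- function(design, atlas = NULL, band_set = EEG_BANDS) {
  gt <- make_ground_truth(design, atlas)
  subjects <- list()
  k <- 0L
  for (site in names(design$groups)) {
    for (g in GROUP_LEVELS) {
      for (s in seq_len(design$groups[[site]][g])) {
        k <- k + 1L
        id <- sprintf("sub-%03d", k)
        meta_seed <- child_seed(design$seed, 1000L + k)
        meta <- with_seed(meta_seed, {
          patient <- g != "control"
          list(age = stats::runif(1, 18, 60),
               sex = if (stats::runif(1) < 0.5) "F" else "M",
               duration = if (patient) stats::runif(1, 1, 30) else NA_real_,
               is_hs = if (patient) stats::runif(1) < 0.5 else NA,
               ied = if (patient) stats::rexp(1, rate = 1 / 0.3) else NA_real_)
        })
        conn <- sample_subject_connectomes(design, gt, g,
                                           seed = child_seed(design$seed, 2000L + k),
                                           subject_id = id, band_set = band_set)
        subjects[[k]] <- subject_record(id, g, meta$age, meta$sex, site,
                                        duration_years = meta$duration,
                                        is_hs = meta$is_hs,
                                        ied_per_min = meta$ied,
                                        connectomes = conn)
      }
    }
  }
  stack <- cohort_stack(subjects, gt$atlas)
  gt$realized <- realized_coupling(stack, band_set)
  list(stack = stack, ground_truth = gt)
}

# per-(group, band) group-mean coupling and per-subject couplings
realized_coupling <- function(stack, band_set = EEG_BANDS) {
  groups <- unique(stack_groups(stack))
  fm <- stack_edges(stack, "fmri")
  grp <- stack_groups(stack)
  group_mean <- sapply(band_set, function(b) {
    ee <- stack_edges(stack, "eeg", b)
    sapply(groups, function(g) {
      stats::cor(colMeans(ee[grp == g, , drop = FALSE]),
                 colMeans(fm[grp == g, , drop = FALSE]))
    })
  })
  if (is.null(dim(group_mean))) {
    group_mean <- matrix(group_mean, nrow = length(groups),
                         dimnames = list(groups, band_set))
  } else {
    rownames(group_mean) <- groups
  }
  per_subject <- sapply(band_set, function(b) {
    ee <- stack_edges(stack, "eeg", b)
    vapply(seq_len(nrow(ee)), function(i) stats::cor(ee[i, ], fm[i, ]), numeric(1))
  })
  list(group_mean = group_mean, per_subject = per_subject)
}

#' Write a simulated cohort to disk
#'
#' Materializes a cohort in the package's file dialects: `metadata.tsv`, one
#' TSV connectome (+ JSON sidecar) per subject/modality/band under
#' `connectomes/` -- or, in time-series mode, per-subject region time series,
#' motion and confound tables under `timeseries/` -- plus
#' `ground_truth.json`.
#'
#' @param design a [simulation_design()].
#' @param out_dir writable output directory (created if missing).
#' @param mode `"connectomes"` (default) or `"timeseries"`.
#' @param band_set EEG bands to generate.
#' @return the in-memory cohort, invisibly (as from [simulate_cohort()]).
#' @export
generate_cohort <- function(design, out_dir, mode = c("connectomes", "timeseries"),
                            band_set = EEG_BANDS) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(design, band_set = band_set)
  write_metadata(sim$stack, file.path(out_dir, "metadata.tsv"))
  if (mode == "connectomes") {
    cdir <- file.path(out_dir, "connectomes")
    dir.create(cdir, showWarnings = FALSE)
    for (s in sim$stack$subjects) {
      for (key in names(s$connectomes)) {
        fn <- file.path(cdir, sprintf("%s_%s.tsv", s$subject_id,
                                      gsub("\\.", "_", key)))
        write_connectome(s$connectomes[[key]], fn)
      }
    }
  } else {
    tdir <- file.path(out_dir, "timeseries")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_along(sim$stack$subjects)) {
      s <- sim$stack$subjects[[i]]
      ts <- sample_region_timeseries(design, s,
                                     seed = child_seed(design$seed, 3000L + i))
      wt <- function(x, name) {
        utils::write.table(format(x, digits = 8, trim = TRUE),
                           file.path(tdir, sprintf("%s_%s.tsv", s$subject_id, name)),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
      wt(ts$fmri$data, "fmri")
      wt(ts$motion, "motion")
      wt(ts$fmri$confounds, "confounds")
      wt(ts$eeg$data, "eeg")
    }
  }
  gt <- sim$ground_truth
  jsonlite::write_json(list(seed = gt$seed, latent = gt$latent,
                            band_latents = gt$band_latents,
                            targets = gt$targets,
                            realized_group_mean = gt$realized$group_mean),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Simulate region-level time series for one subject
#'
#' Exercises the full connectivity stages. fMRI: multivariate Gaussian
#' volumes whose correlation matches the subject's target fMRI connectome,
#' plus a linear drift and a 0.12 Hz physiological component (both removed by
#' the band-pass); motion parameters are smooth random walks with occasional
#' spikes so that framewise-displacement scrubbing triggers. EEG: per band, a
#' narrow-band common driver shared with a fixed 90-degree phase lag by
#' designated region pairs (so lagged coherency is positive there), plus
#' instantaneously mixed background noise -- the volume-conduction surrogate
#' that corrected imaginary coherency must suppress.
#'
#' @param design a [simulation_design()].
#' @param subject a [subject_record()] with a target `fmri` connectome and a
#'   `site` present in the design.
#' @param seed RNG seed.
#' @param lagged_edges data.frame with columns `i`, `j`, `band`, `lag_deg`,
#'   `amplitude` designating driver-coupled region pairs; `NULL` gives one
#'   90-degree driver per band on consecutive region pairs; a zero-row frame
#'   disables drivers (zero-lag mixing only).
#' @param driver_amplitude default amplitude for auto-generated drivers.
#' @param noise_amplitude SD of the EEG background noise.
#' @return list with `fmri` (fields `data` R x T, `tr_s`, `confounds` T x 9),
#'   `motion` (T x 6), and `eeg` (fields `data` R x N, `fs`,
#'   `segment_len_s`, `units = "uV"`).
#' @export
sample_region_timeseries <- function(design, subject, seed,
                                     lagged_edges = NULL,
                                     driver_amplitude = 1.5,
                                     noise_amplitude = 1) {
  sp <- design$site_params[[subject$site]]
  if (is.null(sp)) stop("subject site not present in design", call. = FALSE)
  if (sp$n_volumes < 10) stop("need at least 10 fMRI volumes", call. = FALSE)
  R <- design$R
  if (is.null(lagged_edges)) {
    pairs <- matrix(((seq_len(2 * length(EEG_BANDS)) - 1L) %% R) + 1L, ncol = 2,
                    byrow = TRUE)
    lagged_edges <- data.frame(i = pairs[, 1], j = pairs[, 2], band = EEG_BANDS,
                               lag_deg = 90, amplitude = driver_amplitude,
                               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    ## ---- fMRI ----
    TT <- sp$n_volumes
    target <- subject$connectomes$fmri$values
    sigma <- target
    diag(sigma) <- 1
    ev <- eigen(sigma, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-4)
    sigma <- ev$vectors %*% (ev$values * t(ev$vectors))
    dsc <- 1 / sqrt(diag(sigma))
    sigma <- sigma * tcrossprod(dsc)
    bold <- t(MASS::mvrnorm(TT, mu = rep(0, R), Sigma = sigma))
    tsec <- (seq_len(TT) - 1) * sp$tr_s
    drift <- outer(stats::rnorm(R, 0, 0.5), tsec / max(tsec))
    physio <- outer(stats::rnorm(R, 0, 0.4),
                    rep(1, TT)) * sin(2 * pi * 0.12 * matrix(tsec, R, TT, byrow = TRUE) +
                                      stats::rnorm(R, 0, pi))
    fmri_data <- bold + drift + physio
    ## motion: smooth walks + occasional spikes
    motion <- sapply(c(rep(0.02, 3), rep(4e-4, 3)), function(s) {
      cumsum(stats::rnorm(TT, 0, s))
    })
    spikes <- which(stats::runif(TT) < 0.02)
    for (t in spikes) {
      col <- sample(3, 1)
      motion[t:TT, col] <- motion[t:TT, col] + stats::runif(1, 0.6, 1.5)
    }
    confounds <- cbind(csf = stats::rnorm(TT), wm = stats::rnorm(TT),
                       motion, gray = colMeans(fmri_data))
    ## ---- EEG ----
    L <- round(sp$eeg_fs * sp$tr_s)
    N <- sp$n_segments * L
    tt <- (seq_len(N) - 1) / sp$eeg_fs
    noise <- matrix(stats::rnorm(R * N, 0, noise_amplitude), R, N)
    mixmat <- diag(R) + design$eeg_mixing * matrix(stats::runif(R * R), R, R) / R * 2
    eeg <- mixmat %*% noise
    bands <- band_definitions()
    for (k in seq_len(nrow(lagged_edges))) {
      le <- lagged_edges[k, ]
      bd <- bands[bands$name == le$band, ]
      f <- (bd$f_lo + bd$f_hi) / 2
      phi <- stats::runif(1, 0, 2 * pi)
      am <- 1 + 0.3 * sin(2 * pi * 0.2 * tt + stats::runif(1, 0, 2 * pi))
      eeg[le$i, ] <- eeg[le$i, ] + le$amplitude * am * cos(2 * pi * f * tt + phi)
      eeg[le$j, ] <- eeg[le$j, ] + le$amplitude * am *
        cos(2 * pi * f * tt + phi - le$lag_deg * pi / 180)
    }
    eeg <- eeg * 20  # microvolt scale
    list(fmri = list(data = fmri_data, tr_s = sp$tr_s, confounds = confounds),
         motion = motion,
         eeg = list(data = eeg, fs = sp$eeg_fs, segment_len_s = sp$tr_s,
                    units = "uV"))
  })
}
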
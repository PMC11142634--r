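# shared fixture builders; everything is generated in code at test time

random_symmetric <- function(R, seed = 1, lo = -0.9, hi = 0.9) {
  set.seed(seed)
  m <- matrix(runif(R * R, lo, hi), R, R)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

tiny_atlas <- function(R = 8, seed = 1) synthetic_atlas(R, seed)

# small one-site design for fast cohort simulation
tiny_design <- function(R = 20, n = c(control = 8, lTLE = 6, rTLE = 8),
                        noise_sd = 0.6, seed = 42, ...) {
  simulation_design(R = R, groups = list(siteA = n),
                    site_params = list(siteA = list(tr_s = 2, n_volumes = 120,
                                                    eeg_fs = 250,
                                                    n_segments = 30)),
                    noise_sd = noise_sd, seed = seed, ...)
}

# cohort where the two "groups" are exchangeable (identical generative law)
null_cohort <- function(R = 20, n_per_group = 10, seed = 1) {
  d <- tiny_design(R = R, n = c(control = n_per_group, lTLE = 2,
                                rTLE = n_per_group),
                   seed = seed)
  d$coupling_target["rTLE", ] <- d$coupling_target["control", ]
  d$dmn_decoupling <- NULL
  simulate_cohort(d, atlas = synthetic_atlas(R, seed = 99))$stack
}

# subject records holding given connectome matrices (fmri + one eeg band)
stack_from_matrices <- function(fmri_list, eeg_list = NULL, band = "alpha",
                                groups = NULL, atlas = NULL) {
  R <- nrow(fmri_list[[1]])
  atlas <- atlas %||% synthetic_atlas(R, seed = 3)
  groups <- groups %||% rep("control", length(fmri_list))
  subs <- lapply(seq_along(fmri_list), function(i) {
    conn <- list(fmri = connectome(fmri_list[[i]], "fmri",
                                   subject_id = paste0("s", i)))
    if (!is.null(eeg_list)) {
      conn[[paste0("eeg.", band)]] <- connectome(eeg_list[[i]], "eeg",
                                                 band = band,
                                                 subject_id = paste0("s", i))
    }
    dur <- if (groups[i] == "control") NA_real_ else 5
    hs <- if (groups[i] == "control") NA else TRUE
    ied <- if (groups[i] == "control") NA_real_ else 0.2
    subject_record(paste0("s", i), groups[i], age = 30 + (i * 7) %% 23,
                   sex = c("F", "M")[1 + i %% 2], site = "siteA",
                   duration_years = dur, is_hs = hs, ied_per_min = ied,
                   connectomes = conn)
  })
  cohort_stack(subs, atlas)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
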
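#' Bootstrap-of-group-averages linear models of coupling
#'
#' Quantifies how demographic/clinical covariates relate to the group-mean
#' EEG-fMRI coupling. Each bootstrap iteration resamples subjects with
#' replacement from the pooled model population, averages their connectomes,
#' and records the resulting coupling `r` together with the
#' iteration-averaged covariates (mean age, sex ratio, group fraction, site
#' fraction; model III adds mean epilepsy duration, hippocampal-sclerosis
#' fraction and mean interictal-discharge rate). An ordinary least-squares
#' model of `r` on the iteration-averaged covariates is then fit across
#' iterations.
#'
#' Model populations: I = controls + lTLE (group codes lTLE = 1), II =
#' controls + rTLE (rTLE = 1), III = lTLE + rTLE patients (rTLE = 1) with the
#' clinical covariates added. Sex is coded M = 1, site by the second site
#' label = 1; covariates are left on their natural scales.
#'
#' Significance of a covariate is assessed against a permuted-label null:
#' the target covariate is permuted across subjects, the whole bootstrap
#' distribution rebuilt and the model refit, `n_perm_null` times; the p-value
#' compares the observed t to the null t distribution with the add-one
#' estimator.
#'
#' @param stack a [cohort_stack()].
#' @param model_id `"I"`, `"II"` or `"III"`.
#' @param band EEG band of the coupling.
#' @param n_boot bootstrap iterations per distribution.
#' @param n_perm_null permutations of the target covariate for the null.
#' @param target covariate whose significance is tested (default `"group"`).
#' @param direction `"greater"`, `"less"` or `"two.sided"` comparison of the
#'   observed t to the null t distribution.
#' @param seed RNG seed.
#' @return object of class `bootstrap_model_result`: list with
#'   `coefficients`, `t_values`, `p_perm` (target covariate), `r` (bootstrap
#'   coupling distribution), `model_id`, `covariates`, `n_boot`,
#'   `n_perm_null`, `seed`.
#' @export
bootstrap_coupling_models <- function(stack, model_id = c("I", "II", "III"),
                                      band = "alpha", n_boot = 1000,
                                      n_perm_null = 1000, target = "group",
                                      direction = c("two.sided", "greater", "less"),
                                      seed = NULL) {
  model_id <- match.arg(model_id)
  direction <- match.arg(direction)
  groups <- switch(model_id, I = c("control", "lTLE"), II = c("control", "rTLE"),
                   III = c("lTLE", "rTLE"))
  subs <- stack_subjects(stack, groups)
  n <- length(subs)
  Se <- stack_edges(stack, "eeg", band, groups = groups)
  Sf <- stack_edges(stack, "fmri", groups = groups)
  sites <- sort(unique(vapply(subs, function(s) s$site, character(1))))
  X <- data.frame(
    age = vapply(subs, function(s) s$age, numeric(1)),
    sex = as.numeric(vapply(subs, function(s) s$sex, character(1)) == "M"),
    group = as.numeric(vapply(subs, function(s) s$group, character(1)) == groups[2]),
    site = as.numeric(vapply(subs, function(s) s$site, character(1)) == sites[length(sites)]))
  if (model_id == "III") {
    X$duration <- vapply(subs, function(s) s$duration_years, numeric(1))
    X$is_hs <- as.numeric(vapply(subs, function(s) isTRUE(s$is_hs), logical(1)))
    X$ied <- vapply(subs, function(s) s$ied_per_min, numeric(1))
    if (anyNA(X)) stop("model III requires complete clinical covariates", call. = FALSE)
  }
  const <- vapply(X, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    warning(sprintf("constant covariate(s) excluded: %s",
                    paste(names(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  if (!target %in% names(X)) {
    stop(sprintf("target covariate '%s' not in the model", target), call. = FALSE)
  }
  Xm <- as.matrix(X)

  boot_fit <- function(Xmat, boot_seed) {
    for (attempt in 1:50) {
      draw <- with_seed(child_seed(boot_seed, attempt), {
        t(stats::rmultinom(n_boot, size = n, prob = rep(1 / n, n)))
      })
      r <- rowwise_cor(draw %*% Se, draw %*% Sf)
      Xbar <- (draw %*% Xmat) / n
      D <- cbind(1, Xbar)
      qrd <- qr(D)
      if (qrd$rank == ncol(D)) {
        beta <- qr.coef(qrd, r)
        res <- r - D %*% beta
        sigma2 <- sum(res^2) / (n_boot - ncol(D))
        se <- sqrt(diag(chol2inv(qr.R(qrd))) * sigma2)
        tv <- beta / se
        names(beta) <- names(tv) <- c("(intercept)", colnames(Xmat))
        return(list(coefficients = beta, t = tv, r = r, xbar = Xbar))
      }
    }
    stop("rank-deficient bootstrap design after 50 redraws", call. = FALSE)
  }

  obs <- boot_fit(Xm, child_seed(seed, 1))
  t_obs <- obs$t[target]
  t_null <- vapply(seq_len(n_perm_null), function(k) {
    Xp <- Xm
    Xp[, target] <- with_seed(child_seed(seed, 100L + k),
                              Xp[sample.int(n), target])
    boot_fit(Xp, child_seed(seed, 100000L + k))$t[target]
  }, numeric(1))
  p <- switch(direction,
              two.sided = (1 + sum(abs(t_null) >= abs(t_obs))) / (1 + n_perm_null),
              greater = (1 + sum(t_null >= t_obs)) / (1 + n_perm_null),
              less = (1 + sum(t_null <= t_obs)) / (1 + n_perm_null))
  structure(list(model_id = model_id, band = band,
                 coefficients = obs$coefficients, t_values = obs$t,
                 target = target, t_obs = unname(t_obs), p_perm = p,
                 direction = direction, r = obs$r,
                 covariates = colnames(Xm), n_boot = n_boot,
                 n_perm_null = n_perm_null, seed = seed),
            class = "bootstrap_model_result")
}

#' @export
print.bootstrap_model_result <- function(x, ...) {
  cat(sprintf("<bootstrap_model_result> model %s, band %s: mean r = %.3f (n_boot = %d)\n",
              x$model_id, x$band, mean(x$r), x$n_boot))
  print(round(rbind(coef = x$coefficients, t = x$t_values), 4))
  cat(sprintf("target '%s': t = %.3f, permutation p = %.4g (%s, %d perms)\n",
              x$target, x$t_obs, x$p_perm, x$direction, x$n_perm_null))
  invisible(x)
}
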
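#' Edge-wise general linear model t-statistics
#'
#' Mass-univariate OLS fits of each edge's connectivity on a group indicator
#' plus nuisance covariates; returns the t-statistic of the group
#' coefficient per edge.
#'
#' @param response `n x E` subjects-by-edges matrix (Fisher-z fMRI or raw
#'   EEG band connectivity).
#' @param group numeric group indicator of length `n`.
#' @param nuisance optional `n x K` matrix of nuisance covariates (age, sex,
#'   site).
#' @return numeric edge vector of t-statistics.
#' @export
edgewise_glm <- function(response, group, nuisance = NULL) {
  response <- as.matrix(response)
  n <- nrow(response)
  X <- cbind(intercept = 1, group = group)
  if (!is.null(nuisance)) X <- cbind(X, as.matrix(nuisance))
  if (n <= ncol(X) + 2) stop("need n_subjects > n_covariates + 2", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design (collinear covariates?)", call. = FALSE)
  }
  glm_group_t(response, X, 2L)
}

# batched t-statistics of X column `cidx` over all response columns
glm_group_t <- function(Y, X, cidx) {
  xtxi <- chol2inv(chol(crossprod(X)))
  B <- xtxi %*% crossprod(X, Y)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (nrow(Y) - ncol(X))
  as.numeric(B[cidx, ] / sqrt(sigma2 * xtxi[cidx, cidx]))
}

#' Connected components of suprathreshold edges
#'
#' Keeps edges with `t > threshold` (one-sided) and finds the connected
#' components of the region graph they induce, by union-find. Component size
#' is its edge count (the extent statistic).
#'
#' @param t_map edge vector of t-statistics in canonical order.
#' @param threshold first-level threshold `T`.
#' @param R number of regions.
#' @return list of components, each a list with `edges` (indices into the
#'   edge vector), `regions`, and `size` (edge count); empty list when no
#'   edge is suprathreshold.
#' @export
suprathreshold_components <- function(t_map, threshold, R) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  sel <- which(t_map > threshold)
  if (!length(sel)) return(list())
  idx <- edge_index(R)[sel, , drop = FALSE]
  parent <- seq_len(R)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(idx))) {
    ri <- find(idx[k, 1])
    rj <- find(idx[k, 2])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(idx[, 1], find, integer(1))
  comps <- split(seq_along(sel), roots)
  out <- lapply(comps, function(members) {
    e <- sel[members]
    list(edges = e, regions = sort(unique(as.vector(edge_index(R)[e, ]))),
         size = length(e))
  })
  names(out) <- NULL
  out[order(-vapply(out, `[[`, integer(1), "size"))]
}

#' Network-based statistics for monomodal group differences
#'
#' Edge-wise GLM with group as the regressor of interest and age, sex, site
#' as nuisance covariates, followed by family-wise correction on the extent
#' of suprathreshold connected components: the observed component sizes are
#' compared to the permutation null of the maximal component size under
#' group-label shuffling (nuisance rows held fixed). fMRI connectivity is
#' Fisher z-transformed before fitting. When run as the six-model battery
#' (fMRI + five EEG bands) the family threshold is `alpha / 6`.
#'
#' @param stack a [cohort_stack()].
#' @param modality `"fmri"` or `"eeg"`.
#' @param band EEG band (ignored for fMRI).
#' @param group_a,group_b group labels; the group indicator codes
#'   `group_b = 1`.
#' @param contrast `"b_gt_a"` tests `group_b > group_a` edges, `"a_gt_b"` the
#'   reverse (one-sided `t > T`).
#' @param t_threshold first-level threshold (default 2).
#' @param n_perm label permutations (warning below 100).
#' @param alpha corrected significance threshold (default `0.05 / 6`, the
#'   six-model battery).
#' @param seed RNG seed.
#' @return object of class `nbs_result`: list with `t_map`, `components`
#'   (each gaining `p_corrected`), `max_size`, `null_max` (the permutation
#'   null), `significant` (components with `p_corrected < alpha`), plus the
#'   test parameters.
#' @export
nbs <- function(stack, modality = "fmri", band = "none", group_a, group_b,
                contrast = c("b_gt_a", "a_gt_b"), t_threshold = 2,
                n_perm = 5000, alpha = 0.05 / 6, seed = NULL) {
  contrast <- match.arg(contrast)
  if (n_perm < 100) warning("n_perm < 100: permutation p will be coarse")
  subs <- stack_subjects(stack, c(group_a, group_b))
  grp <- stack_groups(stack, c(group_a, group_b))
  Y <- stack_edges(stack, modality, band, groups = c(group_a, group_b))
  if (modality == "fmri") Y <- atanh(pmin(pmax(Y, -(1 - 1e-7)), 1 - 1e-7))
  sites <- sort(unique(vapply(subs, function(s) s$site, character(1))))
  nuis <- cbind(age = vapply(subs, function(s) s$age, numeric(1)),
                sex = as.numeric(vapply(subs, function(s) s$sex, character(1)) == "M"),
                site = as.numeric(vapply(subs, function(s) s$site, character(1)) ==
                                  sites[length(sites)]))
  nuis <- nuis[, apply(nuis, 2, stats::var) > 0, drop = FALSE]
  g <- as.numeric(grp == group_b)
  sgn <- if (contrast == "b_gt_a") 1 else -1
  R <- n_regions(stack$atlas)
  X <- cbind(1, g, nuis)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: group indicator collinear with nuisance covariates",
         call. = FALSE)
  }
  t_obs <- sgn * glm_group_t(Y, X, 2L)
  comps <- suprathreshold_components(t_obs, t_threshold, R)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      Xp <- X
      repeat {  # a shuffled binary label can collide with a binary nuisance
        Xp[, 2] <- g[sample.int(length(g))]
        if (qr(Xp)$rank == ncol(Xp)) break
      }
      tp <- sgn * glm_group_t(Y, Xp, 2L)
      cp <- suprathreshold_components(tp, t_threshold, R)
      if (length(cp)) max(vapply(cp, `[[`, integer(1), "size")) else 0L
    }, integer(1))
  })
  comps <- lapply(comps, function(cc) {
    cc$p_corrected <- (1 + sum(null_max >= cc$size)) / (1 + n_perm)
    cc
  })
  sig <- Filter(function(cc) cc$p_corrected < alpha, comps)
  structure(list(t_map = t_obs, modality = modality, band = band,
                 groups = c(group_a, group_b), contrast = contrast,
                 t_threshold = t_threshold, components = comps,
                 max_size = if (length(comps)) comps[[1]]$size else 0L,
                 null_max = null_max, significant = sig,
                 alpha = alpha, n_perm = n_perm, seed = seed),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s%s %s vs %s (%s): %d component(s), max size %d\n",
              x$modality, if (x$band != "none") paste0("-", x$band) else "",
              x$groups[1], x$groups[2], x$contrast, length(x$components),
              x$max_size))
  if (length(x$components)) {
    p <- vapply(x$components, `[[`, numeric(1), "p_corrected")
    cat(sprintf("  smallest corrected p = %.4g (alpha = %.4g): %d significant\n",
                min(p), x$alpha, length(x$significant)))
  } else {
    cat("  no suprathreshold component found\n")
  }
  invisible(x)
}
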
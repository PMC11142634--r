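#' Cross-modal spatial correlation of two connectomes
#'
#' Pearson correlation across the (optionally masked) upper-triangle edges of
#' a group-mean EEG connectome and a group-mean fMRI connectome -- the
#' central coupling statistic.
#'
#' @param eeg,fmri [connectome()]s or plain symmetric matrices (or edge
#'   vectors of equal length).
#' @param edge_mask optional logical edge vector selecting at least 3 edges.
#' @return the correlation coefficient.
#' @export
crossmodal_correlation <- function(eeg, fmri, edge_mask = NULL) {
  x <- as_edge_vector(eeg)
  y <- as_edge_vector(fmri)
  if (length(x) != length(y)) stop("edge vectors differ in length", call. = FALSE)
  if (!is.null(edge_mask)) {
    x <- x[edge_mask]
    y <- y[edge_mask]
  }
  if (length(x) < 3) stop("mask selects fewer than 3 edges", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant edge vector: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

as_edge_vector <- function(x) {
  if (inherits(x, "connectome")) return(vectorize_upper(x$values))
  if (is.matrix(x)) return(vectorize_upper(x))
  as.numeric(x)
}

#' Per-edge contribution decomposition of a Pearson correlation
#'
#' Exact additive split of the correlation between edge vectors `x` and `y`:
#' with z-scores normalized so that `sum(z^2) = 1`, the correlation equals
#' `sum(z_x * z_y)` and the relative contribution of edge `i` is
#' `c_i = z_xi * z_yi / r`, so `sum(c) = 1`.
#'
#' @param x,y numeric edge vectors (at least 3 edges, non-constant).
#' @return list with `c` (contributions), `r`, `z_x`, `z_y`.
#' @export
spatial_contribution <- function(x, y) {
  x <- as_edge_vector(x)
  y <- as_edge_vector(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("need two aligned edge vectors of length >= 3", call. = FALSE)
  }
  cx <- x - mean(x)
  cy <- y - mean(y)
  if (all(cx == 0) || all(cy == 0)) stop("constant input vector", call. = FALSE)
  zx <- cx / sqrt(sum(cx^2))
  zy <- cy / sqrt(sum(cy^2))
  r <- sum(zx * zy)
  if (abs(r) < .Machine$double.eps^0.5) {
    stop("correlation is 0: contributions undefined", call. = FALSE)
  }
  list(c = zx * zy / r, r = r, z_x = zx, z_y = zy)
}

# share of the correlation carried by masked edges, row-wise over matrices
contribution_share <- function(A, B, mask) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  num <- rowSums(A[, mask, drop = FALSE] * B[, mask, drop = FALSE])
  num / rowSums(A * B)
}

#' Split-half reliability of a group-mean connectome
#'
#' Subjects of one group are split into two equal halves; the correlation of
#' the two half-mean edge vectors measures within-modality consistency. For
#' even group sizes below 16 all distinct balanced splits are enumerated
#' (complementary splits counted once); otherwise `n_iter` random balanced
#' splits are drawn, leaving one random subject out per split when the group
#' size is odd.
#'
#' @param stack a [cohort_stack()].
#' @param group group label.
#' @param modality,band connectome selector.
#' @param n_iter random iterations when not enumerating.
#' @param seed RNG seed.
#' @return list with `mean_r`, `r` (per split) and `n_splits`.
#' @export
split_half_consistency <- function(stack, group, modality = "fmri",
                                   band = "none", n_iter = 5000, seed = NULL) {
  S <- stack_edges(stack, modality, band, groups = group)
  n <- nrow(S)
  if (n < 2) stop("group size < 2", call. = FALSE)
  half_r <- function(a_idx, rest) {
    stats::cor(colMeans(S[a_idx, , drop = FALSE]),
               colMeans(S[rest, , drop = FALSE]))
  }
  if (n %% 2 == 0 && n < 16) {
    combs <- utils::combn(n, n / 2)
    keep <- combs[1, ] == 1  # fix subject 1 in half A: dedupes complements
    combs <- combs[, keep, drop = FALSE]
    r <- apply(combs, 2, function(a) half_r(a, setdiff(seq_len(n), a)))
  } else {
    r <- with_seed(seed, {
      vapply(seq_len(n_iter), function(k) {
        idx <- if (n %% 2 == 1) sample(n, n - 1) else seq_len(n)
        idx <- sample(idx)
        h <- length(idx) / 2
        half_r(idx[1:h], idx[(h + 1):length(idx)])
      }, numeric(1))
    })
  }
  list(mean_r = mean(r), r = r, n_splits = length(r))
}

# shared permutation engine: null distribution of r_b - r_a where r_g is the
# coupling of group-mean EEG vs group-mean fMRI edge vectors
perm_coupling_null <- function(Se, Sf, is_b, n_perm, seed) {
  n <- nrow(Se)
  nb <- sum(is_b)
  tot_e <- colSums(Se)
  tot_f <- colSums(Sf)
  P <- with_seed(seed, {
    P <- matrix(0, n_perm, n)
    for (k in seq_len(n_perm)) P[k, sample.int(n, nb)] <- 1
    P
  })
  sb_e <- P %*% Se
  sb_f <- P %*% Sf
  sa_e <- matrix(tot_e, n_perm, length(tot_e), byrow = TRUE) - sb_e
  sa_f <- matrix(tot_f, n_perm, length(tot_f), byrow = TRUE) - sb_f
  list(null = rowwise_cor(sb_e, sb_f) - rowwise_cor(sa_e, sa_f),
       means = list(sb_e = sb_e / nb, sb_f = sb_f / nb,
                    sa_e = sa_e / (n - nb), sa_f = sa_f / (n - nb)))
}

perm_p <- function(null, obs, direction) {
  if (direction == "greater") (1 + sum(null >= obs)) / (1 + length(null))
  else (1 + sum(null <= obs)) / (1 + length(null))
}

#' Group-label permutation test of cross-modal coupling
#'
#' Tests whether the coupling (group-mean EEG vs group-mean fMRI spatial
#' correlation) of `group_b` differs from that of `group_a`. The observed
#' statistic is `r_b - r_a`; the null distribution is built by randomly
#' switching group labels while preserving group sizes, and the one-sided p
#' uses the add-one estimator `(1 + #{null >= obs}) / (1 + n_perm)` (mirrored
#' for `direction = "less"`).
#'
#' @param stack a [cohort_stack()].
#' @param group_a,group_b the two group labels.
#' @param band EEG band of the coupling.
#' @param direction `"greater"` tests `r_b > r_a`, `"less"` the reverse.
#' @param n_perm number of label permutations (warning below 100).
#' @param seed RNG seed.
#' @param edge_mask optional logical edge vector (subnetwork or hemisphere
#'   restriction).
#' @param mask_label description stored on the result.
#' @return object of class `coupling_result`: list with `band`, `r_a`, `r_b`,
#'   `stat`, `p_perm`, `direction`, `n_perm`, `mask`, `seed`.
#' @export
group_permutation_test <- function(stack, group_a, group_b, band = "alpha",
                                   direction = c("greater", "less"),
                                   n_perm = 5000, seed = NULL,
                                   edge_mask = NULL, mask_label = "whole-brain") {
  direction <- match.arg(direction)
  if (n_perm < 100) warning("n_perm < 100: permutation p will be coarse")
  grp <- stack_groups(stack, c(group_a, group_b))
  if (!any(grp == group_a) || !any(grp == group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  Se <- stack_edges(stack, "eeg", band, groups = c(group_a, group_b))
  Sf <- stack_edges(stack, "fmri", groups = c(group_a, group_b))
  if (!is.null(edge_mask)) {
    Se <- Se[, edge_mask, drop = FALSE]
    Sf <- Sf[, edge_mask, drop = FALSE]
  }
  is_b <- grp == group_b
  r_a <- stats::cor(colMeans(Se[!is_b, , drop = FALSE]),
                    colMeans(Sf[!is_b, , drop = FALSE]))
  r_b <- stats::cor(colMeans(Se[is_b, , drop = FALSE]),
                    colMeans(Sf[is_b, , drop = FALSE]))
  obs <- r_b - r_a
  pn <- perm_coupling_null(Se, Sf, is_b, n_perm, seed)
  structure(list(band = band, groups = c(group_a, group_b),
                 r_a = r_a, r_b = r_b, stat = obs,
                 p_perm = perm_p(pn$null, obs, direction),
                 direction = direction, n_perm = n_perm,
                 mask = mask_label, seed = seed),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> %s | %s: r(%s)=%.3f r(%s)=%.3f diff=%.3f p_perm=%.4g (%s, %d perms)\n",
              x$mask, x$band, x$groups[1], x$r_a, x$groups[2], x$r_b,
              x$stat, x$p_perm, x$direction, x$n_perm))
  invisible(x)
}

#' Subnetwork coupling and contribution battery
#'
#' For every (ICN, band) cell: the cross-modal coupling restricted to
#' intra-ICN edges in both groups, its group-label permutation p, and a
#' comparison of the ICN-summed contribution to the whole-brain coupling
#' (the share of the global correlation carried by intra-ICN edges). The
#' Bonferroni threshold is `alpha / (n_bands * n_networks)`. ICNs with fewer
#' than two regions are skipped with a warning.
#'
#' @param stack a [cohort_stack()].
#' @param group_a,group_b group labels.
#' @param bands EEG bands to test.
#' @param direction test direction for `group_b` relative to `group_a`.
#' @param n_perm label permutations.
#' @param seed RNG seed.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @return data.frame with one row per (icn, band): `r_a`, `r_b`, `stat`,
#'   `p_perm`, `contrib_a`, `contrib_b`, `contrib_stat`, `contrib_p`;
#'   attributes `bonferroni` and `n_cells`.
#' @export
subnetwork_coupling_tests <- function(stack, group_a, group_b,
                                      bands = EEG_BANDS,
                                      direction = c("greater", "less"),
                                      n_perm = 5000, seed = NULL, alpha = 0.05) {
  direction <- match.arg(direction)
  atlas <- stack$atlas
  icns <- ICN_LEVELS[1:7]
  counts <- table(factor(atlas$icn_assignment, levels = ICN_LEVELS))
  usable <- icns[counts[icns] >= 2]
  if (length(usable) < length(icns)) {
    warning(sprintf("skipping ICN(s) with < 2 regions: %s",
                    paste(setdiff(icns, usable), collapse = ", ")))
  }
  masks <- lapply(usable, function(nw) edge_mask_icn(atlas, nw))
  names(masks) <- usable
  grp <- stack_groups(stack, c(group_a, group_b))
  is_b <- grp == group_b
  Sf <- stack_edges(stack, "fmri", groups = c(group_a, group_b))
  rows <- list()
  for (bi in seq_along(bands)) {
    b <- bands[bi]
    Se <- stack_edges(stack, "eeg", b, groups = c(group_a, group_b))
    me_a <- colMeans(Se[!is_b, , drop = FALSE])
    mf_a <- colMeans(Sf[!is_b, , drop = FALSE])
    me_b <- colMeans(Se[is_b, , drop = FALSE])
    mf_b <- colMeans(Sf[is_b, , drop = FALSE])
    pn <- perm_coupling_null(Se, Sf, is_b, n_perm, child_seed(seed, bi))
    m <- pn$means
    for (nw in usable) {
      mask <- masks[[nw]]
      r_a <- stats::cor(me_a[mask], mf_a[mask])
      r_b <- stats::cor(me_b[mask], mf_b[mask])
      null_r <- rowwise_cor(m$sb_e[, mask, drop = FALSE], m$sb_f[, mask, drop = FALSE]) -
        rowwise_cor(m$sa_e[, mask, drop = FALSE], m$sa_f[, mask, drop = FALSE])
      ## ICN-summed contribution to the whole-brain decomposition
      ctr_a <- contribution_share(rbind(me_a), rbind(mf_a), mask)
      ctr_b <- contribution_share(rbind(me_b), rbind(mf_b), mask)
      null_c <- contribution_share(m$sb_e, m$sb_f, mask) -
        contribution_share(m$sa_e, m$sa_f, mask)
      rows[[length(rows) + 1]] <- data.frame(
        icn = nw, band = b, r_a = r_a, r_b = r_b, stat = r_b - r_a,
        p_perm = perm_p(null_r, r_b - r_a, direction),
        contrib_a = ctr_a, contrib_b = ctr_b, contrib_stat = ctr_b - ctr_a,
        contrib_p = perm_p(null_c, ctr_b - ctr_a, direction),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni") <- alpha / (length(bands) * length(usable))
  attr(out, "n_cells") <- nrow(out)
  out
}

#' Distance-connectivity correlation
#'
#' Pearson correlation between edge-wise Euclidean centroid distance and edge
#' connectivity -- the geometric confound probe.
#'
#' @param atlas an [atlas_model()].
#' @param conn a [connectome()] or symmetric matrix.
#' @return the correlation coefficient.
#' @export
distance_fc_correlation <- function(atlas, conn) {
  d <- edge_distances(atlas)
  if (stats::sd(d) == 0) stop("degenerate centroids: all distances equal", call. = FALSE)
  crossmodal_correlation(d, as_edge_vector(conn))
}

#' Hemisphere-restricted coupling battery
#'
#' Re-runs the group coupling comparison on intra-hemispheric edges of one
#' hemisphere only.
#'
#' @inheritParams group_permutation_test
#' @param hemisphere `"L"` or `"R"`.
#' @param bands EEG bands to test.
#' @return list of [group_permutation_test()] results, one per band.
#' @export
hemisphere_restricted_analysis <- function(stack, group_a, group_b,
                                           hemisphere = c("L", "R"),
                                           bands = EEG_BANDS,
                                           direction = "greater",
                                           n_perm = 5000, seed = NULL) {
  hemisphere <- match.arg(hemisphere)
  mask <- edge_mask_hemisphere(stack$atlas, hemisphere)
  out <- lapply(seq_along(bands), function(k) {
    group_permutation_test(stack, group_a, group_b, bands[k], direction,
                           n_perm, child_seed(seed, k), edge_mask = mask,
                           mask_label = paste0("hemisphere-", hemisphere))
  })
  names(out) <- bands
  out
}

#' Individual-level coupling comparison
#'
#' Computes each subject's own EEG-fMRI coupling (correlation of that
#' subject's edge vectors) and compares the two groups with a one-sided
#' two-sample t test, Bonferroni-corrected over the tested bands.
#'
#' @inheritParams group_permutation_test
#' @param n_comparisons number of bands in the family (Bonferroni divisor).
#' @return list with per-group coupling vectors, `t`, `p`, and
#'   `bonferroni_alpha`.
#' @export
individual_coupling_test <- function(stack, group_a, group_b, band = "alpha",
                                     direction = c("greater", "less"),
                                     n_comparisons = 5) {
  direction <- match.arg(direction)
  per_subj <- function(g) {
    Se <- stack_edges(stack, "eeg", band, groups = g)
    Sf <- stack_edges(stack, "fmri", groups = g)
    vapply(seq_len(nrow(Se)), function(i) stats::cor(Se[i, ], Sf[i, ]), numeric(1))
  }
  ra <- per_subj(group_a)
  rb <- per_subj(group_b)
  tt <- stats::t.test(rb, ra, alternative = direction)
  list(r_a = ra, r_b = rb, t = unname(tt$statistic), p = tt$p.value,
       direction = direction, bonferroni_alpha = 0.05 / n_comparisons)
}
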
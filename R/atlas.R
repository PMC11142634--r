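ICN_LEVELS <- c("visual", "somato-motor", "dorsal-attention",
                "ventral-attention", "limbic", "fronto-parietal",
                "default-mode", "unassigned")

#' Construct an atlas model
#'
#' An atlas is the region-level metadata shared by every connectome in a
#' cohort: region labels, hemisphere tags, centroid coordinates (mm), and the
#' assignment of each region to one of the seven canonical intrinsic
#' connectivity networks (ICNs: visual, somato-motor, dorsal-attention,
#' ventral-attention, limbic, fronto-parietal, default-mode) or "unassigned".
#'
#' @param region_labels character vector of unique region names.
#' @param hemisphere per-region tag, `"L"` or `"R"`.
#' @param centroid_mm numeric `R x 3` matrix of centroid coordinates in mm.
#' @param icn_assignment per-region ICN tag from the closed set above.
#' @return an object of class `atlas_model`.
#' @export
atlas_model <- function(region_labels, hemisphere, centroid_mm, icn_assignment) {
  R <- length(region_labels)
  centroid_mm <- as.matrix(centroid_mm)
  if (length(hemisphere) != R || nrow(centroid_mm) != R ||
      length(icn_assignment) != R) {
    stop("atlas fields have inconsistent region counts", call. = FALSE)
  }
  if (ncol(centroid_mm) != 3) stop("centroids must be 3-vectors (mm)", call. = FALSE)
  if (!all(is.finite(centroid_mm))) stop("centroids must be finite", call. = FALSE)
  if (!all(hemisphere %in% c("L", "R"))) {
    stop("hemisphere tags must be 'L' or 'R'", call. = FALSE)
  }
  bad <- setdiff(unique(icn_assignment), ICN_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown ICN tag(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(ICN_LEVELS, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(region_labels)) stop("region labels must be unique", call. = FALSE)
  structure(list(region_labels = as.character(region_labels),
                 hemisphere = as.character(hemisphere),
                 centroid_mm = unname(centroid_mm),
                 icn_assignment = as.character(icn_assignment)),
            class = "atlas_model")
}

#' @export
print.atlas_model <- function(x, ...) {
  cat(sprintf("<atlas_model> %d regions (%d L / %d R), %d edges\n",
              length(x$region_labels), sum(x$hemisphere == "L"),
              sum(x$hemisphere == "R"),
              n_edges(length(x$region_labels))))
  print(table(icn = x$icn_assignment))
  invisible(x)
}

#' Number of regions in an atlas
#' @param atlas an `atlas_model`.
#' @export
n_regions <- function(atlas) length(atlas$region_labels)

#' Load an atlas from delimited text files
#'
#' Reads either a single combined TSV with columns
#' `label, hemisphere, x, y, z, icn` (header required), or three aligned
#' files: a labels file (`label, hemisphere`), a centroids file (`x, y, z`)
#' and an ICN file (one tag per row).
#'
#' @param labels_path path to the combined table, or to the labels file.
#' @param centroids_path,icn_path optional companion files for the
#'   three-file layout.
#' @return an `atlas_model`.
#' @export
load_atlas <- function(labels_path, centroids_path = NULL, icn_path = NULL) {
  if (is.null(centroids_path) && is.null(icn_path)) {
    tab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("label", "hemisphere", "x", "y", "z", "icn")
    if (!all(need %in% names(tab))) {
      stop(sprintf("atlas file must have columns: %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    return(atlas_model(tab$label, tab$hemisphere,
                       cbind(tab$x, tab$y, tab$z), tab$icn))
  }
  labs <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  cent <- as.matrix(utils::read.table(centroids_path, header = FALSE, sep = "\t"))
  icn <- utils::read.table(icn_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[[1]]
  if (nrow(labs) != nrow(cent) || nrow(labs) != length(icn)) {
    stop("atlas files have mismatched row counts", call. = FALSE)
  }
  atlas_model(labs$label, labs$hemisphere, cent, icn)
}

#' Bundled 68-region reference atlas (synthetic stand-in)
#'
#' Returns the packaged 68-region cortical parcellation (34 regions per
#' hemisphere, Desikan-Killiany naming) with approximate centroid coordinates
#' and an approximate seven-network ICN assignment. The coordinates and
#' assignments are a synthetic stand-in written from field knowledge --
#' adequate for simulation, distance-decay modelling and subnetwork masking,
#' but not a subject-specific parcellation.
#'
#' @return an `atlas_model` with 68 regions.
#' @export
reference_atlas <- function() {
  path <- system.file("extdata", "atlas_desikan68_synthetic.tsv",
                      package = "crossconn", mustWork = TRUE)
  load_atlas(path)
}

#' Pairwise Euclidean centroid distances as an edge vector
#' @param atlas an `atlas_model`.
#' @return numeric edge vector of distances (mm) in canonical edge order.
#' @export
edge_distances <- function(atlas) {
  vectorize_upper(as.matrix(stats::dist(atlas$centroid_mm)))
}

#' Edge masks for subnetwork- and hemisphere-restricted analyses
#'
#' `edge_mask_icn()` selects edges whose two endpoints both belong to the
#' given ICN; `edge_mask_hemisphere()` selects intra-hemispheric edges.
#'
#' @param atlas an `atlas_model`.
#' @param icn one ICN tag (see [atlas_model()]).
#' @return logical edge vector in canonical order.
#' @export
edge_mask_icn <- function(atlas, icn) {
  icn <- match.arg(icn, ICN_LEVELS)
  idx <- edge_index(n_regions(atlas))
  inside <- atlas$icn_assignment == icn
  inside[idx[, 1]] & inside[idx[, 2]]
}

#' @rdname edge_mask_icn
#' @param hemisphere `"L"` or `"R"`.
#' @export
edge_mask_hemisphere <- function(atlas, hemisphere) {
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  if (!any(atlas$hemisphere == hemisphere)) {
    stop(sprintf("no regions tagged hemisphere '%s'", hemisphere), call. = FALSE)
  }
  idx <- edge_index(n_regions(atlas))
  inside <- atlas$hemisphere == hemisphere
  inside[idx[, 1]] & inside[idx[, 2]]
}
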
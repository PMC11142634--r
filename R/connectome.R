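EEG_BANDS <- c("delta", "theta", "alpha", "beta", "gamma")

#' Construct a connectome
#'
#' A connectome is one subject's symmetric region-by-region functional
#' connectivity matrix, tagged by modality and (for EEG) frequency band. The
#' diagonal carries no information and is stored as zero; fMRI values are
#' Pearson correlations in \[-1, 1\], EEG values are corrected imaginary
#' coherency (ciCoh) in \[0, 1\].
#'
#' @param values square symmetric numeric matrix; symmetric within `1e-12`.
#' @param modality `"fmri"` or `"eeg"`.
#' @param band `"none"` (fMRI) or one of delta/theta/alpha/beta/gamma.
#' @param subject_id subject identifier.
#' @param n_samples_used number of fMRI volumes or EEG segments that survived
#'   scrubbing/rejection and entered the estimate.
#' @return an object of class `connectome`.
#' @export
connectome <- function(values, modality = c("fmri", "eeg"), band = "none",
                       subject_id = NA_character_, n_samples_used = NA_integer_) {
  modality <- match.arg(modality)
  band <- match.arg(band, c("none", EEG_BANDS))
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("connectome values must be a square matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("connectome contains non-finite off-diagonal values", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-12) {
    stop(sprintf("connectome not symmetric (max asymmetry %.3g); symmetrize first", asym),
         call. = FALSE)
  }
  diag(values) <- 0
  off <- vectorize_upper(values)
  if (modality == "fmri" && (any(off < -1) || any(off > 1))) {
    stop("fmri connectome values must lie in [-1, 1]", call. = FALSE)
  }
  if (modality == "eeg") {
    if (band == "none") stop("eeg connectomes must carry a band tag", call. = FALSE)
    if (any(off < 0) || any(off > 1)) {
      stop("eeg ciCoh values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(values = unname(values), modality = modality, band = band,
                 subject_id = subject_id,
                 n_samples_used = as.integer(n_samples_used)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s%s, %d regions, subject %s, n_samples %s\n",
              x$modality, if (x$band != "none") paste0("-", x$band) else "",
              nrow(x$values), x$subject_id, x$n_samples_used))
  invisible(x)
}

#' Read and write connectome matrices
#'
#' Connectomes are stored as headerless TSV float matrices with a zero
#' diagonal, plus an optional JSON sidecar (`<path>.meta.json`) carrying
#' modality, band, subject id and sample count. Matrices that are asymmetric
#' beyond `1e-12` (as produced by some upstream tools) are symmetrized as
#' `(M + t(M))/2` with a warning; matrices asymmetric beyond `tol_reject`
#' are refused.
#'
#' @param path file path of the TSV matrix.
#' @param modality,band,subject_id metadata; when omitted, taken from the
#'   sidecar if present.
#' @param tol_reject maximum tolerated asymmetry before read is refused.
#' @return `read_connectome()`: a [connectome()].
#' @export
read_connectome <- function(path, modality = NULL, band = NULL,
                            subject_id = NULL, tol_reject = 0.1) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  if (!is.numeric(m)) stop("connectome file is not numeric", call. = FALSE)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("connectome file is not square (%d x %d)", nrow(m), ncol(m)),
         call. = FALSE)
  }
  diag(m) <- 0
  if (!all(is.finite(m))) {
    stop("connectome file has non-finite off-diagonal entries", call. = FALSE)
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  asym <- max(abs(m - t(m)))
  if (asym > tol_reject) {
    stop(sprintf("matrix asymmetry %.3g exceeds tol_reject", asym), call. = FALSE)
  }
  if (asym > 1e-12) {
    warning(sprintf("asymmetric input (max %.3g); symmetrized as (M + t(M))/2", asym))
    m <- (m + t(m)) / 2
  }
  connectome(m,
             modality = modality %||% meta$modality %||% "fmri",
             band = band %||% meta$band %||% "none",
             subject_id = subject_id %||% meta$subject_id %||% NA_character_,
             n_samples_used = meta$n_samples_used %||% NA_integer_)
}

#' @rdname read_connectome
#' @param x a [connectome()].
#' @param sidecar write the JSON metadata sidecar alongside the matrix?
#' @return `write_connectome()`: `path`, invisibly.
#' @export
write_connectome <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "connectome"))
  utils::write.table(format(x$values, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(list(subject_id = x$subject_id, modality = x$modality,
                              band = x$band, n_samples_used = x$n_samples_used),
                         paste0(path, ".meta.json"), auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Element-wise group average of connectomes
#'
#' Averages the pairwise connectivity values of every subject matching the
#' filter, the group-level representation all cross-modal statistics operate
#' on.
#'
#' @param stack a [cohort_stack()].
#' @param groups group labels to include (e.g. `"control"`), or `NULL` for all.
#' @param modality `"fmri"` or `"eeg"`.
#' @param band band tag (`"none"` for fMRI).
#' @return a [connectome()] whose `n_samples_used` records the subject count.
#' @export
group_average <- function(stack, groups = NULL, modality = "fmri", band = "none") {
  subs <- stack_subjects(stack, groups)
  if (!length(subs)) stop("no subjects match the group filter", call. = FALSE)
  key <- connectome_key(modality, band)
  mats <- lapply(subs, function(s) {
    cm <- s$connectomes[[key]]
    if (is.null(cm)) stop(sprintf("subject %s lacks connectome %s", s$subject_id, key),
                          call. = FALSE)
    cm$values
  })
  avg <- Reduce(`+`, mats) / length(mats)
  connectome(avg, modality = modality, band = band,
             subject_id = sprintf("group_mean(n=%d)", length(mats)),
             n_samples_used = length(mats))
}

#' Fisher z-transform of a correlation connectome
#'
#' Applies `atanh` off-diagonal. Values at exactly +/-1 are clipped to
#' +/-(1 - 1e-7) with a warning. Intended for fMRI Pearson matrices; applying
#' it to an EEG connectome raises a warning but proceeds.
#'
#' @param x a [connectome()] or a plain symmetric matrix.
#' @return same type as the input, transformed.
#' @export
fisher_z <- function(x) {
  is_conn <- inherits(x, "connectome")
  m <- if (is_conn) x$values else x
  if (is_conn && x$modality != "fmri") {
    warning("fisher_z applied to a non-fmri connectome")
  }
  off <- row(m) != col(m)
  if (any(abs(m[off]) >= 1)) {
    warning("values at +/-1 clipped to +/-(1 - 1e-7) before atanh")
    m[off] <- pmin(pmax(m[off], -(1 - 1e-7)), 1 - 1e-7)
  }
  m[off] <- atanh(m[off])
  if (!is_conn) return(m)
  x$values <- m
  x
}

# canonical key under which a connectome is stored in a subject record
connectome_key <- function(modality, band = "none") {
  if (modality == "fmri") "fmri" else paste0("eeg.", band)
}
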
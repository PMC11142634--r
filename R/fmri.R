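#' Framewise displacement from motion parameters
#'
#' The volume-to-volume head-motion summary used for scrubbing: the sum of
#' absolute translation differences plus the sum of absolute rotation
#' differences converted to arc length on a 50 mm sphere,
#' `fd[t] = sum |d trans| + 50 * sum |d rot|`, with `fd[1] = 0` by convention.
#'
#' @param motion_params `T x 6` matrix: three translations (mm) then three
#'   rotations (radians).
#' @return numeric vector of length `T` (mm).
#' @export
framewise_displacement <- function(motion_params) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6) {
    stop("motion parameters must have 6 columns (3 translations mm, 3 rotations rad)",
         call. = FALSE)
  }
  d <- abs(diff(motion_params))
  c(0, rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE]))
}

#' Censor high-motion volumes
#'
#' Removes volumes whose framewise displacement exceeds the threshold
#' (default 0.5 mm). Fewer than 10 surviving volumes is an error -- the
#' subject-exclusion signal.
#'
#' @param series `R x T` region time-series matrix.
#' @param fd framewise displacement vector of length `T`.
#' @param threshold_mm scrubbing threshold in mm.
#' @return list with `series` (censored, `R x T'`) and `mask` (fields `keep`,
#'   `fd`, `threshold_mm`, `n_removed`).
#' @export
scrub <- function(series, fd, threshold_mm = 0.5) {
  series <- as.matrix(series)
  if (ncol(series) != length(fd)) {
    stop("fd length must equal the number of volumes", call. = FALSE)
  }
  keep <- fd <= threshold_mm
  if (sum(keep) < 10) {
    stop(sprintf("only %d volumes survive scrubbing (< 10): exclude subject",
                 sum(keep)), call. = FALSE)
  }
  list(series = series[, keep, drop = FALSE],
       mask = list(keep = keep, fd = fd, threshold_mm = threshold_mm,
                   n_removed = sum(!keep)))
}

#' Regress nuisance signals out of region time series
#'
#' Per-region ordinary least-squares residuals against an intercept plus the
#' confound columns (CSF, white matter, six motion parameters, global gray
#' matter signal).
#'
#' @param series `R x T` matrix.
#' @param confounds `T x K` matrix, rows aligned with volumes.
#' @return `R x T` residual matrix.
#' @export
nuisance_regress <- function(series, confounds) {
  series <- as.matrix(series)
  confounds <- as.matrix(confounds)
  if (ncol(series) != nrow(confounds)) {
    stop("confound rows must align with volumes", call. = FALSE)
  }
  X <- cbind(intercept = 1, confounds)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient confound design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  t(qr.resid(qrx, t(series)))
}

#' Zero-phase Butterworth band-pass for BOLD series
#'
#' Second-order-sections Butterworth (order 2 per pass) applied
#' forward-backward (`filtfilt`), giving zero phase distortion. Defaults to
#' the 0.009-0.08 Hz band.
#'
#' @param series `R x T` matrix.
#' @param tr_s repetition time in seconds (sampling interval).
#' @param low,high band edges in Hz; `high` must be below the Nyquist
#'   frequency `1 / (2 tr_s)`.
#' @return filtered `R x T` matrix.
#' @export
bandpass <- function(series, tr_s, low = 0.009, high = 0.08) {
  series <- as.matrix(series)
  nyq <- 1 / (2 * tr_s)
  if (high >= nyq) {
    stop(sprintf("high edge %.3f Hz is at/above Nyquist %.3f Hz", high, nyq),
         call. = FALSE)
  }
  if (low <= 0 || low >= high) stop("need 0 < low < high", call. = FALSE)
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  # demean first: removes DC exactly and avoids filter edge transients
  t(apply(series, 1, function(x) signal::filtfilt(bf, x - mean(x))))
}

#' Pearson functional connectome from cleaned region time series
#'
#' Unthresholded pairwise Pearson correlation of the cleaned time courses,
#' diagonal stored as zero. Zero-variance regions yield zeroed edges (with a
#' warning) rather than NaNs.
#'
#' @param series `R x T` cleaned matrix (at least 10 volumes).
#' @param subject_id id stored on the connectome.
#' @return a [connectome()] with `modality = "fmri"`; `n_samples_used` is the
#'   number of volumes.
#' @export
fmri_connectome <- function(series, subject_id = NA_character_) {
  series <- as.matrix(series)
  if (ncol(series) < 10) stop("need at least 10 volumes", call. = FALSE)
  v <- apply(series, 1, stats::var)
  flat <- v <= .Machine$double.eps
  r <- matrix(0, nrow(series), nrow(series))
  if (any(flat)) {
    warning(sprintf("%d zero-variance region(s); their edges set to 0", sum(flat)))
  }
  if (any(!flat)) {
    r[!flat, !flat] <- stats::cor(t(series[!flat, , drop = FALSE]))
  }
  diag(r) <- 0
  r[abs(r) > 1] <- sign(r[abs(r) > 1])  # guard tiny numeric overshoot
  connectome((r + t(r)) / 2, "fmri", subject_id = subject_id,
             n_samples_used = ncol(series))
}

#' Full fMRI connectivity pipeline
#'
#' Fixed stage order: nuisance regression, band-pass filtering, motion
#' scrubbing, Pearson correlation. Filtering precedes scrubbing because the
#' filter needs contiguous samples.
#'
#' @param series `R x T` region BOLD matrix.
#' @param motion_params `T x 6` motion table (see
#'   [framewise_displacement()]).
#' @param confounds `T x K` nuisance matrix (should include the motion
#'   columns).
#' @param tr_s repetition time (s).
#' @param fd_threshold scrub threshold (mm).
#' @param subject_id id stored on the connectome.
#' @param low,high band-pass edges (Hz).
#' @return list with `connectome`, `scrub_mask`, and `fd`.
#' @export
fc_fmri_pipeline <- function(series, motion_params, confounds, tr_s,
                             fd_threshold = 0.5, subject_id = NA_character_,
                             low = 0.009, high = 0.08) {
  cleaned <- nuisance_regress(series, confounds)
  filtered <- bandpass(cleaned, tr_s, low, high)
  fd <- framewise_displacement(motion_params)
  sc <- scrub(filtered, fd, fd_threshold)
  list(connectome = fmri_connectome(sc$series, subject_id = subject_id),
       scrub_mask = sc$mask, fd = fd)
}
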
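#' Canonical EEG frequency bands
#'
#' delta 0.3-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-60 Hz. The 2-Hz
#' analysis bins are assigned to bands by bin center (centers 1, 3, ..., 59
#' Hz), so each bin belongs to exactly one band: delta gets centers 1 and 3,
#' theta 5 and 7, alpha 9 and 11, beta 13-29, gamma 31-59.
#'
#' @return data.frame with columns `name`, `f_lo`, `f_hi`.
#' @export
band_definitions <- function() {
  data.frame(name = EEG_BANDS,
             f_lo = c(0.3, 4, 8, 12, 30),
             f_hi = c(4, 8, 12, 30, 60),
             stringsAsFactors = FALSE)
}

# band of each bin center; NA when outside all bands
assign_band <- function(centers) {
  bd <- band_definitions()
  out <- rep(NA_character_, length(centers))
  for (k in seq_len(nrow(bd))) {
    inside <- centers >= bd$f_lo[k] & centers < bd$f_hi[k]
    if (k == nrow(bd)) inside <- inside | centers == bd$f_hi[k]
    out[inside] <- bd$name[k]
  }
  out
}

#' Cut region time series into TR-length segments
#'
#' EEG is segmented into non-overlapping windows matching one repetition time
#' of the paired fMRI acquisition; a trailing partial segment is dropped.
#'
#' @param series `R x N` matrix (or a list with a `data` element).
#' @param fs sampling rate (Hz).
#' @param segment_len_s segment duration in seconds (the fMRI TR).
#' @return list of `R x L` matrices, `L = round(fs * segment_len_s)`.
#' @export
segment <- function(series, fs, segment_len_s) {
  if (is.list(series) && !is.null(series$data)) series <- series$data
  series <- as.matrix(series)
  L <- round(fs * segment_len_s)
  if (L < 64) stop(sprintf("segment length %d samples < 64", L), call. = FALSE)
  n_seg <- floor(ncol(series) / L)
  if (n_seg < 1) stop("recording shorter than one segment", call. = FALSE)
  lapply(seq_len(n_seg), function(k) {
    series[, ((k - 1) * L + 1):(k * L), drop = FALSE]
  })
}

#' Reject artifact-contaminated segments
#'
#' Two site-specific policies: `sd4` drops segments in which any region's
#' samples deviate from that region's whole-recording mean by more than four
#' whole-recording standard deviations; `amp300` drops segments whose
#' amplitude leaves the +/-300 microvolt range (input units must be
#' microvolts). `none` keeps everything.
#'
#' @param segments list of `R x L` matrices (from [segment()]).
#' @param policy `"sd4"`, `"amp300"` or `"none"`.
#' @param units amplitude units of the data; `"uV"` required for `amp300`.
#' @return list with `segments` (kept) and `rejected` (integer indices).
#' @export
reject_segments <- function(segments, policy = c("none", "sd4", "amp300"),
                            units = "au") {
  policy <- match.arg(policy)
  if (policy == "none") {
    return(list(segments = segments, rejected = integer(0)))
  }
  if (policy == "amp300") {
    if (!identical(units, "uV")) {
      stop("amp300 policy requires data in microvolts (units = 'uV')",
           call. = FALSE)
    }
    bad <- vapply(segments, function(s) min(s) < -300 || max(s) > 300, logical(1))
  } else {
    whole <- do.call(cbind, segments)
    mu <- rowMeans(whole)
    sdv <- apply(whole, 1, stats::sd)
    sdv[sdv == 0] <- Inf  # flat region never triggers
    bad <- vapply(segments, function(s) {
      any(abs(s - mu) > 4 * sdv)
    }, logical(1))
  }
  list(segments = segments[!bad], rejected = which(bad))
}

#' Welch cross-spectral coherency of one segment
#'
#' Non-overlapping Hann-windowed sub-windows of `round(fs / 2)` samples (2-Hz
#' frequency resolution); auto- and cross-spectra are averaged over
#' sub-windows and coherency is `C_xy = S_xy / sqrt(S_xx S_yy)`. Independent
#' sub-windows make the recorded degrees of freedom (`2 x` the number of
#' averaged sub-windows) exact, so the analytic significance test is
#' calibrated. Bins
#' retained cover 0-60 Hz: the FFT coefficient at frequency `f` represents
#' the 2-Hz bin `(f - 2, f]` with center `f - 1`, giving bin centers 1, 3,
#' ..., 59 Hz.
#'
#' @param seg `R x L` segment matrix.
#' @param fs sampling rate (Hz).
#' @return object of class `segment_spectra`: list with complex array
#'   `coherency` (`R x R x B`), `centers` (Hz), `dof`, `n_windows`.
#' @export
segment_coherency <- function(seg, fs) {
  seg <- as.matrix(seg)
  R <- nrow(seg)
  L <- ncol(seg)
  nwin <- round(fs / 2)
  hop <- nwin  # non-overlapping: keeps the dof of the estimate exact
  if (L < 2 * nwin) stop("segment too short for 2 Welch sub-windows", call. = FALSE)
  starts <- seq(1, L - nwin + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nwin - 1)) / nwin))
  df <- fs / nwin
  k_max <- min(floor(nwin / 2), floor(60 / df))
  ks <- seq_len(k_max)          # FFT coefficient indices (freq = k * df)
  centers <- ks * df - df / 2
  B <- length(ks)
  S <- array(0 + 0i, c(R, R, B))
  P <- matrix(0, R, B)          # auto-spectra
  for (s0 in starts) {
    X <- stats::mvfft(t(seg[, s0:(s0 + nwin - 1), drop = FALSE]) * w)
    V <- t(X[ks + 1L, , drop = FALSE])  # R x B
    for (b in seq_len(B)) {
      S[, , b] <- S[, , b] + V[, b] %*% t(Conj(V[, b, drop = FALSE]))
    }
    P <- P + Mod(V)^2
  }
  co <- array(0 + 0i, c(R, R, B))
  for (b in seq_len(B)) {
    denom <- sqrt(P[, b] %*% t(P[, b]))
    cb <- S[, , b] / denom
    cb[denom == 0] <- 0
    co[, , b] <- (cb + Conj(t(cb))) / 2  # enforce Hermitian symmetry
  }
  structure(list(coherency = co, centers = centers,
                 dof = 2L * length(starts), n_windows = length(starts)),
            class = "segment_spectra")
}

#' Corrected imaginary coherency (lagged coherence)
#'
#' `ciCoh = sqrt( Im(C)^2 / (1 - Re(C)^2) )`, clipped to \[0, 1\]; where
#' `Re(C)^2 = 1` the value is defined as 0. Purely real coherency of any
#' magnitude -- the signature of instantaneous (volume-conduction-like)
#' mixing -- maps to 0.
#'
#' @param spectra a `segment_spectra` object, or a complex array/matrix of
#'   coherency values.
#' @return real array of the same dimension, diagonal zero.
#' @export
cicoh <- function(spectra) {
  co <- if (inherits(spectra, "segment_spectra")) spectra$coherency else spectra
  re2 <- Re(co)^2
  out <- sqrt(pmax(Im(co)^2, 0) / pmax(1 - re2, .Machine$double.eps))
  out[re2 >= 1 - 1e-12] <- 0
  out <- pmin(pmax(out, 0), 1)
  dm <- dim(co)
  if (length(dm) == 3) {
    R <- dm[1]
    out[cbind(rep(seq_len(R), dm[3]), rep(seq_len(R), dm[3]),
              rep(seq_len(dm[3]), each = R))] <- 0
  } else if (!is.null(dm)) {
    out[cbind(seq_len(dm[1]), seq_len(dm[1]))] <- 0
  }
  out
}

#' Analytic significance mask for coherence estimates
#'
#' Under the null of independent signals, a coherence magnitude estimated
#' from `dof / 2` averaged sub-windows has tail probability
#' `p = (1 - |C|^2)^((dof - 2) / 2)`; bins with `p > alpha` are masked out
#' (set to zero) per segment before band averaging.
#'
#' @param spectra a `segment_spectra` object.
#' @param alpha significance level (default 0.05).
#' @return logical array, `TRUE` where the bin is kept (`p <= alpha`).
#' @export
significance_mask <- function(spectra, alpha = 0.05) {
  stopifnot(inherits(spectra, "segment_spectra"))
  if (spectra$dof <= 2) stop("need dof > 2 for the analytic test", call. = FALSE)
  coh2 <- pmin(Mod(spectra$coherency)^2, 1)
  p <- (1 - coh2)^((spectra$dof - 2) / 2)
  p <= alpha
}

#' Band-wise EEG connectomes from region source time series
#'
#' The full EEG connectivity chain: segment into TR-length epochs, reject
#' artifact segments, estimate segment-wise coherency, form corrected
#' imaginary coherency, zero non-significant bins (analytic test at `alpha`),
#' average bins within each canonical band, then average segment matrices
#' over time (zeros included). No threshold is applied to the final matrix.
#'
#' @param series `R x N` matrix, or a list with `data`, `fs`,
#'   `segment_len_s`, `units` (as produced by the synthetic generator).
#' @param fs sampling rate (Hz); taken from the list form when omitted.
#' @param segment_len_s segment duration (s, the fMRI TR).
#' @param policy segment-rejection policy (see [reject_segments()]).
#' @param alpha significance level of the per-bin mask.
#' @param units amplitude units (needed by the `amp300` policy).
#' @param subject_id id stored on the connectomes.
#' @return named list of [connectome()]s, one per band (`eeg.delta`, ...);
#'   each records the surviving segment count in `n_samples_used`.
#' @export
eeg_connectome <- function(series, fs = NULL, segment_len_s = NULL,
                           policy = "none", alpha = 0.05, units = "au",
                           subject_id = NA_character_) {
  if (is.list(series) && !is.null(series$data)) {
    fs <- fs %||% series$fs
    segment_len_s <- segment_len_s %||% series$segment_len_s
    units <- series$units %||% units
    series <- series$data
  }
  segs <- segment(series, fs, segment_len_s)
  kept <- reject_segments(segs, policy, units = units)
  if (!length(kept$segments)) stop("no segments survive rejection", call. = FALSE)
  R <- nrow(series)
  band_sum <- NULL
  for (seg_k in kept$segments) {
    sp <- segment_coherency(seg_k, fs)
    ci <- cicoh(sp) * significance_mask(sp, alpha)
    band_of <- assign_band(sp$centers)
    bm <- sapply(EEG_BANDS, function(b) {
      sel <- which(band_of == b)
      if (!length(sel)) return(matrix(0, R, R))
      apply(ci[, , sel, drop = FALSE], c(1, 2), mean)
    }, simplify = FALSE)
    if (is.null(band_sum)) band_sum <- bm else {
      band_sum <- Map(`+`, band_sum, bm)
    }
  }
  n_seg <- length(kept$segments)
  out <- lapply(EEG_BANDS, function(b) {
    m <- band_sum[[b]] / n_seg
    m <- (m + t(m)) / 2
    diag(m) <- 0
    connectome(pmin(pmax(m, 0), 1), "eeg", band = b, subject_id = subject_id,
               n_samples_used = n_seg)
  })
  names(out) <- paste0("eeg.", EEG_BANDS)
  out
}
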
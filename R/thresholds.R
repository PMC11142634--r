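#' Multiple-testing thresholds of the analysis battery
#'
#' The three analytic thresholds the pipeline applies: the Bonferroni
#' threshold over the five EEG bands for whole-brain coupling comparisons
#' (`alpha / n_bands = 0.01`), the Bonferroni threshold over the band-by-
#' subnetwork grid (`alpha / (n_bands * n_networks) = 0.05 / 35`), and the
#' family threshold of the six monomodal NBS models (`alpha / n_models =
#' 0.05 / 6`).
#'
#' @param alpha family-wise level.
#' @param n_bands number of EEG bands (5).
#' @param n_networks number of intrinsic connectivity networks (7).
#' @param n_models number of monomodal NBS models (fMRI + 5 bands = 6).
#' @return named list with `band_bonferroni`, `subnetwork_bonferroni`,
#'   `nbs_family`.
#' @export
analysis_thresholds <- function(alpha = 0.05, n_bands = 5, n_networks = 7,
                                n_models = 6) {
  list(band_bonferroni = alpha / n_bands,
       subnetwork_bonferroni = alpha / (n_bands * n_networks),
       nbs_family = alpha / n_models)
}
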
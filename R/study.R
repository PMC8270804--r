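#' Reference synthetic-study configuration
#'
#' The package's canonical end-to-end experiment: a 470-lesion cohort with
#' 62.8% malignant prevalence and the default class-conditional kinetics,
#' rendered on compact lesion grids (log-normal largest diameters, median
#' 8 mm, range 5-25 mm) so that a complete run - synthesis, segmentation,
#' voxelwise Tofts fitting, feature extraction, PCA, MLP training and
#' cutoff evaluation - finishes in minutes on one CPU. The architecture
#' search spans a 10-point ladder of hidden-unit counts within 1-50 and
#' both candidate activations.
#'
#' @param n_lesions cohort size (default 470).
#' @return a [pipeline_config()].
#' @export
study_config <- function(n_lesions = 470L) {
  pipeline_config(
    cohort = cohort_config(n_lesions = n_lesions,
                           size_median_mm = 8, size_sdlog = 0.45,
                           size_range_mm = c(5, 25)),
    mlp = mlp_config(hidden_units = c(1:4, 6L, 8L, 12L, 16L, 24L, 32L),
                     max_epochs = 400L))
}
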
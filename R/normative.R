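#' Normative CoP reference values
#'
#' Published normative per-dog means and SDs of the four CoP measures for
#' healthy adult miniature Dachshunds in quiet standing, per device (force
#' platform at 100 Hz; pressure mat at 60 Hz), with the between-device
#' Pearson correlations. Useful as calibration context for the synthetic
#' cohort generator and as the reference in worked examples: for instance,
#' the expected Bland-Altman bias for any measure equals the difference of
#' the device means.
#'
#' @return A tibble with one row per measure.
#' @export
#' @examples
#' ref <- normative_reference()
#' ref$mean_force_plate - ref$mean_pressure_mat  # expected device biases
normative_reference <- function() {
  readr::read_csv(system.file("extdata", "normative_cop_measures.csv",
                              package = "pawsway"),
                  comment = "#", show_col_types = FALSE, progress = FALSE)
}
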
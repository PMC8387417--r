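#' Published whole-brain group means for the blarcamesine occupancy study
#'
#' Group mean (and SD) of the 2TCM macro-parameters -- binding potential
#' `k3/k4`, total distribution volume `Vt`, volume of specific binding
#' `Vs` -- plus percent receptor occupancy and %ID/g, per genotype and
#' dose arm, as reported for [18F]FTC-146 imaging of sigma-1 receptor
#' occupancy by orally dosed blarcamesine (with a PRE-084 reference arm).
#' Occupancy is `NA` for vehicle by construction. These group means drive
#' the generator calibration and the internal-consistency identity
#' `Vs = Vt * BP / (1 + BP)`.
#'
#' @return Data frame with columns `genotype, drug, dose, bp_mean, bp_sd,
#'   vt_mean, vt_sd, vs_mean, vs_sd, ro_mean, ro_sd, pctidg_mean,
#'   pctidg_sd`.
#' @export
reference_group_means <- function() {
  d <- rbind(
    c("WT", "PRE-084", 1, 0.78, 0.12, 13.82, 1.19, 6.01, 0.14,
      17.64, 6.57, 7.64, 0.24),
    c("WT", "blarcamesine", 0, 1.02, 0.17, 15.27, 3.48, 7.67, 1.81,
      NA, NA, 7.75, 0.94),
    c("WT", "blarcamesine", 1, 0.81, 0.11, 13.64, 2.15, 6.03, 0.68,
      14.30, 7.63, 6.15, 0.94),
    c("WT", "blarcamesine", 10, 0.34, 0.09, 7.93, 1.82, 2.02, 0.80,
      62.63, 10.23, 3.39, 0.84),
    c("WT", "blarcamesine", 30, 0.32, 0.11, 8.16, 1.80, 2.03, 0.92,
      64.44, 11.89, 3.48, 0.65),
    c("KO", "blarcamesine", 0, 0.88, 0.07, 15.75, 2.24, 7.33, 0.80,
      NA, NA, 7.64, 1.38),
    c("KO", "blarcamesine", 1, 0.85, 0.18, 12.02, 0.21, 5.23, 0.22,
      10.61, 5.25, 5.27, 0.81),
    c("KO", "blarcamesine", 10, 0.51, 0.17, 9.34, 0.85, 3.12, 0.97,
      41.15, 19.93, 3.73, 0.83),
    c("KO", "blarcamesine", 30, 0.31, 0.07, 8.25, 0.66, 1.93, 0.36,
      64.29, 8.56, 3.21, 0.62)
  )
  out <- data.frame(
    genotype = d[, 1], drug = d[, 2],
    apply(d[, 3:13, drop = FALSE], 2, as.numeric),
    stringsAsFactors = FALSE
  )
  names(out) <- c("genotype", "drug", "dose", "bp_mean", "bp_sd",
                  "vt_mean", "vt_sd", "vs_mean", "vs_sd", "ro_mean",
                  "ro_sd", "pctidg_mean", "pctidg_sd")
  out
}
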
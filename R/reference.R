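#' Reference Nelore genetic-parameter estimates
#'
#' Posterior-mean variance components, heritabilities and the genetic
#' correlations of the profitability traits with the auxiliary traits, as
#' estimated in commercial Nelore feedlot populations. These values are the
#' package's calibration surface: the synthetic-data generator and the
#' validation studies use them as simulation truth, and the descriptive
#' targets (e.g. AFP mean 151.84 $, DMI mean 8.06 kg/day over an 80-day
#' window) anchor the feedlot-log defaults.
#'
#' `components`: trait, additive variance (var_a), residual variance
#' (var_e) and the published heritability (h2) with its rounding
#' consistency at 2 decimal places (`h2_consistent`: whether
#' var_a/(var_a+var_e) reproduces the printed h2).
#' `genetic_correlations`: genetic correlations of AFP and PFT with the
#' other traits.
#'
#' @return list with data.frames `components`, `genetic_correlations` and
#'   the descriptive `table1` summary (trait means/SDs).
#' @export
nelore_reference <- function() {
  components <- data.frame(
    trait = c("AFP", "PFT", "W450", "DMI", "RFI", "RG", "REA", "RFT",
              "FRAME", "PPC30", "STAY", "AFC", "ACP", "SC365", "APM"),
    var_a = c(6321.23, 10.42, 292.87, 0.23, 0.07, 0.0004, 11.81, 0.52,
              0.55, 0.46, 0.20, 2.36, 162.28, 1.15, 5.79),
    var_e = c(28687.29, 448.46, 539.77, 0.62, 0.41, 0.03, 26.02, 1.13,
              1.17, 1.00, 1.00, 20.77, 514.36, 1.96, 7.51),
    h2 = c(0.18, 0.02, 0.35, 0.27, 0.15, 0.12, 0.31, 0.31,
           0.32, 0.31, 0.16, 0.10, 0.24, 0.36, 0.43),
    stringsAsFactors = FALSE)
  components$h2_consistent <-
    round(components$var_a / (components$var_a + components$var_e), 2) ==
    components$h2
  genetic_correlations <- data.frame(
    profit_trait = rep(c("AFP", "PFT"), each = 13),
    trait = rep(c("W450", "DMI", "RFI", "RG", "REA", "RFT", "FRAME",
                  "PPC30", "STAY", "AFC", "ACP", "SC365", "APM"), 2),
    r = c(0.65, 0.72, 0.28, 0.83, 0.43, -0.10, 0.44,
          0.16, 0.42, -0.19, -0.14, -0.05, -0.21,
          0.64, 0.26, -0.23, 0.88, 0.44, -0.68, 0.77,
          0.73, 0.76, -0.47, -0.01, -0.06, -0.03),
    stringsAsFactors = FALSE)
  table1 <- data.frame(
    trait = c("AFP", "PFT", "DMI"),
    mean = c(151.84, 36.21, 8.06),
    sd = c(66.45, 9.75, 1.87),
    stringsAsFactors = FALSE)
  list(components = components,
       genetic_correlations = genetic_correlations,
       table1 = table1)
}
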
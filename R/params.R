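#' Reference trait parameters for the maize seedling phosphorus trial
#'
#' Published per-trait summaries for a panel of 151 tropical maize inbred
#' lines phenotyped at seedling stage under applied (AP) and non-applied
#' (NAP) phosphorus: genotypic means per condition, residual coefficients
#' of variation, percentage reduction of the mean under P stress, and
#' REML variance components with broad-sense heritabilities from the
#' per-condition and combined mixed-model analyses.
#'
#' These values serve two purposes: they are the default parameterization
#' of [sim_config()] (so simulated panels carry realistic magnitudes for
#' every trait), and they let the heritability / CV / reduction arithmetic
#' be checked against an externally reported table.
#'
#' Units: SD and RAD in mm; PH, DG, LRL and TRL in cm; SDW, RDW and TDW in
#' mg; RSR in mg/mg; RSA in cm^2; RV in cm^3; RTD in mg/cm^3.  Variances
#' are on the squared trait scale.
#'
#' @return A data frame with one row per trait and columns
#'   `trait`, `mean_nap`, `mean_ap`, `cv_nap`, `cv_ap`, `reduction_pct`,
#'   `varG_nap`, `varE_nap`, `h2_nap`, `varG_ap`, `varE_ap`, `h2_ap`,
#'   `varG_comb`, `varGxP_comb`, `varE_comb`, `h2_comb`.
#' @export
#' @examples
#' p <- maize_trait_params()
#' p[p$trait == "SD", c("varG_nap", "varE_nap", "h2_nap")]
maize_trait_params <- function() {
  df <- data.frame(
    trait = c("SD", "PH", "SDW", "RDW", "RSR", "TDW", "DG",
              "LRL", "TRL", "RSA", "RV", "RAD", "RTD"),
    mean_nap = c(4.49, 10.99, 665.49, 359.00, 0.55, 1024.48, 0.31,
                 1048.99, 1569.73, 266.30, 3.65, 0.55, 99.15),
    mean_ap = c(8.70, 18.09, 1701.13, 525.17, 0.32, 2226.29, 0.70,
                1533.24, 2297.37, 426.40, 6.38, 0.59, 82.83),
    cv_nap = c(12.81, 13.20, 17.79, 16.67, 12.29, 16.52, 14.97,
               21.79, 18.17, 16.03, 17.29, 7.72, 8.26),
    cv_ap = c(8.23, 8.49, 17.96, 18.65, 15.96, 16.53, 8.22,
              21.04, 17.55, 14.14, 16.01, 8.79, 12.18),
    reduction_pct = c(48.32, 39.22, 60.88, 31.64, -73.91, 53.98, 56.34,
                      31.58, 31.67, 37.55, 42.81, 7.61, -19.70),
    varG_nap = c(0.31, 2.78, 19301, 6216, 1.10e-2, 38787, 2.77e-3,
                 60534, 92465, 2387, 0.60, 2.50e-3, 98.63),
    varE_nap = c(0.33, 2.11, 14023, 3582, 4.66e-3, 28632, 2.10e-3,
                 52250, 81310, 1822, 0.40, 1.79e-3, 67.04),
    h2_nap = c(0.74, 0.80, 0.81, 0.84, 0.88, 0.80, 0.80,
               0.78, 0.77, 0.80, 0.82, 0.81, 0.82),
    varG_ap = c(1.35, 8.26, 283212, 20261, 2.32e-3, 438747, 8.16e-3,
                70003, 165270, 8260, 2.79, 1.83e-3, 40.90),
    varE_ap = c(0.51, 2.36, 93362, 9588, 2.59e-3, 135469, 3.31e-3,
                104060, 162570, 3637, 1.04, 2.72e-3, 101.80),
    h2_ap = c(0.89, 0.91, 0.90, 0.86, 0.73, 0.91, 0.88,
              0.67, 0.75, 0.87, 0.89, 0.67, 0.55),
    varG_comb = c(0.16, 2.76, 31094, 4208, 3.46e-3, 48953, 2.30e-3,
                  38754, 64782, 2186, 0.67, 1.47e-3, 46.56),
    varGxP_comb = c(0.67, 2.76, 120162, 9031, 3.19e-3, 189815, 3.16e-3,
                    26515, 64086, 3140, 1.02, 6.95e-4, 23.21),
    varE_comb = c(0.42, 2.23, 53692, 6585, 3.62e-3, 82051, 2.70e-3,
                  78154, 121939, 2730, 0.72, 2.25e-3, 84.41),
    h2_comb = c(0.29, 0.61, 0.31, 0.43, 0.61, 0.31, 0.53,
                0.60, 0.55, 0.52, 0.51, 0.67, 0.64),
    stringsAsFactors = FALSE
  )
  df
}

#' Named trait presets
#'
#' `"paper8"` is the eight-trait set retained after variance-inflation
#' pruning in the reference trial (stalk diameter, plant height,
#' root:shoot ratio, daily growth, lateral root length, root volume,
#' root average diameter, root tissue density); `"all13"` is the full
#' measured + derived trait set.
#'
#' @param preset one of `"paper8"`, `"all13"`.
#' @return character vector of trait names.
#' @export
#' @examples
#' trait_preset("paper8")
trait_preset <- function(preset = c("paper8", "all13")) {
  preset <- match.arg(preset)
  switch(preset,
    paper8 = c("SD", "PH", "RSR", "DG", "LRL", "RV", "RAD", "RTD"),
    all13  = maize_trait_params()$trait
  )
}
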
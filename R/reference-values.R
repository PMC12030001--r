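#' Published variance components of the emulated maize trial
#'
#' Variance-component estimates reported for the three-year, 16-hybrid,
#' four-replicate field trial whose statistical structure the synthetic
#' generator emulates: the four observed traits (grain yield, grain
#' moisture, Fv/Fm, PI_ABS) and the four fluorescence-predicted traits
#' (each source trait predicted from the 58 biophysical parameters or
#' from the 118 raw transients). These values serve as calibration
#' targets for [defaultTrialConfig()] and as worked examples for
#' [heritability()].
#'
#' @return data.frame with columns \code{trait, sigma2_G, sigma2_E,
#'   sigma2_GxE, sigma2_e, nE, nR}.
#' @examples
#' rv <- referenceVarianceComponents()
#' gm <- rv[rv$trait == "gm", ]
#' heritability(varianceComponents(gm$sigma2_G, gm$sigma2_GxE,
#'                                 gm$sigma2_e, nE = gm$nE, nR = gm$nR))
#' @export
referenceVarianceComponents <- function() {
  data.frame(
    trait = c("gy", "gm", "fvfm", "piabs",
              "gy_parameters", "gm_parameters",
              "gy_transients", "gm_transients"),
    sigma2_G   = c(0.553, 1.296, 5.88e-6, 0.120,
                   0.036, 0.29686, 0.080, 0.032),
    sigma2_E   = c(2.124, 25.335, 1.02e-5, 0.622,
                   0.191, 8.053031, 1.156, 10.087),
    sigma2_GxE = c(0.307, 2.209, 7.17e-5, 0.003,
                   0.001, 0.81675, 0.137, 1.650),
    sigma2_e   = c(2.593, 0.795, 2.97e-5, 0.272,
                   0.233, 4.19772, 0.409, 2.996),
    nE = 3L, nR = 4L,
    stringsAsFactors = FALSE)
}
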
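# Single registry of physical constants. Nothing outside this file may
# restate a numeric physical constant.

## unit conversions
MEV_TO_J <- 1.602176634e-13        # 1 MeV in joule
MEV_PER_G_TO_GY <- 1.602176634e-10 # 1 MeV/g in gray (J/kg)
CM_TO_M <- 1e-2
MM_TO_M <- 1e-3

## water at room temperature
WATER_SOUND_SPEED <- 1492   # m/s, tank-calibrated value
WATER_C_P <- 4186           # J kg^-1 K^-1
WATER_RHO <- 1000           # kg m^-3
WATER_RHO_G_CM3 <- 1        # g cm^-3, used by the cm/MeV dose module
WATER_ALPHA_EXP <- 2.07e-4  # K^-1, volumetric thermal expansion (~20 C)

## default acquisition
DEFAULT_FS <- 1e7           # Hz, 10 MS/s
DEFAULT_DURATION <- 5e-4    # s, 500 us records

#' Physical constants used by the package
#'
#' Returns the registry of physical constants (water properties, unit
#' conversions, default acquisition settings) as a named list. All
#' package code draws its constants from this single registry.
#'
#' @return Named list of constants.
#' @export
#' @examples
#' braggloc_constants()$c_water
braggloc_constants <- function() {
  list(
    mev_to_j = MEV_TO_J,
    mev_per_g_to_gy = MEV_PER_G_TO_GY,
    c_water = WATER_SOUND_SPEED,
    C_p_water = WATER_C_P,
    rho_water = WATER_RHO,
    alpha_exp_water = WATER_ALPHA_EXP,
    default_fs = DEFAULT_FS,
    default_duration = DEFAULT_DURATION
  )
}
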
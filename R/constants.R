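#' Thermal voltage kT/e in millivolts
#'
#' Converts an absolute temperature to the thermal voltage used throughout
#' the voltage-activation formalism, kT/e = k_B T / e expressed in mV.
#' At the recording temperature used as the package default (24 degrees C,
#' 297.15 K) this is 25.61 mV.
#'
#' @param temperature_K Absolute temperature in kelvin.
#' @return Thermal voltage in mV.
#' @examples
#' kT_mV(297.15) # 25.61 mV
#' @export
kT_mV <- function(temperature_K) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  # k_B / e = 0.08617333262 mV/K
  0.08617333262 * temperature_K
}

# Default recording temperature, 24 degrees C.
.GK_TEMPERATURE_K <- 297.15

# Conversion factor: 1 eV (= 1 e0 x 1 V) in kcal/mol.
.GK_EV_TO_KCAL_MOL <- 23.0609
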
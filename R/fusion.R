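#' Gibbs energy of fusion at a working temperature
#'
#' The free-energy penalty for transferring the crystalline solute into a
#' hypothetical supercooled liquid at temperature `T`, using the standard
#' simplification that the heat-capacity change upon melting is negligible:
#'
#' \deqn{\Delta_{fus}G(T) = \Delta_{fus}H \, (1 - T/T_m)}
#'
#' The raw value is clamped at zero — above the melting point the solute is
#' already a liquid and no penalty applies.  The clamped value is the one
#' entering the saturation equation; the raw (possibly negative) value is
#' kept for diagnostics.
#'
#' @param solute A solute name (looked up in [example_solutes()]), a one-row
#'   solute tibble, or a list with `tm` (K) and `hfus` (kJ/mol).
#' @param temperature Working temperature in kelvin, positive.  Vectorised.
#' @return A tibble with columns `temperature`, `raw_gibbs_fusion` and
#'   `gibbs_fusion` (both kJ/mol).
#' @export
#' @examples
#' gibbs_fusion("benzamide", 298.15)
gibbs_fusion <- function(solute, temperature) {
  solute <- as_solute(solute)
  stopifnot(is.numeric(temperature), all(temperature > 0))
  raw <- solute$hfus * (1 - temperature / solute$tm)
  tibble(
    temperature = temperature,
    raw_gibbs_fusion = raw,
    gibbs_fusion = pmax(0, raw)
  )
}

#' Ideal saturation mole fraction
#'
#' The solubility obtained when the saturated solution is ideal (activity
#' coefficient 1): \eqn{x^{id} = \exp(-\Delta_{fus}G / RT)}.  Because the
#' fusion free energy is clamped at zero above the melting point, the ideal
#' solubility saturates at 1 there (complete miscibility of two liquids in
#' the ideal limit).
#'
#' @inheritParams gibbs_fusion
#' @return A numeric vector of mole fractions in `(0, 1]`, one per
#'   temperature.
#' @export
#' @examples
#' ideal_solubility("benzamide", 298.15) # about 0.115
ideal_solubility <- function(solute, temperature) {
  fs <- gibbs_fusion(solute, temperature)
  exp(-(fs$gibbs_fusion * 1000) / (R_GAS * temperature))
}

# Thermodynamic activity of the solid at saturation, a = gamma * x; the
# quantity the fixed-point solver drives gamma*x toward.
activity_target <- function(solute, temperature) {
  ideal_solubility(solute, temperature)
}
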
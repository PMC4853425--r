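## Physical constants used throughout. Energies are kcal/mol, distances
## Angstrom unless a function documents otherwise; sedimentation works in CGS.

#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
.RGAS_KCAL <- 1.987204258640832e-3

#' Gas constant in erg mol^-1 K^-1 (CGS), for sedimentation exponents
#' @keywords internal
.RGAS_CGS <- 8.31446261815324e7

#' Avogadro constant, mol^-1
#' @keywords internal
.AVOGADRO <- 6.02214076e23

## Volume per molecule (Angstrom^3) at 1 M standard concentration
.V_STANDARD_A3 <- 1e27 / .AVOGADRO

#' Thermal energy RT in kcal/mol
#' @param temperature temperature in K
#' @return RT in kcal/mol
#' @export
thermalRT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .RGAS_KCAL * temperature
}

## Overflow-safe log(sum(exp(x)))
logSumExp <- function(x) {
  if (length(x) == 0L) stop("logSumExp: empty input")
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
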
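# physical constants (SI)
GAS_R <- 8.314462618      # J mol-1 K-1
FARADAY <- 96485.33212    # C mol-1
ATM_PA <- 101325          # Pa per standard atmosphere

#' Construct a redox couple
#'
#' @param name couple name.
#' @param e0PrimeMv standard (midpoint) potential at pH 7, 25 C, in mV.
#' @param nElectrons electrons per reaction (>= 1).
#' @param protonsPerReaction protons per reaction (per nElectrons transfer).
#' @return a [RedoxCouple-class].
#' @export
redoxCouple <- function(name, e0PrimeMv, nElectrons, protonsPerReaction) {
  new("RedoxCouple", name = name, e0PrimeMv = e0PrimeMv,
      nElectrons = as.integer(nElectrons),
      protonsPerReaction = as.integer(protonsPerReaction))
}

#' The NAD+/NADH couple
#'
#' E0' = -320 mV at pH 7, 25 C; 2 electrons, 1 proton
#' (NAD+ + H+ + 2 e- -> NADH).
#' @param e0PrimeMv override for the standard potential.
#' @return a [RedoxCouple-class].
#' @export
nadCouple <- function(e0PrimeMv = -320) {
  redoxCouple("NAD+/NADH", e0PrimeMv, 2L, 1L)
}

#' The 2H+/H2 couple
#'
#' E0' = -414 mV at pH 7, 25 C; 2 electrons, 2 protons
#' (2 H+ + 2 e- -> H2).
#' @param e0PrimeMv override for the standard potential.
#' @return a [RedoxCouple-class].
#' @export
h2Couple <- function(e0PrimeMv = -414) {
  redoxCouple("2H+/H2", e0PrimeMv, 2L, 2L)
}

#' Assay conditions for equilibrium calculations
#'
#' @param temperatureK absolute temperature (default 298.15 K, 25 C).
#' @param pH solution pH (default 7.5, the assay buffer pH).
#' @param referencePressurePa standard-state pressure (default 101325 Pa,
#'   1 atm).
#' @return a list of validated conditions.
#' @export
standardConditions <- function(temperatureK = 298.15, pH = 7.5,
                               referencePressurePa = ATM_PA) {
  stopifnot(temperatureK > 0, pH > 0, pH < 14, referencePressurePa > 0)
  list(temperatureK = temperatureK, pH = pH,
       referencePressurePa = referencePressurePa)
}

# Nernst slope ln(10) R T / F in mV (59.16 mV at 298.15 K)
nernstSlopeMv <- function(temperatureK) {
  1000 * log(10) * GAS_R * temperatureK / FARADAY
}

#' Half-cell potential from the Nernst equation
#'
#' \deqn{E = E_0' - s \frac{m}{n} (pH - 7) + \frac{s}{n}\log_{10}
#'   \frac{[ox]}{[red]}}
#' with s the Nernst slope (ln(10) R T / F, in mV), n the electron and m the
#' proton stoichiometry of the couple. For a gas-evolving couple such as
#' 2H+/H2, supply the gas partial pressure instead: [ox]/[red] is taken as
#' the reciprocal of p divided by the reference pressure.
#'
#' @param couple a [RedoxCouple-class].
#' @param conditions from [standardConditions()].
#' @param ratioOxRed oxidized-over-reduced activity ratio (> 0).
#' @param pGasPa gas partial pressure in Pa (> 0); alternative to
#'   \code{ratioOxRed}.
#' @return potential in mV.
#' @export
nernstPotential <- function(couple, conditions = standardConditions(),
                            ratioOxRed = NULL, pGasPa = NULL) {
  stopifnot(is(couple, "RedoxCouple"))
  if (is.null(ratioOxRed) == is.null(pGasPa))
    stop("supply exactly one of ratioOxRed or pGasPa")
  if (!is.null(pGasPa)) {
    if (any(pGasPa <= 0)) stop("gas partial pressure must be positive")
    ratioOxRed <- 1 / (pGasPa / conditions$referencePressurePa)
  }
  if (any(ratioOxRed <= 0)) stop("ratioOxRed must be positive")
  s <- nernstSlopeMv(conditions$temperatureK)
  n <- couple@nElectrons
  couple@e0PrimeMv -
    s * (couple@protonsPerReaction / n) * (conditions$pH - 7) +
    (s / n) * log10(ratioOxRed)
}

#' Equilibrium hydrogen partial pressure for a NADH/NAD+ ratio
#'
#' Solves E_NAD(ratio, pH) = E_H2(p, pH) in closed form for the hydrogen
#' partial pressure at which NADH-driven proton reduction
#' (NADH + H+ <-> NAD+ + H2) is at equilibrium. Because both couples carry
#' two electrons, the equilibrium pressure is exactly proportional to the
#' NADH/NAD+ ratio.
#'
#' @param ratioNadhNad NADH over NAD+ concentration ratio (> 0); vectorized.
#' @param conditions from [standardConditions()].
#' @param nad,h2 the two [RedoxCouple-class] half-cells.
#' @return data.frame with columns \code{ratio_nadh_nad}, \code{p_h2_Pa} and
#'   \code{E_couple_mV} (the common potential at equilibrium).
#' @export
equilibriumH2Pressure <- function(ratioNadhNad,
                                  conditions = standardConditions(),
                                  nad = nadCouple(), h2 = h2Couple()) {
  if (any(ratioNadhNad <= 0)) stop("ratioNadhNad must be positive")
  s <- nernstSlopeMv(conditions$temperatureK)
  eNad <- nernstPotential(nad, conditions, ratioOxRed = 1 / ratioNadhNad)
  # E_H2(p) = E0h - s (m/n)(pH-7) - (s/n) log10(p/p0) = eNad
  nH <- h2@nElectrons
  e0hTerm <- h2@e0PrimeMv -
    s * (h2@protonsPerReaction / nH) * (conditions$pH - 7)
  log10p <- (e0hTerm - eNad) * nH / s
  p <- conditions$referencePressurePa * 10^log10p
  data.frame(ratio_nadh_nad = ratioNadhNad, p_h2_Pa = p, E_couple_mV = eNad)
}

#' NADH/NAD+ ratio at equilibrium with a hydrogen partial pressure
#'
#' Exact closed-form inverse of [equilibriumH2Pressure()]: the ratio at
#' which the given hydrogen pressure is the equilibrium pressure.
#'
#' @param pH2Pa hydrogen partial pressure in Pa (> 0); vectorized.
#' @param conditions from [standardConditions()].
#' @param nad,h2 the two [RedoxCouple-class] half-cells.
#' @return positive NADH/NAD+ ratio(s).
#' @export
ratioForPressure <- function(pH2Pa, conditions = standardConditions(),
                             nad = nadCouple(), h2 = h2Couple()) {
  if (any(pH2Pa <= 0)) stop("pH2Pa must be positive")
  # proportionality: p(r) = p(1) * r for the two-electron couples
  p1 <- equilibriumH2Pressure(1, conditions, nad, h2)$p_h2_Pa
  pH2Pa / p1
}

#' Moles of gas in a headspace from the ideal gas law
#'
#' n = p V / (R T), reported in nanomoles.
#'
#' @param pPa partial pressure in Pa.
#' @param headspaceVolumeL headspace volume in litres.
#' @param temperatureK absolute temperature.
#' @return amount in nmol.
#' @export
headspaceAmount <- function(pPa, headspaceVolumeL, temperatureK = 298.15) {
  stopifnot(all(pPa >= 0), headspaceVolumeL > 0, temperatureK > 0)
  pPa * (headspaceVolumeL / 1000) / (GAS_R * temperatureK) * 1e9
}
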
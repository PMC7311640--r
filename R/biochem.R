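# average (not monoisotopic) residue masses in Da; one water is added per
# chain. Average masses match kDa-scale predictions from sequence.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Predicted molecular mass of a protein from its sequence
#'
#' Sum of standard average residue masses plus one water, in kDa. Unknown
#' residues (X) have no defined mass and are an error.
#'
#' @param seq sequence (forms accepted by [globalAlign()]).
#' @return mass in kDa.
#' @export
proteinMassKda <- function(seq) {
  r <- .asRecord(seq, "seq")
  chars <- strsplit(r$seq, "")[[1]]
  if (any(chars == "X"))
    stop("sequence contains X: mass undefined")
  bad <- setdiff(chars, names(AA_RESIDUE_MASS))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  (sum(AA_RESIDUE_MASS[chars]) + WATER_MASS) / 1000
}

#' Default side-chain and terminal pKa values (EMBOSS set)
#'
#' pI values are pKa-table dependent; this single published set ships as
#' the default and can be overridden wholesale.
#'
#' @return named numeric vector with entries Nterm, Cterm, C, D, E, H, K,
#'   R, Y.
#' @export
defaultPkaTable <- function() {
  c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

# net charge of a protein at a given pH (Henderson-Hasselbalch over the
# ionizable side chains and the two termini)
.netCharge <- function(pH, counts, pka) {
  pos <- function(pk, n) n / (1 + 10^(pH - pk))
  neg <- function(pk, n) -n / (1 + 10^(pk - pH))
  pos(pka[["Nterm"]], 1) + pos(pka[["H"]], counts[["H"]]) +
    pos(pka[["K"]], counts[["K"]]) + pos(pka[["R"]], counts[["R"]]) +
    neg(pka[["Cterm"]], 1) + neg(pka[["C"]], counts[["C"]]) +
    neg(pka[["D"]], counts[["D"]]) + neg(pka[["E"]], counts[["E"]]) +
    neg(pka[["Y"]], counts[["Y"]])
}

#' Theoretical isoelectric point of a protein
#'
#' Bisection root of the net-charge curve (Henderson-Hasselbalch over
#' D, E, C, Y, H, K, R and the termini) to 1e-4 pH units.
#'
#' @param seq sequence (forms accepted by [globalAlign()]).
#' @param pkaTable named pKa vector; default [defaultPkaTable()].
#' @return the pI (pH at zero net charge).
#' @export
theoreticalPi <- function(seq, pkaTable = defaultPkaTable()) {
  r <- .asRecord(seq, "seq")
  chars <- strsplit(r$seq, "")[[1]]
  counts <- vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                   function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (.netCharge(mid, counts, pkaTable) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Specific enzyme activity from a spectrophotometric assay
#'
#' U = umol substrate converted per minute. From the Beer-Lambert relation,
#' \code{(dA/min) / (epsilon * path)} gives mM/min = umol/ml/min in the
#' cuvette, scaled by the assay volume and divided by protein amount and an
#' optional electron-stoichiometry factor (e.g. 2 for two one-electron
#' viologen reductions per H2).
#'
#' @param deltaAPerMin absorbance change per minute.
#' @param epsilonMMcm extinction coefficient in mM-1 cm-1 (e.g. 6.2 for NADH
#'   at 340 nm, 13.1 for ferredoxin at 430 nm, 10.0 for methyl viologen at
#'   600 nm).
#' @param pathCm light path in cm (default 1).
#' @param volumeMl assay volume in ml (default 1).
#' @param proteinMg protein in the assay, mg (> 0).
#' @param stoichFactor substrate-per-chromophore stoichiometry divisor
#'   (default 1).
#' @return specific activity in U per mg.
#' @export
specificActivity <- function(deltaAPerMin, epsilonMMcm, pathCm = 1,
                             volumeMl = 1, proteinMg, stoichFactor = 1) {
  stopifnot(deltaAPerMin > 0, epsilonMMcm > 0, pathCm > 0, volumeMl > 0,
            stoichFactor > 0)
  if (proteinMg <= 0) stop("specific activity undefined for zero protein")
  (deltaAPerMin / (epsilonMMcm * pathCm)) * volumeMl / proteinMg /
    stoichFactor
}

#' Purification table statistics
#'
#' Per-step specific activity, purification fold relative to the first step
#' and percent yield relative to the first step.
#'
#' @param steps data.frame with columns \code{name},
#'   \code{total_protein_mg}, \code{total_activity_U}; the first row is the
#'   starting material and must have positive protein and activity.
#' @return the input with added columns \code{specific_activity_U_mg},
#'   \code{fold} and \code{yield_pct}.
#' @export
purificationStats <- function(steps) {
  if (!is.data.frame(steps) || nrow(steps) == 0L)
    stop("steps must be a non-empty data.frame")
  need <- c("name", "total_protein_mg", "total_activity_U")
  if (!all(need %in% colnames(steps)))
    stop("steps must have columns ", paste(need, collapse = ", "))
  if (steps$total_protein_mg[1] <= 0 || steps$total_activity_U[1] <= 0)
    stop("first step must have positive protein and activity")
  sa <- steps$total_activity_U / steps$total_protein_mg
  steps$specific_activity_U_mg <- sa
  steps$fold <- sa / sa[1]
  steps$yield_pct <- 100 * steps$total_activity_U / steps$total_activity_U[1]
  steps
}

#' Per-subcomplex value from a per-complex measurement
#'
#' E.g. iron per alpha2beta2 heterotetramer divided by 2 gives iron per
#' alphabeta heterodimer.
#'
#' @param valuePerComplex measured value per complex.
#' @param subcomplexesPerComplex number of subcomplexes (>= 1).
#' @return value per subcomplex (unrounded; see [roundReport()] for the
#'   1-decimal reporting convention).
#' @export
perSubcomplex <- function(valuePerComplex, subcomplexesPerComplex) {
  stopifnot(subcomplexesPerComplex >= 1)
  valuePerComplex / subcomplexesPerComplex
}

#' Half-up rounding for reported values
#'
#' Deterministic round-half-up at a fixed number of decimals (R's
#' \code{round} rounds half to even), matching the 1-decimal reporting
#' convention used for stoichiometry values (35.85 -> 35.9).
#'
#' @param x numeric vector.
#' @param digits decimals to keep (default 1).
#' @return rounded numeric vector.
#' @export
roundReport <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
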
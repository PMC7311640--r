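#' @import methods
NULL

# 20 standard amino acids plus X (unknown); the gap sentinel is "-".
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_ALPHABET20, "X")

#' Gap sentinel used throughout the package
#'
#' Reference positions that align to a gap in a query are reported as this
#' explicit one-character token, never as 0, NA-coerced integers or an empty
#' string.
#' @export
GAP <- "-"

#' PositionMap: reference-frame coordinate map
#'
#' An injective, monotone mapping from 1-based residue numbers of a reference
#' sequence (e.g. T. maritima HydB numbering) to 1-based positions of a query
#' homolog, derived from a pairwise global alignment. Reference positions
#' that align to a gap in the query carry \code{NA_integer_} internally and
#' are reported as [GAP] by accessors.
#'
#' @slot refId single identifier of the reference sequence.
#' @slot queryId single identifier of the query sequence.
#' @slot queryPos integer vector of length equal to the reference length;
#'   element i is the query position aligned to reference position i, or NA.
#' @export
setClass("PositionMap",
  representation(refId = "character", queryId = "character",
                 queryPos = "integer"))

setValidity("PositionMap", function(object) {
  msg <- character()
  if (length(object@refId) != 1L || length(object@queryId) != 1L)
    msg <- c(msg, "refId and queryId must be single strings")
  qp <- object@queryPos
  if (length(qp) == 0L)
    msg <- c(msg, "queryPos must be non-empty (covers 1..len(reference))")
  nz <- qp[!is.na(qp)]
  if (length(nz) && (any(nz < 1L) || any(diff(nz) <= 0L)))
    msg <- c(msg, "non-gap query positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' AlignedPair: a pairwise global alignment
#'
#' Equal-length gapped strings for the two sequences plus the optimal score
#' under the substitution scheme that produced it. Removing gaps recovers the
#' input sequences exactly and no column is gap-gap.
#'
#' @slot aId,bId sequence identifiers.
#' @slot aAligned,bAligned gapped strings of equal length.
#' @slot score alignment score (affine gap convention: a gap run of length L
#'   costs \code{gapOpen + L * gapExtend}).
#' @export
setClass("AlignedPair",
  representation(aId = "character", bId = "character",
                 aAligned = "character", bAligned = "character",
                 score = "numeric"))

setValidity("AlignedPair", function(object) {
  a <- object@aAligned; b <- object@bAligned
  if (length(a) != 1L || length(b) != 1L)
    return("aAligned and bAligned must be single strings")
  if (nchar(a) != nchar(b))
    return("aligned strings must have equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (any(av == GAP & bv == GAP))
    return("gap-gap columns are not allowed")
  TRUE
})

#' ClusterHits: iron-sulfur cluster annotations for one sequence
#'
#' Non-overlapping candidate cofactor-binding regions detected from cysteine
#' spacing motifs, in N-to-C order. Types are \code{FeS4} ([4Fe-4S], 4 Fe),
#' \code{FeS2} ([2Fe-2S], 2 Fe) and \code{HCLUSTER} (H-cluster, 6 Fe).
#'
#' @slot seqId identifier of the scanned sequence.
#' @slot type character vector of cluster types.
#' @slot start,end 1-based inclusive spans.
#' @slot feAtoms iron atoms contributed by each cluster (2, 4 or 6).
#' @slot cysPositions list of strictly increasing cysteine positions, all
#'   within the span and all C in the sequence.
#' @export
setClass("ClusterHits",
  representation(seqId = "character", type = "character",
                 start = "integer", end = "integer",
                 feAtoms = "integer", cysPositions = "list"))

CLUSTER_FE <- c(FeS2 = 2L, FeS4 = 4L, HCLUSTER = 6L)

setValidity("ClusterHits", function(object) {
  n <- length(object@type)
  if (length(object@start) != n || length(object@end) != n ||
      length(object@feAtoms) != n || length(object@cysPositions) != n)
    return("all annotation slots must have equal length")
  if (n == 0L) return(TRUE)
  if (!all(object@type %in% names(CLUSTER_FE)))
    return("unknown cluster type")
  if (!identical(object@feAtoms, unname(CLUSTER_FE[object@type])))
    return("feAtoms must be 2 (FeS2), 4 (FeS4) or 6 (HCLUSTER)")
  if (any(object@start > object@end))
    return("start must not exceed end")
  for (i in seq_len(n)) {
    cp <- object@cysPositions[[i]]
    if (any(cp < object@start[i]) || any(cp > object@end[i]) ||
        (length(cp) > 1L && any(diff(cp) <= 0L)))
      return("cysPositions must be strictly increasing within [start, end]")
  }
  if (n > 1L && any(object@start[-1L] <= object@end[-n]))
    return("annotations must be non-overlapping and in N-to-C order")
  TRUE
})

#' FingerprintRule: one diagnostic residue criterion
#'
#' A named criterion over one or more reference-frame positions with the
#' residue sets (or exact motif) characteristic of electron-bifurcating (BF)
#' versus non-bifurcating (non-BF) beta subunits.
#'
#' @slot name rule identifier, e.g. \code{nadh_site_232}.
#' @slot refPositions strictly increasing 1-based positions in the reference
#'   (HydB) frame.
#' @slot bfAllowed residues allowed for BF (single-position rules) or a single
#'   exact motif string when \code{motif} is TRUE.
#' @slot nonbfAllowed residues allowed for non-BF, or \code{"*"} meaning
#'   anything that is not the BF motif and contains no gap.
#' @slot motif TRUE when bfAllowed is an exact multi-position motif.
#' @export
setClass("FingerprintRule",
  representation(name = "character", refPositions = "integer",
                 bfAllowed = "character", nonbfAllowed = "character",
                 motif = "logical"))

setValidity("FingerprintRule", function(object) {
  if (length(object@name) != 1L || nchar(object@name) == 0L)
    return("name must be a single non-empty string")
  rp <- object@refPositions
  if (length(rp) == 0L || any(rp < 1L) ||
      (length(rp) > 1L && any(diff(rp) <= 0L)))
    return("refPositions must be non-empty and strictly increasing")
  if (length(object@motif) != 1L)
    return("motif must be a single flag")
  if (object@motif) {
    if (length(object@bfAllowed) != 1L ||
        nchar(object@bfAllowed) != length(rp))
      return("motif rules need one BF motif string spanning refPositions")
  } else {
    if (length(intersect(object@bfAllowed, object@nonbfAllowed)))
      return("bfAllowed and nonbfAllowed residue sets must be disjoint")
  }
  TRUE
})

#' ClassificationResult: per-sequence verdict with evidence
#'
#' @slot seqId identifier of the classified sequence.
#' @slot evidence data.frame with columns \code{rule}, \code{observed},
#'   \code{verdict} (BF / nonBF / indeterminate), one row per rule.
#' @slot fesSupport extra iron-sulfur cluster count relative to the reference
#'   (advisory, never part of the decision rule).
#' @slot overall BF, nonBF or ambiguous.
#' @slot identity coverage-weighted identity: identical columns of the
#'   query/reference alignment divided by the reference length.
#' @slot note free-text reason, e.g. for a refuse-to-classify result.
#' @export
setClass("ClassificationResult",
  representation(seqId = "character", evidence = "data.frame",
                 fesSupport = "integer", overall = "character",
                 identity = "numeric", note = "character"))

setValidity("ClassificationResult", function(object) {
  if (!all(c("rule", "observed", "verdict") %in% colnames(object@evidence)))
    return("evidence must have columns rule, observed, verdict")
  if (!object@overall %in% c("BF", "nonBF", "ambiguous"))
    return("overall must be BF, nonBF or ambiguous")
  bad <- grepl(GAP, object@evidence$observed, fixed = TRUE) &
    object@evidence$verdict != "indeterminate"
  if (any(bad))
    return("gap-containing observations must be indeterminate")
  TRUE
})

#' ClassificationSet: a batch of classification results
#'
#' @slot results list of [ClassificationResult-class], input order preserved.
#' @slot referenceId identifier of the reference scaffold used.
#' @export
setClass("ClassificationSet",
  representation(results = "list", referenceId = "character"))

setValidity("ClassificationSet", function(object) {
  if (!all(vapply(object@results, is, logical(1), "ClassificationResult")))
    return("results must all be ClassificationResult objects")
  TRUE
})

#' RedoxCouple: a half-cell with standard potential and stoichiometry
#'
#' @slot name couple name, e.g. \code{"NAD+/NADH"}.
#' @slot e0PrimeMv standard (midpoint) potential at pH 7, 25 C, in mV.
#' @slot nElectrons electrons transferred per reaction.
#' @slot protonsPerReaction protons consumed per reaction (per nElectrons).
#' @export
setClass("RedoxCouple",
  representation(name = "character", e0PrimeMv = "numeric",
                 nElectrons = "integer", protonsPerReaction = "integer"))

setValidity("RedoxCouple", function(object) {
  if (object@nElectrons < 1L) return("nElectrons must be >= 1")
  TRUE
})

setMethod("show", "PositionMap", function(object) {
  n <- length(object@queryPos)
  cat(sprintf("PositionMap: %s (1..%d) -> %s; %d gapped reference position(s)\n",
              object@refId, n, object@queryId, sum(is.na(object@queryPos))))
})

setMethod("show", "AlignedPair", function(object) {
  cat(sprintf("AlignedPair %s / %s: %d columns, score %g\n",
              object@aId, object@bId, nchar(object@aAligned), object@score))
})

setMethod("show", "ClusterHits", function(object) {
  cat(sprintf("ClusterHits for %s: %d annotation(s), %d Fe predicted\n",
              object@seqId, length(object@type), sum(object@feAtoms)))
  if (length(object@type))
    print(data.frame(type = object@type, start = object@start,
                     end = object@end, fe = object@feAtoms))
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult %s: %s (identity %.3f, Fe-S support %+d)\n",
              object@seqId, object@overall, object@identity,
              object@fesSupport))
  print(object@evidence)
  if (nchar(object@note)) cat("note:", object@note, "\n")
})

setMethod("show", "ClassificationSet", function(object) {
  s <- classSummary(object)
  cat(sprintf("ClassificationSet: %d sequence(s) vs reference %s\n",
              length(object@results), object@referenceId))
  cat(sprintf("  BF: %d  nonBF: %d  ambiguous: %d\n",
              s[["BF"]], s[["nonBF"]], s[["ambiguous"]]))
})

setMethod("show", "RedoxCouple", function(object) {
  cat(sprintf("RedoxCouple %s: E0' = %g mV, n = %d e-, %d H+\n",
              object@name, object@e0PrimeMv, object@nElectrons,
              object@protonsPerReaction))
})

setMethod("show", "FingerprintRule", function(object) {
  cat(sprintf("FingerprintRule %s @ %s: BF = {%s}, nonBF = {%s}%s\n",
              object@name, paste(object@refPositions, collapse = ","),
              paste(object@bfAllowed, collapse = ","),
              paste(object@nonbfAllowed, collapse = ","),
              if (object@motif) " [motif]" else ""))
})
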
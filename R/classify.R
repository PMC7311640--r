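#' The default diagnostic fingerprint rules
#'
#' Four residue criteria, in T. maritima HydB numbering, that separate the
#' beta subunits of electron-bifurcating (BF) enzymes from non-bifurcating
#' (non-BF) NADH-dependent enzymes:
#' \itemize{
#'   \item \code{nadh_site_232}: BF A or E; non-BF T or S (NADH-binding
#'     region).
#'   \item \code{nadh_site_234}: BF M; non-BF K, S or A.
#'   \item \code{fmn_site_367}: BF F; non-BF Y (FMN-binding region; in
#'     respiratory Nqo1 the tyrosine is thought to hydrogen-bond NADH).
#'   \item \code{slbb_427_431}: BF carries the exact motif GGPSG in the SLBB
#'     domain; non-BF is anything else (without a gap).
#' }
#' The two NADH-site positions are separate criteria internally; together
#' with the FMN site and the SLBB motif they correspond to the three
#' differential sequence regions, with the (advisory) extra iron-sulfur
#' cluster count as a fourth line of evidence.
#'
#' @return list of [FingerprintRule-class] objects.
#' @export
defaultRules <- function() {
  list(
    new("FingerprintRule", name = "nadh_site_232", refPositions = 232L,
        bfAllowed = c("A", "E"), nonbfAllowed = c("T", "S"), motif = FALSE),
    new("FingerprintRule", name = "nadh_site_234", refPositions = 234L,
        bfAllowed = "M", nonbfAllowed = c("K", "S", "A"), motif = FALSE),
    new("FingerprintRule", name = "fmn_site_367", refPositions = 367L,
        bfAllowed = "F", nonbfAllowed = "Y", motif = FALSE),
    new("FingerprintRule", name = "slbb_427_431", refPositions = 427:431,
        bfAllowed = "GGPSG", nonbfAllowed = "*", motif = TRUE)
  )
}

#' Write fingerprint rules to a JSON rules file
#'
#' @param rules list of [FingerprintRule-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRules <- function(rules, path) {
  payload <- lapply(rules, function(r) {
    list(name = r@name, ref_positions = r@refPositions,
         bf_allowed = r@bfAllowed, nonbf_allowed = r@nonbfAllowed,
         motif = r@motif)
  })
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read fingerprint rules from a JSON rules file
#'
#' @param path path written by [writeRules()] (or hand-authored in the same
#'   schema).
#' @return list of [FingerprintRule-class].
#' @export
readRules <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(p) {
    new("FingerprintRule", name = p$name,
        refPositions = as.integer(p$ref_positions),
        bfAllowed = as.character(p$bf_allowed),
        nonbfAllowed = as.character(p$nonbf_allowed),
        motif = isTRUE(as.logical(p$motif)))
  })
}

#' Evaluate one fingerprint criterion on observed residues
#'
#' Returns BF when the observation matches the BF residue set (or the exact
#' BF motif), nonBF when it matches the non-BF set (for motif rules: fails
#' the BF motif while containing no gap), and indeterminate when any gap is
#' present or the residue matches neither set.
#'
#' @param rule a [FingerprintRule-class].
#' @param observed character vector of residues (gaps as \code{"-"}), same
#'   length as \code{rule@refPositions}.
#' @return list with elements \code{rule}, \code{observed} (collapsed
#'   string), \code{verdict}.
#' @export
evaluateCriterion <- function(rule, observed) {
  stopifnot(is(rule, "FingerprintRule"))
  if (length(observed) != length(rule@refPositions))
    stop("observed length must equal the number of rule positions")
  obs <- paste(observed, collapse = "")
  verdict <- if (any(observed == GAP)) {
    "indeterminate"
  } else if (rule@motif) {
    if (obs == rule@bfAllowed) "BF" else "nonBF"
  } else if (obs %in% rule@bfAllowed) {
    "BF"
  } else if ("*" %in% rule@nonbfAllowed || obs %in% rule@nonbfAllowed) {
    "nonBF"
  } else {
    "indeterminate"
  }
  list(rule = rule@name, observed = obs, verdict = verdict)
}

# unanimity-with-quorum decision over per-criterion verdicts
.overallVerdict <- function(verdicts, quorum = 2L) {
  informative <- verdicts[verdicts != "indeterminate"]
  if (length(informative) >= quorum && length(unique(informative)) == 1L)
    informative[1]
  else "ambiguous"
}

#' Classify one beta-subunit sequence
#'
#' Aligns the query globally to the reference scaffold, builds the
#' reference-frame position map, reads off the residues at every rule's
#' positions, evaluates all criteria, and applies the overall decision rule:
#' BF (resp. nonBF) when all non-indeterminate criteria agree and at least
#' \code{quorum} are informative, otherwise ambiguous. The extra
#' iron-sulfur cluster count relative to the reference is attached as
#' advisory evidence and never overrides the residue criteria. Queries whose
#' alignment identity falls below \code{identityFloor} are refused
#' (ambiguous, with the reason recorded in the result note).
#'
#' @param query,reference sequences (forms accepted by [globalAlign()]).
#' @param rules list of [FingerprintRule-class]; default [defaultRules()].
#' @param scheme substitution scheme; default [defaultScheme()].
#' @param identityFloor minimum alignment identity (default 0.15) below
#'   which classification is refused.
#' @param quorum minimum number of informative criteria (default 2).
#' @param motifConfig iron-sulfur motif configuration for the advisory scan.
#' @return a [ClassificationResult-class].
#' @export
classifySequence <- function(query, reference, rules = defaultRules(),
                             scheme = defaultScheme(),
                             identityFloor = 0.15, quorum = 2L,
                             motifConfig = defaultMotifConfig()) {
  q <- .asRecord(query, "query")
  aln <- globalAlign(reference, query, scheme)
  # coverage-weighted identity: identical columns over reference length, so
  # fragments and unrelated sequences fall below the floor even when their
  # few aligned columns look locally similar
  ident <- referenceIdentity(aln)
  pmap <- buildPositionMap(aln, referenceIsA = TRUE)
  ev <- lapply(rules, function(rule) {
    obs <- residuesAt(query, pmap, rule@refPositions)
    evaluateCriterion(rule, obs)
  })
  evidence <- data.frame(
    rule = vapply(ev, `[[`, character(1), "rule"),
    observed = vapply(ev, `[[`, character(1), "observed"),
    verdict = vapply(ev, `[[`, character(1), "verdict"),
    stringsAsFactors = FALSE)
  fes <- extraClusterCount(scanClusters(query, motifConfig),
                           scanClusters(reference, motifConfig))
  if (ident < identityFloor) {
    overall <- "ambiguous"
    note <- sprintf(
      "refused: alignment identity %.3f below floor %.3f", ident,
      identityFloor)
    evidence$verdict <- "indeterminate"
  } else {
    overall <- .overallVerdict(evidence$verdict, quorum)
    note <- ""
  }
  new("ClassificationResult", seqId = q$id, evidence = evidence,
      fesSupport = as.integer(fes), overall = overall,
      identity = ident, note = note)
}

#' Classify a batch of sequences
#'
#' Independent per-sequence classification in input order; per-record
#' refusals are carried through without aborting the batch.
#'
#' @param records an [Biostrings::AAStringSet] (or named character vector).
#' @param reference the reference scaffold.
#' @inheritParams classifySequence
#' @return a [ClassificationSet-class].
#' @export
classifyBatch <- function(records, reference, rules = defaultRules(),
                          scheme = defaultScheme(), identityFloor = 0.15,
                          quorum = 2L,
                          motifConfig = defaultMotifConfig()) {
  if (is.character(records)) records <- Biostrings::AAStringSet(records)
  if (length(records) == 0L) stop("records must be non-empty")
  ref <- .asRecord(reference, "reference")
  results <- lapply(seq_along(records), function(i) {
    classifySequence(records[i], reference, rules = rules, scheme = scheme,
                     identityFloor = identityFloor, quorum = quorum,
                     motifConfig = motifConfig)
  })
  new("ClassificationSet", results = results, referenceId = ref$id)
}

#' Summary counts for a classification batch
#'
#' @param x a [ClassificationSet-class].
#' @return named integer vector with counts of BF, nonBF and ambiguous.
#' @export
classSummary <- function(x) {
  stopifnot(is(x, "ClassificationSet"))
  overall <- vapply(x@results, function(r) r@overall, character(1))
  vapply(c(BF = "BF", nonBF = "nonBF", ambiguous = "ambiguous"),
         function(v) sum(overall == v), integer(1))
}

#' Overall verdicts of a classification batch
#'
#' @param x a [ClassificationSet-class].
#' @return character vector named by sequence id, input order.
#' @export
classCalls <- function(x) {
  stopifnot(is(x, "ClassificationSet"))
  stats::setNames(vapply(x@results, function(r) r@overall, character(1)),
                  vapply(x@results, function(r) r@seqId, character(1)))
}
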
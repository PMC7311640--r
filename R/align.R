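#' Default substitution scheme
#'
#' BLOSUM62 with affine gap penalties, gap open -11 and gap extend -1: the
#' conventional protein-alignment default. A gap run of length L is charged
#' \code{gapOpen + L * gapExtend} (both negative). The matrix is symmetric
#' and the penalties satisfy gapOpen <= gapExtend < 0.
#'
#' @param matrix named 20x20 (or larger) integer substitution matrix.
#' @param gapOpen,gapExtend negative integers.
#' @return a list with elements \code{matrix}, \code{gapOpen},
#'   \code{gapExtend}.
#' @export
defaultScheme <- function(matrix = NULL, gapOpen = -11L, gapExtend = -1L) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (!(gapOpen <= 0 && gapExtend < 0))
    stop("require gapOpen <= 0 and gapExtend < 0 (gapOpen = 0 gives a
         linear gap model)")
  list(matrix = matrix, gapOpen = as.integer(gapOpen),
       gapExtend = as.integer(gapExtend))
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix format used by NCBI (comment lines starting
#' with \code{#}, a header row of residue letters, one labelled row per
#' residue).
#'
#' @param path path to the matrix file.
#' @return a named integer matrix.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1L)
  vals <- t(vapply(body, function(x) as.integer(x[-1]),
                   integer(length(cols))))
  dimnames(vals) <- list(rows, cols)
  vals
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under an affine gap model, computed by
#' [Biostrings::pairwiseAlignment]. The score is optimal for the scheme; a
#' gap run of length L costs \code{gapOpen + L * gapExtend}.
#'
#' @param a,b sequences: one-record AAStringSet, named character of length 1,
#'   or plain strings.
#' @param scheme substitution scheme from [defaultScheme()].
#' @return an [AlignedPair-class].
#' @export
globalAlign <- function(a, b, scheme = defaultScheme()) {
  a <- .asRecord(a, "a"); b <- .asRecord(b, "b")
  if (nchar(a$seq) == 0L || nchar(b$seq) == 0L)
    stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    pattern = a$seq, subject = b$seq, type = "global",
    substitutionMatrix = scheme$matrix,
    gapOpening = -scheme$gapOpen, gapExtension = -scheme$gapExtend)
  new("AlignedPair", aId = a$id, bId = b$id,
      aAligned = as.character(Biostrings::alignedPattern(pa)),
      bAligned = as.character(Biostrings::alignedSubject(pa)),
      score = Biostrings::score(pa))
}

.asRecord <- function(x, argname) {
  if (is(x, "XStringSet")) {
    if (length(x) != 1L) stop(argname, " must be a single sequence")
    list(id = if (is.null(names(x))) argname else names(x),
         seq = as.character(x)[[1]])
  } else if (is.character(x) && length(x) == 1L) {
    list(id = if (is.null(names(x))) argname else names(x),
         seq = unname(x))
  } else stop(argname, " must be a single sequence")
}

#' Build a reference-frame position map from an alignment
#'
#' For every reference residue (1..reference length) records the aligned
#' query position, or a gap. Query residues aligned to reference gaps
#' (insertions relative to the reference) are unmapped by construction.
#' The resulting map is monotone and injective on its non-gap entries;
#' this is asserted by the class validity on every construction.
#'
#' @param aln an [AlignedPair-class].
#' @param referenceIsA TRUE when the reference is the first (a) sequence.
#' @return a [PositionMap-class].
#' @export
buildPositionMap <- function(aln, referenceIsA = TRUE) {
  stopifnot(is(aln, "AlignedPair"))
  ra <- strsplit(if (referenceIsA) aln@aAligned else aln@bAligned, "")[[1]]
  qa <- strsplit(if (referenceIsA) aln@bAligned else aln@aAligned, "")[[1]]
  refCursor <- cumsum(ra != GAP)
  qryCursor <- cumsum(qa != GAP)
  keep <- ra != GAP
  qp <- ifelse(qa[keep] == GAP, NA_integer_, qryCursor[keep])
  new("PositionMap",
      refId = if (referenceIsA) aln@aId else aln@bId,
      queryId = if (referenceIsA) aln@bId else aln@aId,
      queryPos = as.integer(qp))
}

#' Read query residues at reference-frame positions
#'
#' The read-off primitive of the fingerprint machinery: returns, for each
#' 1-based reference position, the query residue aligned to it, or [GAP].
#'
#' @param query the query sequence (same forms as [globalAlign()]).
#' @param pmap a [PositionMap-class] whose query is \code{query}.
#' @param refPositions 1-based reference positions, all within the
#'   reference length.
#' @return character vector of residues, with \code{"-"} for gapped
#'   positions.
#' @export
residuesAt <- function(query, pmap, refPositions) {
  stopifnot(is(pmap, "PositionMap"))
  q <- .asRecord(query, "query")
  n <- length(pmap@queryPos)
  refPositions <- as.integer(refPositions)
  if (any(refPositions < 1L) || any(refPositions > n))
    stop("reference position out of range 1..", n)
  qp <- pmap@queryPos[refPositions]
  res <- rep(GAP, length(qp))
  ok <- !is.na(qp)
  if (any(ok))
    res[ok] <- strsplit(q$seq, "")[[1]][qp[ok]]
  res
}

#' Percent-identity of an aligned pair
#'
#' Identity over mutually aligned columns: identical residues divided by the
#' number of columns where neither sequence has a gap.
#'
#' @param aln an [AlignedPair-class].
#' @return fraction in [0, 1].
#' @export
alignmentIdentity <- function(aln) {
  stopifnot(is(aln, "AlignedPair"))
  av <- strsplit(aln@aAligned, "")[[1]]
  bv <- strsplit(aln@bAligned, "")[[1]]
  shared <- av != GAP & bv != GAP
  if (!any(shared)) return(0)
  sum(av[shared] == bv[shared]) / sum(shared)
}

#' Identity of an aligned pair relative to the first (reference) sequence
#'
#' Identical columns divided by the ungapped length of the first sequence:
#' a coverage-weighted identity, low for fragments or unrelated sequences
#' even when their few aligned columns match well. Used for the
#' refuse-to-classify floor.
#'
#' @param aln an [AlignedPair-class] whose first sequence is the reference.
#' @return fraction in [0, 1].
#' @export
referenceIdentity <- function(aln) {
  stopifnot(is(aln, "AlignedPair"))
  av <- strsplit(aln@aAligned, "")[[1]]
  bv <- strsplit(aln@bAligned, "")[[1]]
  sum(av != GAP & av == bv) / sum(av != GAP)
}

#' Map one query sequence onto a reference frame
#'
#' Convenience wrapper: aligns query to reference and returns the reference
#' frame projection (one residue or gap per reference position). Insertions
#' relative to the reference are dropped, which is the star-alignment
#' simplification used for the phylogeny mode.
#'
#' @param query,reference sequences (see [globalAlign()]).
#' @param scheme substitution scheme.
#' @return character vector of length \code{nchar(reference)}.
#' @export
projectToReference <- function(query, reference, scheme = defaultScheme()) {
  aln <- globalAlign(reference, query, scheme)
  pmap <- buildPositionMap(aln, referenceIsA = TRUE)
  residuesAt(query, pmap, seq_len(length(pmap@queryPos)))
}
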
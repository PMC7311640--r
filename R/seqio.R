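#' Read protein sequences from a FASTA file
#'
#' Reads a protein FASTA file into a named [Biostrings::AAStringSet].
#' Sequences are uppercased, terminal stop symbols (\code{*}) are stripped
#' and the ambiguity letters B, Z, U and O are mapped to X with a warning,
#' since the downstream fingerprint machinery works over the 20-letter
#' alphabet plus X. Any other character outside that alphabet is a parse
#' error reporting the offending line number. Record order is preserved;
#' names carry the id (first whitespace-delimited token of the header) and
#' the full description is kept in the \code{description} attribute-free
#' metadata returned by [recordDescriptions()].
#'
#' Note that a sequence containing only A, C, G and T letters is accepted:
#' the protein alphabet is a superset of the nucleotide letters, so
#' nucleotide-looking input is not second-guessed.
#'
#' @param path path to a FASTA file.
#' @return an [Biostrings::AAStringSet] named by record id.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">a demo", "MKV"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # pre-scan the raw lines: the backing parser silently drops invalid
  # letters, and a parse error should name the offending line
  line <- .fastaBadLine(path)
  if (!is.na(line))
    stop("illegal residue character in ", path, ", line ", line)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    .fastaDiagnose(path)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("no records found in ", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  if (any(grepl("[BZUO]", seqs))) {
    warning("ambiguity characters B/Z/U/O mapped to X")
    seqs <- chartr("BZUO", "XXXX", seqs)
  }
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record '", headers[which(nchar(seqs) == 0L)[1]], "'")
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[anyDuplicated(ids)])
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  attr(out, "descriptions") <- stats::setNames(headers, ids)
  out
}

# locate the first line carrying a character outside the accepted alphabet
.fastaBadLine <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ok <- paste0("^[", paste(AA_ALLOWED, collapse = ""), "BZUObzuo*\\s]*$")
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) next
    if (!grepl(ok, toupper(lines[i]))) return(i)
  }
  NA_integer_
}

.fastaDiagnose <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && !startsWith(lines[1], ">"))
    message("first line is not a FASTA header (line 1)")
  invisible(NULL)
}

#' Record descriptions stored by readFasta
#'
#' @param set an AAStringSet returned by [readFasta()].
#' @return named character vector of full FASTA headers (id -> header).
#' @export
recordDescriptions <- function(set) {
  d <- attr(set, "descriptions")
  if (is.null(d)) stats::setNames(names(set), names(set)) else d
}

#' Write protein sequences to FASTA
#'
#' Writes a named [Biostrings::AAStringSet] (or named character vector) as
#' FASTA, wrapped at 60 columns.
#'
#' @param set sequences, named by id.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(set, path) {
  if (is.character(set)) set <- Biostrings::AAStringSet(set)
  if (is.null(names(set)) || any(!nzchar(names(set))))
    stop("all records must be named")
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Construct a single named protein record
#'
#' Convenience constructor for a one-record [Biostrings::AAStringSet] with
#' the package's residue validation applied.
#'
#' @param id record identifier (no whitespace).
#' @param residues uppercase amino-acid string (20 letters plus X).
#' @return an AAStringSet of length 1.
#' @export
proteinRecord <- function(id, residues) {
  stopifnot(length(id) == 1L, length(residues) == 1L)
  if (grepl("\\s", id)) stop("id must not contain whitespace")
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("residues must be non-empty")
  if (grepl(paste0("[^", paste(AA_ALLOWED, collapse = ""), "]"), residues))
    stop("illegal residue character in sequence '", id, "'")
  out <- Biostrings::AAStringSet(residues)
  names(out) <- id
  out
}

#' Flatten a ClassificationSet into a report table
#'
#' One row per sequence: id, overall class, per-criterion observed residues
#' and verdicts, extra iron-sulfur cluster count and alignment identity.
#' Column order is deterministic. Indeterminate cells keep their verdict;
#' empty observations are rendered as the literal token "NA".
#'
#' @param x a [ClassificationSet-class] (or list of ClassificationResult).
#' @return a data.frame.
#' @export
reportTable <- function(x) {
  results <- if (is(x, "ClassificationSet")) x@results else x
  if (length(results) == 0L) stop("no results to report")
  rules <- results[[1]]@evidence$rule
  rows <- lapply(results, function(r) {
    stopifnot(identical(r@evidence$rule, rules))
    obs <- r@evidence$observed
    obs[!nzchar(obs)] <- NA_character_
    row <- c(list(id = r@seqId, overall = r@overall),
             stats::setNames(as.list(obs), paste0(rules, "_observed")),
             stats::setNames(as.list(r@evidence$verdict),
                             paste0(rules, "_verdict")),
             list(fes_support = r@fesSupport,
                  identity = round(r@identity, 4)))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a classification report
#'
#' Serializes classification results as TSV (missing values as the literal
#' token "NA") or JSON (re-parsing the JSON recovers the report table).
#'
#' @param x a [ClassificationSet-class] or list of ClassificationResult.
#' @param path output path.
#' @param format "tsv" or "json".
#' @return the path, invisibly.
#' @export
writeReport <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- reportTable(x)
  if (format == "tsv") {
    ok <- tryCatch({
      utils::write.table(tab, file = path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write report to ", path)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
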
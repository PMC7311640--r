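#' Default iron-sulfur motif configuration
#'
#' Cysteine-spacing windows for the three cluster classes. The grammar is a
#' transparent, curator-tunable stand-in for domain-annotation inventories:
#' \itemize{
#'   \item \code{FeS4} ([4Fe-4S]): \code{C x(2) C x(2) C x(2,4) C}
#'   \item \code{FeS2} ([2Fe-2S]): \code{C x(4,6) C x(1,3) C x(20,40) C}
#'   \item \code{HCLUSTER}: the signature block \code{C x(2) C x(2) C} plus a
#'     downstream fourth cysteine within a configurable window (default
#'     6-40 residues).
#' }
#' Each motif contributes a fixed iron count (4, 2 and 6 atoms). Overlaps are
#' resolved left-to-right (leftmost, then by the priority order given here,
#' then longest), so scanning is deterministic.
#'
#' @param priority cluster types in decreasing priority for overlap
#'   resolution.
#' @param hclusterWindow integer length-2 window (min, max spacer) between
#'   the signature block and the downstream cysteine of an H-cluster.
#' @return a named list of motif definitions plus the priority order.
#' @export
defaultMotifConfig <- function(priority = c("FeS4", "FeS2", "HCLUSTER"),
                               hclusterWindow = c(6L, 40L)) {
  stopifnot(setequal(priority, names(CLUSTER_FE)),
            length(hclusterWindow) == 2L,
            hclusterWindow[1] >= 1L, hclusterWindow[1] <= hclusterWindow[2])
  list(
    motifs = list(
      FeS4 = "C.{2}C.{2}C.{2,4}C",
      FeS2 = "C.{4,6}C.{1,3}C.{20,40}C",
      HCLUSTER = sprintf("C.{2}C.{2}C.{%d,%d}C",
                         hclusterWindow[1], hclusterWindow[2])
    ),
    priority = priority
  )
}

#' Scan a sequence for iron-sulfur cluster binding motifs
#'
#' Finds all candidate matches of each motif in [defaultMotifConfig()]
#' (including overlapping candidates, longest match per start per motif) and
#' resolves overlaps greedily left-to-right with the configured priority.
#' Every reported cysteine position indexes a C in the sequence; this is
#' asserted by the [ClusterHits-class] validity.
#'
#' @param seq the sequence to scan (forms accepted by [globalAlign()]).
#' @param config motif configuration from [defaultMotifConfig()].
#' @return a [ClusterHits-class] with non-overlapping annotations in N-to-C
#'   order.
#' @export
scanClusters <- function(seq, config = defaultMotifConfig()) {
  r <- .asRecord(seq, "seq")
  s <- r$seq
  cand <- list()
  for (type in names(config$motifs)) {
    pat <- config$motifs[[type]]
    # lookahead finds overlapping starts; group 1 carries the (greedy,
    # hence longest) match at each start
    m <- gregexpr(paste0("(?=(", pat, "))"), s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1L]
    cand[[type]] <- data.frame(type = type, start = starts,
                               end = starts + lens - 1L)
  }
  hits <- .emptyHits(r$id)
  if (length(cand) == 0L) return(hits)
  cand <- do.call(rbind, cand)
  prio <- match(cand$type, config$priority)
  ord <- order(cand$start, prio, -cand$end)
  cand <- cand[ord, , drop = FALSE]
  lastEnd <- 0L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > lastEnd) {
      keep[i] <- TRUE
      lastEnd <- cand$end[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  chars <- strsplit(s, "")[[1]]
  cys <- lapply(seq_len(nrow(cand)), function(i) {
    span <- cand$start[i]:cand$end[i]
    span[chars[span] == "C"]
  })
  new("ClusterHits", seqId = r$id, type = cand$type,
      start = as.integer(cand$start), end = as.integer(cand$end),
      feAtoms = unname(CLUSTER_FE[cand$type]), cysPositions = cys)
}

.emptyHits <- function(id) {
  new("ClusterHits", seqId = id, type = character(), start = integer(),
      end = integer(), feAtoms = integer(), cysPositions = list())
}

#' Counts of annotations per cluster type
#'
#' @param hits a [ClusterHits-class].
#' @return named integer vector over FeS4, FeS2, HCLUSTER.
#' @export
clusterCounts <- function(hits) {
  stopifnot(is(hits, "ClusterHits"))
  vapply(names(CLUSTER_FE), function(t) sum(hits@type == t), integer(1))
}

#' Predicted iron content of an annotated subunit
#'
#' Sum of the per-cluster iron contributions (2 per [2Fe-2S], 4 per
#' [4Fe-4S], 6 per H-cluster). Additive and order-independent; e.g. five
#' [4Fe-4S] plus two [2Fe-2S] plus one H-cluster predicts 30 Fe per alpha/beta
#' heterodimer.
#'
#' @param hits a [ClusterHits-class].
#' @return integer total iron atoms.
#' @export
predictedIronContent <- function(hits) {
  stopifnot(is(hits, "ClusterHits"))
  sum(hits@feAtoms)
}

#' Extra cluster count relative to a baseline
#'
#' Difference in the number of detected cluster annotations between a query
#' and a baseline subunit (may be negative). Advisory evidence only: both
#' enzyme groups vary substantially in cluster arrangement, so the count is
#' never allowed to decide a classification on its own.
#'
#' @param query,baseline [ClusterHits-class] objects.
#' @return integer difference (query minus baseline).
#' @export
extraClusterCount <- function(query, baseline) {
  stopifnot(is(query, "ClusterHits"), is(baseline, "ClusterHits"))
  length(query@type) - length(baseline@type)
}

#' Export cluster annotations as a BED-like table
#'
#' 1-based inclusive coordinates (documented; unlike BED's 0-based
#' half-open convention).
#'
#' @param hits a [ClusterHits-class].
#' @param path optional output TSV path.
#' @return the data.frame, invisibly if written to a file.
#' @export
clusterTable <- function(hits, path = NULL) {
  stopifnot(is(hits, "ClusterHits"))
  tab <- data.frame(
    seq_id = rep(hits@seqId, length(hits@type)),
    start = hits@start, end = hits@end, type = hits@type,
    fe_atoms = hits@feAtoms,
    cys_positions = vapply(hits@cysPositions, paste, character(1),
                           collapse = ","))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
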
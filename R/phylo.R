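#' Trim alignment columns by occupancy
#'
#' Keeps columns whose non-gap fraction is at least \code{minOccupancy},
#' preserving column order. With threshold 0 this is the identity. An
#' automated surrogate for manual alignment-block trimming before
#' tree building.
#'
#' @param gapped character matrix (sequences x columns) or equal-length
#'   gapped strings.
#' @param minOccupancy fraction in [0, 1]; default 0.5.
#' @return list with \code{sequences} (character matrix) and \code{kept}
#'   (integer vector of surviving column indices).
#' @export
trimColumns <- function(gapped, minOccupancy = 0.5) {
  mat <- .asAlnMatrix(gapped)
  occ <- colMeans(mat != GAP)
  kept <- which(occ >= minOccupancy)
  if (length(kept) == 0L) stop("no columns survive occupancy trimming")
  list(sequences = mat[, kept, drop = FALSE], kept = kept)
}

.asAlnMatrix <- function(gapped) {
  if (is.matrix(gapped)) return(gapped)
  if (is.character(gapped)) {
    if (length(unique(nchar(gapped))) != 1L)
      stop("gapped sequences must have equal length")
    mat <- do.call(rbind, strsplit(gapped, ""))
    rownames(mat) <- names(gapped)
    return(mat)
  }
  stop("expected a character matrix or equal-length gapped strings")
}

#' Pairwise evolutionary distance between two gapped sequences
#'
#' \code{p}: mismatches divided by shared (both non-gap) columns.
#' \code{poisson}: the Poisson correction \code{-log(1 - p)}, infinite-error
#' when p >= 1.
#'
#' @param a,b equal-length gapped strings or character vectors.
#' @param model "p" or "poisson".
#' @return non-negative distance.
#' @export
pairwiseDistance <- function(a, b, model = c("p", "poisson")) {
  model <- match.arg(model)
  av <- if (length(a) > 1L) a else strsplit(a, "")[[1]]
  bv <- if (length(b) > 1L) b else strsplit(b, "")[[1]]
  if (length(av) != length(bv)) stop("sequences must have equal length")
  shared <- av != GAP & bv != GAP
  if (!any(shared)) stop("no shared non-gap columns: distance undefined")
  p <- sum(av[shared] != bv[shared]) / sum(shared)
  if (model == "p") return(p)
  if (p >= 1) stop("Poisson correction undefined for p >= 1")
  -log(1 - p)
}

#' Distance matrix over a set of gapped sequences
#'
#' @param gapped character matrix (sequences x columns, rownames = ids) or
#'   named equal-length gapped strings.
#' @param model distance model, see [pairwiseDistance()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(gapped, model = c("p", "poisson")) {
  model <- match.arg(model)
  mat <- .asAlnMatrix(gapped)
  n <- nrow(mat)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- pairwiseDistance(mat[i, ], mat[j, ], model)
  }
  d
}

#' Star alignment of a sequence set through a reference scaffold
#'
#' Projects every sequence onto the reference frame via pairwise global
#' alignment (insertions relative to the reference are dropped) and stacks
#' the projections into a pseudo multiple alignment of reference length.
#' A deterministic, order-independent simplification of progressive multiple
#' alignment, adequate for distance-based trees of homologous subunits.
#'
#' @param records an [Biostrings::AAStringSet].
#' @param reference the reference scaffold.
#' @param scheme substitution scheme.
#' @param includeReference add the reference itself as the first row.
#' @return character matrix (sequences x reference positions).
#' @export
starAlignment <- function(records, reference, scheme = defaultScheme(),
                          includeReference = FALSE) {
  if (is.character(records)) records <- Biostrings::AAStringSet(records)
  ref <- .asRecord(reference, "reference")
  rows <- lapply(seq_along(records), function(i)
    projectToReference(records[i], reference, scheme))
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(records)
  if (includeReference) {
    mat <- rbind(strsplit(ref$seq, "")[[1]], mat)
    rownames(mat)[1] <- ref$id
  }
  mat
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via [ape::nj]); additive distance matrices
#' are recovered exactly (topology and branch lengths). Negative branch
#' length estimates, which NJ can produce on noisy input, are clamped to 0
#' and counted in the \code{clamped} attribute, with a warning.
#'
#' @param d symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return an unrooted [ape::phylo] tree; attribute \code{clamped} gives the
#'   number of negative branch lengths clamped.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(!is.finite(d))) stop("distances must be finite")
  tree <- ape::nj(d)
  nClamped <- sum(tree$edge.length < 0)
  if (nClamped > 0L) {
    warning(nClamped, " negative branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped") <- nClamped
  tree
}

#' Test whether a label set is monophyletic on an unrooted tree
#'
#' TRUE iff some edge bipartitions the leaves into exactly \code{labels}
#' versus the complement. Singletons are always monophyletic (their pendant
#' edge). When true, the splitting edge (row index into \code{tree$edge}) is
#' attached as the \code{edge} attribute.
#'
#' @param tree an [ape::phylo] tree.
#' @param labels non-empty proper subset of the tip labels.
#' @return logical flag with attribute \code{edge}.
#' @export
isMonophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(labels %in% tips)) stop("unknown label(s): ",
                                   paste(setdiff(labels, tips), collapse = ", "))
  if (length(labels) == 0L || length(labels) == length(tips))
    stop("labels must be a non-empty proper subset of the tips")
  target <- sort(match(labels, tips))
  nTip <- length(tips)
  # leaf set under the child end of every edge, by postorder accumulation
  below <- vector("list", nTip + tree$Nnode)
  for (i in seq_len(nTip)) below[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  for (k in seq_len(nrow(tree$edge))) {
    side <- sort(below[[tree$edge[k, 2]]])
    comp <- sort(setdiff(seq_len(nTip), side))
    if (identical(side, target) || identical(comp, target)) {
      out <- TRUE
      attr(out, "edge") <- k
      return(out)
    }
  }
  FALSE
}

#' Write a tree in Newick format
#'
#' Branch lengths included, internal labels omitted.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  tree$node.label <- NULL
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Beta-subunit phylogeny pipeline
#'
#' Star-aligns the sequences through the reference, trims columns by
#' occupancy, computes distances and returns the neighbor-joining tree.
#'
#' @param records an [Biostrings::AAStringSet] of at least 3 sequences.
#' @param reference the reference scaffold.
#' @param model distance model, see [pairwiseDistance()].
#' @param minOccupancy column occupancy threshold (default 0.5).
#' @param scheme substitution scheme.
#' @return an unrooted [ape::phylo] tree.
#' @export
betaSubunitTree <- function(records, reference, model = c("poisson", "p"),
                            minOccupancy = 0.5, scheme = defaultScheme()) {
  model <- match.arg(model)
  mat <- starAlignment(records, reference, scheme)
  trimmed <- trimColumns(mat, minOccupancy)
  njTree(distanceMatrix(trimmed$sequences, model))
}
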
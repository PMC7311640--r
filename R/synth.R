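# fingerprint geometry of the reference frame (HydB numbering)
FP_SINGLE <- c(nadh_site_232 = 232L, nadh_site_234 = 234L,
               fmn_site_367 = 367L)
FP_SLBB <- 427:431
FP_ALL <- sort(c(unname(FP_SINGLE), FP_SLBB))
FP_GUARD <- 5L

BF_RESIDUES <- list(`232` = c("A", "E"), `234` = "M", `367` = "F",
                    slbb = "GGPSG")
NONBF_RESIDUES <- list(`232` = c("T", "S"), `234` = c("K", "S", "A"),
                       `367` = "Y")

# default planted cluster inventory per class: BF subunits carry at least
# one extra iron-sulfur domain relative to non-BF ones
DEFAULT_CLUSTERS <- list(
  BF = c(FeS4 = 3L, FeS2 = 1L, HCLUSTER = 0L),
  nonBF = c(FeS4 = 2L, FeS2 = 1L, HCLUSTER = 0L))

# run code under a deterministic, restored RNG state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

.nonCysAlphabet <- setdiff(AA_ALPHABET20, "C")

# motif zones: 54-residue windows on a 100-residue pitch, skipping any
# window that touches a fingerprint guard band; the pitch keeps planted
# cysteines of neighbouring motifs > 41 residues apart, outside every
# motif's largest spacing window, so zones can never combine into a
# spurious cross-zone match
.motifZones <- function(length) {
  span <- 54L
  guards <- sort(unique(unlist(lapply(FP_ALL, function(p)
    max(1L, p - FP_GUARD):(p + FP_GUARD)))))
  starts <- integer(0)
  p <- 10L
  while (p + span - 1L <= length) {
    if (!any(seq(p, p + span - 1L) %in% guards)) {
      starts <- c(starts, p)
      p <- p + 100L
    } else {
      # slide past the guard band; the forward jump keeps consecutive
      # zones at least 46 residues apart
      p <- p + 1L
    }
  }
  data.frame(start = starts, end = starts + span - 1L)
}

#' Generate the synthetic reference scaffold
#'
#' A cysteine-free random beta-subunit-like sequence with the BF fingerprint
#' fixed at the reference positions (A at 232, M at 234, F at 367, GGPSG at
#' 427-431) and reserved cysteine-free motif zones where iron-sulfur
#' cluster motifs are planted per sequence. Deterministic per seed: the same
#' seed always yields the same scaffold, and different seeds differ only in
#' the background, never in the fingerprint geometry.
#'
#' @param length scaffold length (>= 450 so position 431 exists;
#'   default 600).
#' @param seed integer seed.
#' @param id record id (default "scaffold").
#' @return a one-record [Biostrings::AAStringSet] carrying the frame
#'   annotation in attributes \code{fingerprintPositions} and
#'   \code{motifZones}.
#' @export
makeReferenceScaffold <- function(length = 600L, seed = 1L,
                                  id = "scaffold") {
  length <- as.integer(length)
  if (length < 450L) stop("scaffold length must be >= 450")
  chars <- .withSeed(seed,
    sample(.nonCysAlphabet, length, replace = TRUE))
  chars[232L] <- "A"; chars[234L] <- "M"; chars[367L] <- "F"
  chars[FP_SLBB] <- strsplit(BF_RESIDUES$slbb, "")[[1]]
  rec <- proteinRecord(id, paste(chars, collapse = ""))
  attr(rec, "fingerprintPositions") <- FP_ALL
  attr(rec, "motifZones") <- .motifZones(length)
  rec
}

# sample the cysteine anchor offsets for one motif instance within a zone
.motifAnchors <- function(type) {
  if (type == "FeS4") {
    cumsum(c(1L, 3L, 3L, sample(3:5, 1L)))
  } else if (type == "FeS2") {
    cumsum(c(1L, sample(5:7, 1L), sample(2:4, 1L), sample(21:41, 1L)))
  } else {  # HCLUSTER: signature block plus a distal fourth cysteine
    cumsum(c(1L, 3L, 3L, sample(10:30, 1L)))
  }
}

#' Plant a labelled synthetic beta-subunit sequence
#'
#' Starting from a scaffold (or a previously planted ancestor carrying the
#' same frame annotation), writes class-appropriate fingerprint residues
#' (sampled uniformly from the class's allowed set), plants the requested
#' iron-sulfur motifs into the reserved zones, mutates background positions
#' down to the requested identity (substitutions drawn uniformly over the
#' 18 non-cysteine alternatives so the planted cluster inventory stays
#' exact), and applies insertions/deletions outside a +/-5 guard band
#' around the fingerprint positions and outside the motif zones. The truth
#' record captures everything planted.
#'
#' @param scaffold output of [makeReferenceScaffold()] (or of a previous
#'   [plantSequence()] call, for class-ancestor simulations).
#' @param cls "BF" or "nonBF".
#' @param backgroundIdentity target identity to the scaffold over
#'   non-fingerprint positions, in (0, 1].
#' @param indelRate expected indel events per residue (default 0).
#' @param seed integer seed.
#' @param clusterCounts named integer vector over FeS4/FeS2/HCLUSTER;
#'   default per-class inventory (BF gets one extra cluster).
#' @param id record id (default derived from class and seed).
#' @return a one-record [Biostrings::AAStringSet] with the frame annotation
#'   attributes and a \code{truth} attribute (one-row data.frame).
#' @export
plantSequence <- function(scaffold, cls = c("BF", "nonBF"),
                          backgroundIdentity = 0.75, indelRate = 0,
                          seed = 1L, clusterCounts = NULL, id = NULL) {
  cls <- match.arg(cls)
  stopifnot(backgroundIdentity > 0, backgroundIdentity <= 1, indelRate >= 0)
  if (is.null(clusterCounts)) clusterCounts <- DEFAULT_CLUSTERS[[cls]]
  clusterCounts <- clusterCounts[clusterCounts > 0]
  zones <- attr(scaffold, "motifZones")
  if (is.null(zones)) stop("scaffold lacks the motif-zone annotation")
  if (sum(clusterCounts) > nrow(zones))
    stop("requested ", sum(clusterCounts), " motifs but only ",
         nrow(zones), " zones are available; use a longer scaffold")
  if (is.null(id)) id <- sprintf("%s_s%d", cls, as.integer(seed))

  .withSeed(seed, {
    chars <- strsplit(as.character(scaffold)[[1]], "")[[1]]
    L <- length(chars)

    # fingerprint residues for the class
    fp <- list(
      `232` = sample(BF_RESIDUES$`232`, 1L),
      `234` = sample(BF_RESIDUES$`234`, 1L),
      `367` = sample(BF_RESIDUES$`367`, 1L),
      slbb = BF_RESIDUES$slbb)
    if (cls == "nonBF") {
      fp$`232` <- sample(NONBF_RESIDUES$`232`, 1L)
      fp$`234` <- sample(NONBF_RESIDUES$`234`, 1L)
      fp$`367` <- NONBF_RESIDUES$`367`
      # any non-GGPSG, gap-free motif reads as non-BF; mutate one position
      slbb <- strsplit(BF_RESIDUES$slbb, "")[[1]]
      k <- sample(seq_along(slbb), 1L)
      slbb[k] <- sample(setdiff(.nonCysAlphabet, slbb[k]), 1L)
      fp$slbb <- paste(slbb, collapse = "")
    }
    chars[232L] <- fp$`232`; chars[234L] <- fp$`234`
    chars[367L] <- fp$`367`
    chars[FP_SLBB] <- strsplit(fp$slbb, "")[[1]]

    # clear any cysteines inherited in the zones, then plant the motifs
    zonePos <- unlist(lapply(seq_len(nrow(zones)), function(i)
      zones$start[i]:zones$end[i]))
    inherited <- zonePos[chars[zonePos] == "C"]
    if (length(inherited))
      chars[inherited] <- sample(.nonCysAlphabet, length(inherited),
                                 replace = TRUE)
    types <- rep(names(clusterCounts), clusterCounts)
    anchorPos <- integer(0)
    for (i in seq_along(types)) {
      anchors <- zones$start[i] - 1L + .motifAnchors(types[i])
      chars[anchors] <- "C"
      anchorPos <- c(anchorPos, anchors)
    }

    # background substitutions: uniform over the non-cysteine alternatives
    protected <- c(FP_ALL, anchorPos)
    mutable <- setdiff(seq_len(L), protected)
    nMut <- min(round((1 - backgroundIdentity) * L), length(mutable))
    mutPos <- sample(mutable, nMut)
    for (p in mutPos)
      chars[p] <- sample(setdiff(.nonCysAlphabet, chars[p]), 1L)

    # indels outside guard bands and motif zones, applied right to left so
    # earlier coordinates stay valid
    guards <- sort(unique(c(
      unlist(lapply(FP_ALL, function(p) max(1L, p - FP_GUARD):(p + FP_GUARD))),
      zonePos)))
    nIndel <- if (indelRate > 0) stats::rpois(1L, indelRate * L) else 0L
    indelPos <- sort(sample(setdiff(5:(L - 5L), guards),
                            min(nIndel, 50L)), decreasing = TRUE)
    for (p in indelPos) {
      len <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {
        if (all(!((p:(p + len - 1L)) %in% guards)) && p + len - 1L <= length(chars))
          chars <- chars[-(p:(p + len - 1L))]
      } else {
        chars <- append(chars, sample(.nonCysAlphabet, len, replace = TRUE),
                        after = p)
      }
    }

    rec <- proteinRecord(id, paste(chars, collapse = ""))
    attr(rec, "fingerprintPositions") <- FP_ALL
    attr(rec, "motifZones") <- zones
    counts <- vapply(names(CLUSTER_FE), function(t)
      sum(types == t), integer(1))
    attr(rec, "truth") <- data.frame(
      id = id, class = cls, background_identity = backgroundIdentity,
      res_232 = fp$`232`, res_234 = fp$`234`, res_367 = fp$`367`,
      slbb = fp$slbb,
      n_fes4 = counts[["FeS4"]], n_fes2 = counts[["FeS2"]],
      n_hcluster = counts[["HCLUSTER"]],
      n_indels = length(indelPos), seed = as.integer(seed),
      stringsAsFactors = FALSE)
    rec
  })
}

#' Generate a labelled synthetic dataset
#'
#' Seeded, reproducible set of BF and non-BF planted sequences with a truth
#' table. With \code{classDivergence > 0} the two classes descend from
#' distinct class ancestors (themselves derived from the scaffold), giving
#' the elevated between-class divergence needed for clade-level simulations.
#'
#' @param nBf,nNonbf numbers of BF and non-BF sequences (total >= 1).
#' @param identityRange length-2 range of background identities sampled
#'   uniformly per sequence (default c(0.6, 0.9)).
#' @param seed integer seed governing scaffold and all plants.
#' @param indelRate expected indels per residue (default 0).
#' @param classDivergence per-class ancestor divergence from the scaffold
#'   (0 = both classes drawn straight from the scaffold).
#' @param scaffoldLength scaffold length (default 600).
#' @param outPrefix if given, writes \code{<prefix>.faa} and
#'   \code{<prefix>.truth.tsv}.
#' @return list with \code{records} (AAStringSet), \code{truth}
#'   (data.frame), \code{scaffold}.
#' @export
generateDataset <- function(nBf, nNonbf, identityRange = c(0.6, 0.9),
                            seed = 1L, indelRate = 0, classDivergence = 0,
                            scaffoldLength = 600L, outPrefix = NULL) {
  stopifnot(nBf >= 0, nNonbf >= 0, nBf + nNonbf >= 1,
            length(identityRange) == 2L,
            identityRange[1] <= identityRange[2],
            classDivergence >= 0, classDivergence < 1)
  scaffold <- makeReferenceScaffold(scaffoldLength, seed)
  parents <- list(BF = scaffold, nonBF = scaffold)
  if (classDivergence > 0) {
    parents$BF <- plantSequence(scaffold, "BF", 1 - classDivergence,
                                seed = seed + 900001L, id = "BF_ancestor")
    parents$nonBF <- plantSequence(scaffold, "nonBF", 1 - classDivergence,
                                   seed = seed + 900002L,
                                   id = "nonBF_ancestor")
  }
  classes <- c(rep("BF", nBf), rep("nonBF", nNonbf))
  idents <- .withSeed(seed + 700001L,
    stats::runif(length(classes), identityRange[1], identityRange[2]))
  recs <- vector("list", length(classes))
  truths <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cls <- classes[i]
    rec <- plantSequence(parents[[cls]], cls, idents[i],
                         indelRate = indelRate, seed = seed + i,
                         id = sprintf("%s_%03d", cls, i))
    recs[[i]] <- rec
    truths[[i]] <- attr(rec, "truth")
  }
  records <- do.call(c, lapply(recs, function(r) {
    attributes(r)[c("truth", "fingerprintPositions", "motifZones")] <- NULL
    r
  }))
  truth <- do.call(rbind, truths)
  if (!is.null(outPrefix)) {
    writeFasta(records, paste0(outPrefix, ".faa"))
    utils::write.table(truth, paste0(outPrefix, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(records = records, truth = truth, scaffold = scaffold)
}

#' Cumulative mutation ladder for one planted sequence
#'
#' One planted sequence degraded along a single mutation trajectory: the
#' mutation stream is drawn once, and each rung applies a prefix of it, so
#' a later rung contains every substitution of the earlier ones. Used to
#' check that classification degrades monotonically (a verdict may decay to
#' ambiguous but never flip directly between classes).
#'
#' @param scaffold output of [makeReferenceScaffold()].
#' @param cls "BF" or "nonBF".
#' @param identities decreasing identity levels
#'   (default \code{seq(0.9, 0.1, by = -0.1)}).
#' @param seed integer seed.
#' @return an [Biostrings::AAStringSet], one rung per identity, named
#'   \code{rung_<identity>}.
#' @export
mutationLadder <- function(scaffold, cls = c("BF", "nonBF"),
                           identities = seq(0.9, 0.1, by = -0.1),
                           seed = 1L) {
  cls <- match.arg(cls)
  stopifnot(all(diff(identities) < 0))
  base <- plantSequence(scaffold, cls, backgroundIdentity = 1,
                        seed = seed, id = "base")
  .withSeed(seed + 31L, {
    chars0 <- strsplit(as.character(base)[[1]], "")[[1]]
    L <- length(chars0)
    hits <- scanClusters(base)
    protected <- c(FP_ALL, unlist(hits@cysPositions))
    mutable <- sample(setdiff(seq_len(L), protected))  # mutation order
    repl <- vapply(mutable, function(p)
      sample(setdiff(.nonCysAlphabet, chars0[p]), 1L), character(1))
    rungs <- lapply(identities, function(idy) {
      n <- min(round((1 - idy) * L), length(mutable))
      chars <- chars0
      if (n > 0) chars[mutable[seq_len(n)]] <- repl[seq_len(n)]
      paste(chars, collapse = "")
    })
    out <- Biostrings::AAStringSet(unlist(rungs))
    names(out) <- sprintf("rung_%0.2f", identities)
    out
  })
}
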
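# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomProtein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exhaustive global-alignment score: enumerate every monotone set of matched
# column pairs (sum over k of choose(m,k)*choose(n,k) matchings) and charge
# each maximal unmatched run as one affine gap (open + len * extend). The
# optimum over matchings equals the optimal affine Needleman-Wunsch score.
bruteForceAlignScore <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  S <- scheme$matrix; go <- scheme$gapOpen; ge <- scheme$gapExtend
  gapCost <- function(idx, len) {
    unmatched <- len - length(idx)
    if (unmatched == 0L) return(0)
    segs <- diff(c(0L, idx, len + 1L)) - 1L
    sum(segs > 0L) * go + unmatched * ge
  }
  best <- gapCost(integer(0), m) + gapCost(integer(0), n)
  for (k in seq_len(min(m, n))) {
    ia <- if (k == m) matrix(seq_len(m), nrow = 1L) else t(utils::combn(m, k))
    ib <- if (k == n) matrix(seq_len(n), nrow = 1L) else t(utils::combn(n, k))
    for (i in seq_len(nrow(ia))) {
      subA <- av[ia[i, ]]
      costA <- gapCost(ia[i, ], m)
      for (j in seq_len(nrow(ib))) {
        sc <- sum(S[cbind(subA, bv[ib[j, ]])]) + costA +
          gapCost(ib[j, ], n)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# column-count p-distance oracle
pDistOracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  shared <- which(av != "-" & bv != "-")
  sum(av[shared] != bv[shared]) / length(shared)
}

# independent net-charge function for pI checks (Henderson-Hasselbalch)
netChargeOracle <- function(seq, pH, pka = defaultPkaTable()) {
  chars <- strsplit(seq, "")[[1]]
  cnt <- function(a) sum(chars == a)
  plus <- function(pk, n) n / (1 + 10^(pH - pk))
  minus <- function(pk, n) -n / (1 + 10^(pk - pH))
  plus(pka[["Nterm"]], 1) + plus(pka[["H"]], cnt("H")) +
    plus(pka[["K"]], cnt("K")) + plus(pka[["R"]], cnt("R")) +
    minus(pka[["Cterm"]], 1) + minus(pka[["C"]], cnt("C")) +
    minus(pka[["D"]], cnt("D")) + minus(pka[["E"]], cnt("E")) +
    minus(pka[["Y"]], cnt("Y"))
}
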
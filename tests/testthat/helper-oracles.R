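# Independent brute-force oracles and fixture builders used across tests.

ACGT <- c("A", "C", "G", "T")

allKmers <- function(k) {
  grid <- do.call(expand.grid,
                  c(rep(list(ACGT), k), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = ""))
}

# enumerate every substring position independently; skip windows with
# non-ACGT characters
naiveKmerCounts <- function(seq, k) {
  n <- nchar(seq)
  words <- substring(seq, seq_len(n - k + 1L), k:n)
  words <- words[grepl("^[ACGT]+$", words)]
  as.integer(table(factor(words, levels = allKmers(k))))  # allKmers order
}

randSeq <- function(n, alphabet = ACGT)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# site-by-site p-distance with pairwise deletion
naivePDistance <- function(a, b) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  comp <- a %in% ACGT & b %in% ACGT
  sum(a[comp] != b[comp]) / sum(comp)
}

# two species, two accessions each, from literal sequences
twoSpeciesDataset <- function(seqsA, seqsB, more = NULL) {
  seqs <- c(seqsA, seqsB, unlist(more))
  species <- c(rep("SpA", length(seqsA)), rep("SpB", length(seqsB)),
               rep(names(more), vapply(more, length, 1L)))
  accession <- unlist(lapply(c(list(seqsA, seqsB), unname(more)),
                             function(x) as.character(seq_along(x))))
  BarcodeDataset(seqs, species, accession)
}

# constructed mini-barcode fixture: species carry diagnostic G-runs with
# distinct GG counts confined to alignment columns 1..95 (pairwise GG count
# gap >= 2 windows), shared A/C intraspecific polymorphism at columns
# 101..150, and an invariant ACGT-repeat core beyond -- so resolution
# survives any 3' trimming that keeps the signature block and collapses once
# the 5' block is removed
makeMiniBarcodeFixture <- function(nSpecies = 6, acc = 4, seed = 1,
                                   flipP = 0.35) {
  stopifnot(nSpecies <= 6)
  set.seed(seed)
  base <- c(rep(c("A", "C"), length.out = 150),
            rep(c("A", "C", "G", "T"), length.out = 450))
  cursor <- 3L
  seqs <- character(0); species <- character(0); accession <- character(0)
  for (i in seq_len(nSpecies)) {
    s <- base
    runLen <- i + 1L
    for (r in 1:2) {
      s[cursor:(cursor + runLen - 1L)] <- "G"
      cursor <- cursor + runLen + 2L
    }
    stopifnot(cursor <= 96L)
    for (j in seq_len(acc)) {
      sj <- s
      flip <- 100L + which(stats::runif(50) < flipP)
      sj[flip] <- ifelse(sj[flip] == "A", "C", "A")
      seqs <- c(seqs, paste(sj, collapse = ""))
      species <- c(species, sprintf("Fix%02d", i))
      accession <- c(accession, as.character(j))
    }
  }
  BarcodeDataset(seqs, species, accession)
}

# mean number of discriminating oligonucleotides per resolved pair
meanDiscOligos <- function(ds, k) {
  rm <- resolutionMatrix(ds, k)
  n <- vapply(Filter(function(ev) isTRUE(ev$resolved), rm@evidence),
              function(ev) nrow(ev$discriminating), 1)
  if (length(n)) mean(n) else 0
}

# expected p-distance between two tips whose branches carry substitution
# probabilities d1 and d2 under the uniform (Jukes-Cantor-like) model:
# sites agree when both branches are silent or both hit the same target base
expectedPDiff <- function(d1, d2) 1 - ((1 - d1) * (1 - d2) + d1 * d2 / 3)
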
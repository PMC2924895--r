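#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among compared sites; a site is compared
#' only when both sequences carry an unambiguous A/C/G/T base there
#' (pairwise deletion of gaps and ambiguity codes). With
#' \code{deletion = "complete"} the comparable-site mask must be applied at
#' the dataset level, so this function only exposes pairwise deletion; see
#' [pDistanceMatrix()] for the complete-deletion variant.
#'
#' @param a,b aligned DNA strings of equal (gapped) length.
#' @return p-distance in [0, 1].
#' @examples
#' pDistance("ACGT", "ACGA")  # 0.25
#' pDistance("AC-T", "ACGT")  # 0: 3 compared sites, none differ
#' @export
pDistance <- function(a, b) {
  a <- strsplit(toupper(as.character(a)), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(as.character(b)), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b))
    stop("sequences must have equal aligned length", call. = FALSE)
  comp <- a %in% .ACGT & b %in% .ACGT
  if (!any(comp))
    stop("no comparable site: p-distance undefined", call. = FALSE)
  sum(a[comp] != b[comp]) / sum(comp)
}

#' Pairwise p-distance matrix of an aligned dataset
#'
#' @param ds an aligned [BarcodeDataset-class].
#' @param deletion \code{"pairwise"} (default): sites with a gap or
#'   ambiguity code in either member of a pair are excluded per pair;
#'   \code{"complete"}: columns with any gap/ambiguity in any record are
#'   excluded globally first.
#' @return symmetric numeric matrix, rows/cols named
#'   \code{species|accession}.
#' @export
pDistanceMatrix <- function(ds, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (!isAligned(ds))
    stop("p-distance requires an aligned (equal-width) dataset",
         call. = FALSE)
  chars <- .charMatrix(ds)
  valid <- matrix(chars %in% .ACGT, nrow = nrow(chars))
  if (deletion == "complete") {
    keep <- colSums(valid) == nrow(chars)
    if (!any(keep))
      stop("no comparable site under complete deletion", call. = FALSE)
    chars <- chars[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop(sprintf("no comparable site between '%s' and '%s'",
                     rownames(chars)[i], rownames(chars)[j]), call. = FALSE)
      d[i, j] <- d[j, i] <- sum(chars[i, comp] != chars[j, comp]) / nc
    }
  }
  d
}

#' Euclidean distance between two k-mer frequency profiles
#'
#' D = sqrt( sum over all 4^k oligonucleotides of (F1 - F2)^2 ), the
#' composition distance used for oligonucleotide-frequency barcoding. No 1/N
#' normalisation is applied; any positive scale factor leaves the
#' min-interspecific vs max-intraspecific resolution criterion unchanged.
#'
#' @param p1,p2 k-mer frequency vectors of equal k (as returned by
#'   [kmerFrequencies()] or rows of [kmerFrequencyMatrix()]).
#' @return non-negative distance; 0 iff the profiles are identical.
#' @export
euclideanDistance <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("profiles have different k (different numbers of oligonucleotides)",
         call. = FALSE)
  k1 <- attr(p1, "k"); k2 <- attr(p2, "k")
  if (!is.null(k1) && !is.null(k2) && k1 != k2)
    stop("profiles have different k", call. = FALSE)
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

#' Pairwise Euclidean k-mer distance matrix
#'
#' @param ds a [BarcodeDataset-class] (gaps removed for counting).
#' @param k k-mer size.
#' @return symmetric numeric matrix over accessions.
#' @export
kmerDistanceMatrix <- function(ds, k) {
  freqs <- kmerFrequencyMatrix(ds, k)
  as.matrix(stats::dist(freqs, method = "euclidean"))
}

#' Distance-based species resolution (barcoding-gap criterion)
#'
#' A species is resolved when the minimum interspecific distance involving
#' any of its accessions is strictly larger than its maximum intraspecific
#' distance. Species with fewer than 2 accessions have no intraspecific
#' distance and are marked not evaluable.
#'
#' @param ds a [BarcodeDataset-class]; must be aligned for
#'   \code{metric = "p"}.
#' @param metric \code{"p"} (uncorrected p-distance, aligned view) or
#'   \code{"euclid"} (Euclidean k-mer distance, degapped view).
#' @param k k-mer size, required for \code{metric = "euclid"}.
#' @param deletion passed to [pDistanceMatrix()] for \code{metric = "p"}.
#' @return list with \code{per_species} data.frame (species_id, evaluable,
#'   max_intra, min_inter, resolved) and \code{percent} (100 x resolved /
#'   evaluable).
#' @export
distanceResolution <- function(ds, metric = c("p", "euclid"), k = 2L,
                               deletion = "pairwise") {
  metric <- match.arg(metric)
  d <- if (metric == "p") pDistanceMatrix(ds, deletion)
       else kmerDistanceMatrix(ds, k)
  sp <- ds@species
  ids <- speciesIds(ds)
  rows <- lapply(ids, function(s) {
    own <- which(sp == s)
    other <- which(sp != s)
    evaluable <- length(own) >= 2L
    maxIntra <- if (evaluable) max(d[own, own][upper.tri(d[own, own])])
                else NA_real_
    minInter <- if (length(other)) min(d[own, other, drop = FALSE])
                else NA_real_
    data.frame(species_id = s, evaluable = evaluable,
               max_intra = maxIntra, min_inter = minInter,
               resolved = if (evaluable) minInter > maxIntra else NA,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (!any(per$evaluable))
    stop("no species with >= 2 accessions; criterion undefined",
         call. = FALSE)
  list(per_species = per,
       percent = 100 * sum(per$resolved[per$evaluable]) /
         sum(per$evaluable))
}
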
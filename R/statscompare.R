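#' Per-pair barcoding-gap deltas and OFR support
#'
#' For every species pair where both species have >= 2 accessions:
#' \code{p_delta} = (minimum interspecific p-distance between the two
#' species' accessions) - (maximum intraspecific p-distance within either);
#' \code{euclid_delta} the same on Euclidean k-mer distances; \code{n_ofr}
#' the number of oligonucleotides whose frequency ranges are separated by at
#' least the dataset threshold t. Positive deltas indicate a barcoding gap
#' for the pair.
#'
#' @param ds an aligned [BarcodeDataset-class] (p-distance needs the aligned
#'   view; frequencies use the degapped view).
#' @param k k-mer size.
#' @return data.frame: species_a, species_b, p_delta, euclid_delta, n_ofr.
#' @export
pairwiseDeltas <- function(ds, k = 2L) {
  dp <- pDistanceMatrix(ds)
  de <- kmerDistanceMatrix(ds, k)
  rm <- resolutionMatrix(ds, k)
  sp <- ds@species
  nAcc <- accessionCounts(ds)
  ids <- names(nAcc)[nAcc >= 2L]
  out <- list()
  delta <- function(d, ia, ib) {
    intra <- max(d[ia, ia][upper.tri(d[ia, ia])],
                 d[ib, ib][upper.tri(d[ib, ib])])
    min(d[ia, ib]) - intra
  }
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      ia <- which(sp == ids[i]); ib <- which(sp == ids[j])
      ev <- pairEvidence(rm, ids[i], ids[j])
      out[[length(out) + 1L]] <- data.frame(
        species_a = ids[j], species_b = ids[i],
        p_delta = delta(dp, ia, ib),
        euclid_delta = delta(de, ia, ib),
        n_ofr = nrow(ev$discriminating),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    stop("no species pair with >= 2 accessions each", call. = FALSE)
  do.call(rbind, out)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param xs,ys numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with \code{r} and \code{p}.
#' @export
pearsonCorrelation <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3L)
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  if (stats::var(xs) == 0 || stats::var(ys) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(xs, ys, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Arcsine transform of a percentage
#'
#' \code{asin(sqrt(p/100))}, the variance-stabilising transform commonly
#' applied to percent-resolution data before ANOVA.
#'
#' @param percent percentage in [0, 100].
#' @return transformed value in [0, pi/2], radians.
#' @export
arcsineTransform <- function(percent) {
  if (any(percent < 0 | percent > 100))
    stop("percent must lie in [0, 100]", call. = FALSE)
  asin(sqrt(percent / 100))
}

#' Compare the six species-resolution methods on one dataset
#'
#' Runs, on the identical record set: OFR with di- and trinucleotides
#' (degapped view), the p-distance and Euclidean (di- and trinucleotide)
#' barcoding-gap criteria, and the simple-character criterion (aligned
#' view), and the Pearson correlations between per-pair p-distance deltas
#' and (a) Euclidean deltas, (b) the number of non-overlapping OFRs.
#'
#' @param ds an aligned [BarcodeDataset-class].
#' @param mode resolution mode for the matrix-based methods
#'   ("species"/"pairs").
#' @param characterRequire passed to [characterResolution()].
#' @param deltaK k-mer size for the per-pair delta table (default 2).
#' @return list with \code{percent} (named numeric: p_distance, euclid_di,
#'   euclid_tri, characters, ofr_di, ofr_tri), \code{correlations} (list
#'   p_vs_euclid, p_vs_nofr, each with r and p), and \code{deltas} (the
#'   per-pair table).
#' @export
compareMethods <- function(ds, mode = "species",
                           characterRequire = "pure", deltaK = 2L) {
  if (!isAligned(ds))
    stop("compareMethods() requires an aligned dataset (p-distance and ",
         "characters operate on alignment columns)", call. = FALSE)
  pct <- c(
    p_distance = distanceResolution(ds, "p")$percent,
    euclid_di = distanceResolution(ds, "euclid", k = 2L)$percent,
    euclid_tri = distanceResolution(ds, "euclid", k = 3L)$percent,
    characters = percentResolution(characterResolution(ds, characterRequire),
                                   mode),
    ofr_di = percentResolution(resolutionMatrix(ds, 2L), mode),
    ofr_tri = percentResolution(resolutionMatrix(ds, 3L), mode)
  )
  deltas <- pairwiseDeltas(ds, deltaK)
  cors <- list(p_vs_euclid = NULL, p_vs_nofr = NULL)
  if (nrow(deltas) >= 3L) {
    cors$p_vs_euclid <- tryCatch(
      pearsonCorrelation(deltas$p_delta, deltas$euclid_delta),
      error = function(e) NULL)
    cors$p_vs_nofr <- tryCatch(
      pearsonCorrelation(deltas$p_delta, deltas$n_ofr),
      error = function(e) NULL)
  }
  list(percent = pct, correlations = cors, deltas = deltas)
}
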
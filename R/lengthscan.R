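#' Mini-barcode trimming scan
#'
#' Removes blocks of alignment columns from one end in coarse steps,
#' recomputing at every truncation the degapped dataset, its mean length,
#' the OFR threshold (which grows as sequences shorten), the resolution
#' matrix, percent resolution, and the mean number of discriminating
#' oligonucleotides per resolved pair. At the first truncation whose
#' resolution drops below the running maximum, the scan rewinds one coarse
#' step and proceeds in fine steps until resolution drops again, locating
#' the shortest average length that still attains the maximum resolution.
#'
#' @param ds an aligned [BarcodeDataset-class] with >= 2 species.
#' @param k k-mer size for the OFR criterion.
#' @param end end to trim: \code{"5p"} or \code{"3p"}.
#' @param coarse,fine step sizes in alignment columns (defaults 50 and 10).
#' @param mode resolution mode passed to [percentResolution()].
#' @param minAccessions passed to [resolutionMatrix()].
#' @return a [LengthScanResult-class].
#' @export
trimScan <- function(ds, k = 2L, end = c("5p", "3p"), coarse = 50L,
                     fine = 10L, mode = "species", minAccessions = 2L) {
  end <- match.arg(end)
  if (!isAligned(ds))
    stop("trimScan() requires an aligned (equal-width) dataset",
         call. = FALSE)
  wid <- Biostrings::width(ds@seqs)[1L]
  if (wid <= coarse)
    stop(sprintf("alignment width %d is not longer than one coarse step (%d)",
                 wid, coarse), call. = FALSE)

  evalAt <- function(ncut) {
    sub <- if (ncut == 0L) ds
           else if (end == "5p")
             BarcodeDataset(XVector::subseq(ds@seqs, start = ncut + 1L),
                            ds@species, ds@accession, aligned = TRUE)
           else
             BarcodeDataset(XVector::subseq(ds@seqs, end = wid - ncut),
                            ds@species, ds@accession, aligned = TRUE)
    dg <- degap(sub)
    rm <- resolutionMatrix(dg, k, minAccessions = minAccessions)
    resolvedPairs <- Filter(function(ev) isTRUE(ev$resolved), rm@evidence)
    nDisc <- vapply(resolvedPairs, function(ev) nrow(ev$discriminating), 1)
    data.frame(
      columns_removed = ncut,
      avg_length = averageLength(dg),
      percent = percentResolution(rm, mode),
      mean_disc_oligos = if (length(nDisc)) mean(nDisc) else 0,
      threshold = rm@threshold)
  }

  canEval <- function(ncut) {
    # every record must keep at least k non-gap characters
    keep <- if (end == "5p") XVector::subseq(ds@seqs, start = ncut + 1L)
            else XVector::subseq(ds@seqs, end = wid - ncut)
    all(Biostrings::width(keep) -
        Biostrings::letterFrequency(keep, .GAP) >= max(k + 1L, 2L))
  }

  points <- list(evalAt(0L))
  maxPct <- points[[1L]]$percent
  dropAt <- NA_integer_
  ncut <- coarse
  while (ncut < wid && canEval(ncut)) {
    pt <- evalAt(ncut)
    points[[length(points) + 1L]] <- pt
    if (pt$percent < maxPct - 1e-9) { dropAt <- ncut; break }
    maxPct <- max(maxPct, pt$percent)
    ncut <- ncut + coarse
  }
  if (!is.na(dropAt) && fine < coarse) {
    for (f in seq(dropAt - coarse + fine, dropAt - fine, by = fine)) {
      if (f <= 0L || !canEval(f)) next
      pt <- evalAt(f)
      points[[length(points) + 1L]] <- pt
      if (pt$percent < maxPct - 1e-9) break
    }
  }
  tab <- do.call(rbind, points)
  tab <- tab[order(-tab$avg_length), ]
  tab <- tab[!duplicated(tab$columns_removed), ]
  rownames(tab) <- NULL
  best <- max(tab$percent)
  minFull <- if (best <= 0) tab$avg_length[1L]
             else min(tab$avg_length[tab$percent >= best - 1e-9])
  new("LengthScanResult", end = end, k = as.integer(k), points = tab,
      minFullLength = minFull)
}

#' @export
setMethod("show", "LengthScanResult", function(object) {
  cat(sprintf(
    "LengthScanResult (%s end, k = %d): %d points, max resolution %.1f%%, shortest length at max %.1f nt\n",
    object@end, object@k, nrow(object@points), max(object@points$percent),
    object@minFullLength))
  invisible(NULL)
})

#' @describeIn trimScan the scan table (one row per truncation).
#' @param res a LengthScanResult.
#' @export
scanPoints <- function(res) res@points

#' Shortest average length retaining the maximum resolution
#'
#' The smallest average retained length among scan points whose percent
#' resolution equals the maximum observed in the scan; when nothing is ever
#' resolved (maximum 0%), the full input length, by convention.
#'
#' @param res a [LengthScanResult-class].
#' @return average length in nt.
#' @export
minLengthFullResolution <- function(res) {
  pts <- res@points
  if (!nrow(pts)) stop("empty scan", call. = FALSE)
  best <- max(pts$percent)
  if (best <= 0) return(pts$avg_length[1L])
  min(pts$avg_length[pts$percent >= best - 1e-9])
}
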
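.T_TOL <- 1e-12

#' OFR discrimination threshold
#'
#' t = 1/(a - k + 1): the frequency weight of one k-mer window in a sequence
#' of average length a, i.e. 1/(a-1) for dinucleotides and 1/(a-2) for
#' trinucleotides. Two species' frequency ranges for an oligonucleotide are
#' considered discriminating only when separated by at least t.
#'
#' @param averageLength mean ungapped sequence length a (nt); must exceed
#'   k - 1.
#' @param k k-mer size.
#' @return a [ThresholdSpec-class].
#' @examples
#' tValue(ofrThreshold(651, 2))  # 1/650
#' tValue(ofrThreshold(651, 3))  # 1/649
#' @export
ofrThreshold <- function(averageLength, k) {
  k <- as.integer(k)
  if (averageLength <= k - 1)
    stop(sprintf("average length %.1f is too short for k = %d",
                 averageLength, k), call. = FALSE)
  new("ThresholdSpec", k = k, averageLength = as.numeric(averageLength),
      t = 1 / (averageLength - k + 1))
}

#' @describeIn ofrThreshold numeric threshold value t.
#' @param ts a ThresholdSpec.
#' @export
tValue <- function(ts) ts@t

#' @export
setMethod("show", "ThresholdSpec", function(object) {
  cat(sprintf("ThresholdSpec: k = %d, a = %.2f nt, t = 1/(a-%d) = %.6g\n",
              object@k, object@averageLength, object@k - 1L, object@t))
  invisible(NULL)
})

#' Oligonucleotide frequency range of one species
#'
#' For every k-mer, the minimum and maximum frequency across the species'
#' accessions.
#'
#' @param ds a gap-free [BarcodeDataset-class] (gaps are removed if present).
#' @param speciesId species label present in \code{ds}.
#' @param k k-mer size.
#' @return an [OFRProfile-class].
#' @export
speciesOFR <- function(ds, speciesId, k) {
  if (!speciesId %in% ds@species)
    stop(sprintf("unknown species '%s'", speciesId), call. = FALSE)
  m <- kmerFrequencyMatrix(ds[ds@species == speciesId], k)
  new("OFRProfile", speciesId = speciesId, k = as.integer(k),
      lo = apply(m, 2L, min), hi = apply(m, 2L, max),
      nAccessions = nrow(m))
}

#' @export
setMethod("show", "OFRProfile", function(object) {
  w <- object@hi - object@lo
  cat(sprintf(
    "OFRProfile: species '%s', k = %d (%d oligos), %d accessions, mean range width %.4g\n",
    object@speciesId, object@k, length(object@lo), object@nAccessions,
    mean(w)))
  invisible(NULL)
})

#' @describeIn speciesOFR frequency ranges as a data.frame (oligo, lo, hi).
#' @param x an OFRProfile.
#' @export
ofrRanges <- function(x) {
  data.frame(oligo = names(x@lo), lo = unname(x@lo), hi = unname(x@hi),
             stringsAsFactors = FALSE)
}

# signed separation per oligo: positive = gap between the ranges,
# negative = overlap magnitude
.rangeGaps <- function(pa, pb) pmax(pb@lo - pa@hi, pa@lo - pb@hi)

#' Resolve one species pair by the OFR criterion
#'
#' An oligonucleotide discriminates the pair when its two frequency ranges
#' do not overlap and are separated by at least the threshold t (inclusive).
#' The pair is resolved when at least one oligonucleotide discriminates it.
#' Species with fewer than \code{minAccessions} accessions give a
#' not-evaluable outcome (resolved = NA), distinct from unresolved.
#'
#' @param pa,pb [OFRProfile-class] objects with equal k.
#' @param ts a [ThresholdSpec-class] with the same k.
#' @param minAccessions minimum accessions per species for the range to be
#'   meaningful (default 2).
#' @return list with elements \code{species_a}, \code{species_b},
#'   \code{resolved} (TRUE/FALSE/NA), \code{discriminating} (data.frame
#'   oligo, gap), \code{max_gap} (largest signed separation; negative values
#'   are overlap magnitudes), \code{evaluable}.
#' @export
resolvePair <- function(pa, pb, ts, minAccessions = 2L) {
  if (pa@k != pb@k || pa@k != ts@k)
    stop("k mismatch between profiles and threshold", call. = FALSE)
  evaluable <- pa@nAccessions >= minAccessions &&
    pb@nAccessions >= minAccessions
  gaps <- .rangeGaps(pa, pb)
  disc <- gaps >= ts@t - .T_TOL
  out <- list(
    species_a = pa@speciesId, species_b = pb@speciesId,
    resolved = if (evaluable) any(disc) else NA,
    discriminating = data.frame(oligo = names(gaps)[disc],
                                gap = unname(gaps[disc]),
                                stringsAsFactors = FALSE),
    max_gap = max(gaps),
    evaluable = evaluable
  )
  if (!evaluable) out$discriminating <- out$discriminating[0L, ]
  out
}

#' Binomial species-pair resolution matrix by the OFR criterion
#'
#' Evaluates every unordered species pair with the dataset-wide threshold
#' t = 1/(a - k + 1), where a is the mean ungapped length over all records.
#' Cell values: 1 resolved, 0 unresolved, NA not evaluable (a species with
#' fewer than \code{minAccessions} accessions).
#'
#' @param ds a [BarcodeDataset-class] with at least 2 species; gaps are
#'   removed for frequency computation.
#' @param k k-mer size (2 or 3 in standard use).
#' @param minAccessions minimum accessions per species (default 2; set 1 to
#'   allow zero-width ranges from singletons).
#' @param averageLength override for the mean length a used for the
#'   threshold (default: computed from \code{ds}).
#' @return a [ResolutionMatrix-class] with per-pair evidence.
#' @export
resolutionMatrix <- function(ds, k, minAccessions = 2L,
                             averageLength = NULL) {
  if (nSpecies(ds) < 2L)
    stop("at least 2 species are required", call. = FALSE)
  k <- as.integer(k)
  a <- if (is.null(averageLength)) averageLength(ds) else averageLength
  ts <- ofrThreshold(a, k)
  freqs <- kmerFrequencyMatrix(ds, k)
  sp <- factor(ds@species, levels = speciesIds(ds))
  lo <- apply(freqs, 2L, function(col) tapply(col, sp, min))
  hi <- apply(freqs, 2L, function(col) tapply(col, sp, max))
  nAcc <- accessionCounts(ds)
  ids <- speciesIds(ds)
  profiles <- lapply(ids, function(s)
    new("OFRProfile", speciesId = s, k = k,
        lo = stats::setNames(lo[s, ], colnames(freqs)),
        hi = stats::setNames(hi[s, ], colnames(freqs)),
        nAccessions = nAcc[[s]]))
  names(profiles) <- ids
  n <- length(ids)
  cells <- matrix(0, n, n, dimnames = list(ids, ids))
  evidence <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pr <- resolvePair(profiles[[i]], profiles[[j]], ts, minAccessions)
      val <- if (!pr$evaluable) NA_real_ else as.numeric(pr$resolved)
      cells[i, j] <- cells[j, i] <- val
      evidence[[.pairKey(ids[i], ids[j])]] <- pr
    }
  }
  new("ResolutionMatrix", speciesIds = ids, cells = cells,
      evidence = evidence, method = sprintf("ofr_k%d", k), threshold = ts@t)
}

.pairKey <- function(a, b) paste(sort(c(a, b)), collapse = "||")

#' @describeIn resolutionMatrix evidence for one species pair.
#' @param rm a ResolutionMatrix.
#' @param a,b species labels.
#' @export
pairEvidence <- function(rm, a, b) rm@evidence[[.pairKey(a, b)]]

#' @describeIn resolutionMatrix the 0/1/NA cell matrix.
#' @export
resolutionCells <- function(rm) rm@cells

#' @export
setMethod("show", "ResolutionMatrix", function(object) {
  up <- object@cells[upper.tri(object@cells)]
  cat(sprintf(
    "ResolutionMatrix (%s): %d species, %d/%d evaluable pairs resolved%s\n",
    object@method, length(object@speciesIds),
    sum(up == 1, na.rm = TRUE), sum(!is.na(up)),
    if (is.na(object@threshold)) "" else sprintf(", t = %.6g",
                                                 object@threshold)))
  invisible(NULL)
})

#' Percent species resolution from a resolution matrix
#'
#' Mode \code{"species"}: percentage of evaluable species resolved against
#' every other evaluable species. Mode \code{"pairs"}: percentage of
#' evaluable pairs resolved. Not-evaluable pairs are excluded from both
#' denominators.
#'
#' @param rm a [ResolutionMatrix-class].
#' @param mode \code{"species"} (default) or \code{"pairs"}.
#' @return percentage in [0, 100].
#' @export
percentResolution <- function(rm, mode = c("species", "pairs")) {
  mode <- match.arg(mode)
  cells <- rm@cells
  up <- cells[upper.tri(cells)]
  if (all(is.na(up)))
    stop("no evaluable species pair; percent resolution is undefined",
         call. = FALSE)
  if (mode == "pairs")
    return(100 * mean(up[!is.na(up)] == 1))
  evaluable <- vapply(seq_along(rm@speciesIds), function(i)
    !all(is.na(cells[i, -i])), TRUE)
  resolved <- vapply(which(evaluable), function(i) {
    row <- cells[i, evaluable]
    row <- row[-match(i, which(evaluable))]
    length(row) > 0L && all(row == 1, na.rm = FALSE)
  }, TRUE)
  100 * sum(resolved) / sum(evaluable)
}
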
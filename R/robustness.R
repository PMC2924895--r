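#' Worst-case frequency perturbation of an indel of length L
#'
#' Conservative bound of this package's design: an indel of length L
#' destroys or creates at most L + k - 1 sliding windows and shifts the
#' window count of a sequence of average length a by L, so the frequency of
#' a single oligonucleotide can move by at most
#' Delta(L) = (L + k - 1) / (a - L - k + 1). Strictly increasing in L;
#' kept in one function so an alternative bound can be swapped in.
#'
#' @param L indel length (nt), >= 1.
#' @param a average sequence length (nt).
#' @param k k-mer size.
#' @return the bound Delta(L); \code{Inf} when the denominator is
#'   non-positive (the indel exhausts the sequence).
#' @export
indelPerturbationBound <- function(L, a, k) {
  den <- a - L - k + 1
  ifelse(den > 0, (L + k - 1) / den, Inf)
}

#' Minimum indel length that can flip an OFR decision
#'
#' Deletions make sequences shorter than the dataset average, so they face a
#' weaker (larger) effective threshold and can turn an overlapping pair into
#' an apparent gap of at least t: a false positive (Type I). Insertions make
#' sequences longer, face a more stringent threshold, and can shrink a
#' sufficient gap below t: a false negative (Type II). Assuming all
#' accessions of a species are of equal length, the smallest indel length m
#' whose worst-case single-oligonucleotide perturbation
#' [indelPerturbationBound()] reaches the decision margin is returned:
#' margin |x| + t for deletions acting on the largest overlap, margin x - t
#' for insertions acting on the smallest sufficient gap (m = 1 when that
#' margin is non-positive, i.e. a borderline pair).
#'
#' @param ts a [ThresholdSpec-class].
#' @param x signed extreme separation between the two species' OFRs for the
#'   oligonucleotide with the largest gap or overlap: positive = gap,
#'   negative = overlap magnitude.
#' @param direction \code{"deletion"} (Type I risk) or \code{"insertion"}
#'   (Type II risk).
#' @return integer m >= 1, or \code{Inf} when no finite indel length reaches
#'   the margin before exhausting the average sequence length.
#' @export
minIndelForError <- function(ts, x, direction = c("deletion", "insertion")) {
  direction <- match.arg(direction)
  margin <- if (direction == "deletion") abs(x) + ts@t else x - ts@t
  if (direction == "insertion" && margin <= .T_TOL) return(1L)
  a <- ts@averageLength; k <- ts@k
  for (L in seq_len(max(1L, ceiling(a)))) {
    if (a - L - k + 1 <= 0) return(Inf)
    if (indelPerturbationBound(L, a, k) >= margin - .T_TOL) return(L)
  }
  Inf
}

#' Type I / Type II risk from length deviation of a species pair
#'
#' For a species pair whose sequence lengths deviate from the dataset
#' average: D_l is the excess of the longest sequence over the average
#' (insertions), D_s the shortfall of the shortest sequence under the
#' average (deletions). D_s > D_l indicates Type I risk (possible false
#' positive resolution), D_l > D_s indicates Type II risk (possible false
#' negative); equality is neutral.
#'
#' @param Dl,Ds non-negative length deviations (nt).
#' @return \code{"type_I"}, \code{"type_II"} or \code{"none"}.
#' @export
pairLengthRisk <- function(Dl, Ds) {
  if (Dl < 0 || Ds < 0)
    stop("length deviations must be non-negative", call. = FALSE)
  if (Ds > Dl) "type_I" else if (Dl > Ds) "type_II" else "none"
}

#' Indel risk audit of a resolution matrix
#'
#' For every evaluable species pair, derives the extreme OFR separation x
#' from the matrix evidence, the pair's length deviations D_l/D_s from the
#' dataset average, the implied error type, and the minimum indel length m
#' that could flip the pair's decision. Pairs with a non-"none" error type
#' are flagged.
#'
#' @param ds the [BarcodeDataset-class] the matrix was computed on.
#' @param rm the [ResolutionMatrix-class] (an OFR matrix with evidence).
#' @param ts the [ThresholdSpec-class] used for \code{rm} (default:
#'   recomputed from \code{ds} and the matrix's k).
#' @return data.frame with one row per evaluable pair: species_a, species_b,
#'   resolved, x, D_l, D_s, error_type, m, flagged.
#' @export
datasetIndelAudit <- function(ds, rm, ts = NULL) {
  if (!length(rm@evidence))
    stop("resolution matrix carries no pair evidence to audit",
         call. = FALSE)
  k <- as.integer(sub("^ofr_k", "", rm@method))
  if (is.na(k))
    stop("indel audit requires an OFR resolution matrix", call. = FALSE)
  if (is.null(ts)) ts <- ofrThreshold(averageLength(ds), k)
  a <- ts@averageLength
  len <- ungappedLengths(ds)
  bySpecies <- split(len, ds@species)
  if (any(vapply(bySpecies, function(x) length(unique(x)) > 1L, TRUE)))
    warning("accessions of unequal length within a species; ",
            "per-pair indel bounds assume equal lengths", call. = FALSE)
  rows <- lapply(rm@evidence, function(ev) {
    if (!ev$evaluable) return(NULL)
    pairLen <- c(bySpecies[[ev$species_a]], bySpecies[[ev$species_b]])
    Dl <- max(0, round(max(pairLen) - a))
    Ds <- max(0, round(a - min(pairLen)))
    direction <- if (isTRUE(ev$resolved)) "insertion" else "deletion"
    data.frame(
      species_a = ev$species_a, species_b = ev$species_b,
      resolved = ev$resolved, x = ev$max_gap, D_l = Dl, D_s = Ds,
      error_type = pairLengthRisk(Dl, Ds),
      m = minIndelForError(ts, ev$max_gap, direction),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop("no evaluable pair to audit", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$flagged <- out$error_type != "none"
  out
}
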
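#' @import methods
#' @importFrom Biostrings DNAStringSet letterFrequency width
NULL

#' BarcodeDataset: a set of barcode-locus sequences grouped by species
#'
#' Container for a multi-species, multi-accession barcode dataset. Sequences
#' are held as a \link[Biostrings]{DNAStringSet} (gapped when aligned) and
#' every record carries a species and an accession label. The dataset-wide
#' mean ungapped length (the quantity from which the OFR discrimination
#' threshold is derived) is available through \code{averageLength()}.
#'
#' @slot seqs DNAStringSet of residues; may contain \code{-} gap characters
#'   when the dataset is aligned.
#' @slot species character vector, species label per record.
#' @slot accession character vector, accession label per record.
#' @slot aligned logical; \code{TRUE} when all records have equal (gapped)
#'   width so that column-wise operations (trimming, p-distance, diagnostic
#'   characters) are defined.
#'
#' @seealso [BarcodeDataset()], [readBarcodeFasta()], [degap()],
#'   [trimCommonWindow()]
#' @export
setClass("BarcodeDataset",
  representation(
    seqs = "DNAStringSet",
    species = "character",
    accession = "character",
    aligned = "logical"
  )
)

setValidity("BarcodeDataset", function(object) {
  n <- length(object@seqs)
  msgs <- character()
  if (n == 0L) msgs <- c(msgs, "dataset contains no sequences")
  if (length(object@species) != n || length(object@accession) != n)
    msgs <- c(msgs, "species/accession labels must match number of sequences")
  if (n > 0L) {
    if (any(Biostrings::width(object@seqs) == 0L))
      msgs <- c(msgs, "empty sequence record")
    key <- paste(object@species, object@accession, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, sprintf(
        "duplicate (species, accession) pair: %s",
        paste(object@species[duplicated(key)][1L],
              object@accession[duplicated(key)][1L], sep = "|")))
    if (length(object@aligned) != 1L || is.na(object@aligned))
      msgs <- c(msgs, "'aligned' must be TRUE or FALSE")
    else if (object@aligned &&
             length(unique(Biostrings::width(object@seqs))) != 1L)
      msgs <- c(msgs, "aligned dataset must have equal gapped lengths")
  }
  if (length(msgs)) msgs else TRUE
})

#' ThresholdSpec: the OFR discrimination threshold t
#'
#' For k-mers of size k and mean ungapped sequence length a, the minimum
#' frequency gap required between two species' oligonucleotide frequency
#' ranges is t = 1/(a - k + 1): 1/(a-1) for dinucleotides and 1/(a-2) for
#' trinucleotides. This is the frequency contribution of a single k-mer
#' window in a sequence of average length, so two ranges count as separated
#' only when they differ by at least one window's worth of frequency.
#'
#' @slot k integer k-mer size.
#' @slot averageLength numeric, mean ungapped sequence length (nt).
#' @slot t numeric threshold value.
#' @seealso [ofrThreshold()]
#' @export
setClass("ThresholdSpec",
  representation(k = "integer", averageLength = "numeric", t = "numeric")
)

setValidity("ThresholdSpec", function(object) {
  if (object@averageLength <= object@k - 1)
    return("averageLength must exceed k - 1")
  if (object@t <= 0) return("t must be positive")
  TRUE
})

#' OFRProfile: per-species oligonucleotide frequency ranges
#'
#' For one species, the minimum and maximum frequency of every k-mer across
#' the species' accessions.
#'
#' @slot speciesId character species label.
#' @slot k integer k-mer size.
#' @slot lo,hi named numeric vectors over all 4^k A/C/G/T oligonucleotides;
#'   minimum and maximum frequency across accessions.
#' @slot nAccessions integer number of accessions the range is built from.
#' @seealso [speciesOFR()], [resolvePair()]
#' @export
setClass("OFRProfile",
  representation(
    speciesId = "character",
    k = "integer",
    lo = "numeric",
    hi = "numeric",
    nAccessions = "integer"
  )
)

setValidity("OFRProfile", function(object) {
  if (length(object@lo) != 4L^object@k || length(object@hi) != 4L^object@k)
    return("lo/hi must cover all 4^k oligonucleotides")
  if (!identical(names(object@lo), names(object@hi)))
    return("lo/hi must be keyed identically")
  if (any(object@lo < 0) || any(object@hi > 1 + 1e-12) ||
      any(object@lo > object@hi + 1e-12))
    return("ranges must satisfy 0 <= lo <= hi <= 1")
  if (object@nAccessions < 1L) return("nAccessions must be >= 1")
  TRUE
})

#' ResolutionMatrix: binary species-pair resolution matrix
#'
#' Symmetric 0/1 matrix over species ("binomial matrix"): 1 when the pair is
#' resolved by the criterion that produced the matrix, 0 when unresolved, NA
#' when the pair could not be evaluated (e.g. a species with fewer
#' accessions than required). Per-pair supporting evidence is retained.
#'
#' @slot speciesIds ordered character vector of species labels.
#' @slot cells symmetric numeric matrix of 0/1/NA, zero/ignored diagonal.
#' @slot evidence named list, one entry per unordered pair (key
#'   \code{"A||B"} with A < B) holding the pair's evidence (for OFR: the
#'   discriminating oligonucleotides and their gaps; for characters: the
#'   diagnoses).
#' @slot method character, the criterion that produced the matrix.
#' @slot threshold numeric, the OFR threshold t used (NA for non-OFR
#'   methods).
#' @seealso [resolutionMatrix()], [characterResolution()],
#'   [percentResolution()]
#' @export
setClass("ResolutionMatrix",
  representation(
    speciesIds = "character",
    cells = "matrix",
    evidence = "list",
    method = "character",
    threshold = "numeric"
  )
)

setValidity("ResolutionMatrix", function(object) {
  m <- object@cells
  if (nrow(m) != length(object@speciesIds) || ncol(m) != nrow(m))
    return("cells must be square over speciesIds")
  if (!isTRUE(all.equal(m, t(m))) && !identical(m, t(m)))
    return("cells must be symmetric")
  ok <- m[!is.na(m)]
  if (length(ok) && !all(ok %in% c(0, 1)))
    return("cells must contain only 0, 1 or NA")
  TRUE
})

#' LengthScanResult: mini-barcode trimming scan
#'
#' Resolution as a function of end-trimming: percent species resolution and
#' mean number of discriminating oligonucleotides per resolved pair at each
#' retained length, scanned with a coarse step refined to a fine step around
#' the first drop in resolution.
#'
#' @slot end character, \code{"5p"} or \code{"3p"}: the trimmed end.
#' @slot k integer k-mer size used for the OFR criterion.
#' @slot points data.frame with columns \code{columns_removed},
#'   \code{avg_length}, \code{percent}, \code{mean_disc_oligos}, ordered by
#'   strictly decreasing \code{avg_length}.
#' @slot minFullLength numeric, shortest average retained length at which
#'   the maximum observed resolution is still attained (full input length by
#'   convention when nothing is ever resolved).
#' @seealso [trimScan()], [minLengthFullResolution()]
#' @export
setClass("LengthScanResult",
  representation(
    end = "character",
    k = "integer",
    points = "data.frame",
    minFullLength = "numeric"
  )
)
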
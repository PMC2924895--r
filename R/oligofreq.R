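#' @importFrom Biostrings DNAString oligonucleotideFrequency
NULL

.checkKmerInput <- function(seq, k) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (grepl(.GAP, seq, fixed = TRUE))
    stop("sequence contains gap characters; degap() before counting k-mers",
         call. = FALSE)
  if (nchar(seq) < k)
    stop(sprintf("sequence of length %d is too short for k = %d",
                 nchar(seq), k), call. = FALSE)
}

#' Count k-mers with a single-nucleotide sliding window
#'
#' Counts every length-k A/C/G/T word over all \code{length(seq) - k + 1}
#' window positions. Windows containing any non-ACGT character (ambiguity
#' codes such as N, R, Y) contribute to no count.
#'
#' @param seq a gap-free DNA string (character or
#'   \link[Biostrings]{DNAString}).
#' @param k word size (2 = dinucleotides, 3 = trinucleotides; any k >= 1).
#' @return named integer vector over all 4^k oligonucleotides.
#' @examples
#' kmerCounts("AAAA", 2)["AA"]   # 3
#' kmerCounts("ACGT", 3)         # ACG = 1, CGT = 1
#' @export
kmerCounts <- function(seq, k) {
  k <- as.integer(k)
  seq <- chartr("U", "T", toupper(as.character(seq)))
  .checkKmerInput(seq, k)
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                       width = k, step = 1L)
}

#' k-mer frequencies of one sequence
#'
#' Each count is divided by the total number of window positions,
#' \code{length(seq) - k + 1} (n-1 positions for dinucleotides, n-2 for
#' trinucleotides). With \code{denominator = "valid"} the number of windows
#' free of ambiguity codes is used instead, so frequencies always sum to 1.
#'
#' @inheritParams kmerCounts
#' @param denominator \code{"positions"} (default; all window positions) or
#'   \code{"valid"} (ambiguity-free windows only).
#' @return named numeric vector over all 4^k oligonucleotides, with
#'   attributes \code{k}, \code{n_windows} (valid windows) and
#'   \code{seq_length}.
#' @examples
#' kmerFrequencies("ACGTACGT", 2)[c("AC", "TA")]  # 2/7, 1/7
#' @export
kmerFrequencies <- function(seq, k, denominator = c("positions", "valid")) {
  denominator <- match.arg(denominator)
  counts <- kmerCounts(seq, k)
  nPos <- nchar(chartr("U", "T", toupper(as.character(seq)))) -
    as.integer(k) + 1L
  nValid <- sum(counts)
  den <- if (denominator == "positions") nPos else nValid
  if (den == 0L)
    stop("no usable k-mer window in sequence", call. = FALSE)
  structure(counts / den, k = as.integer(k), n_windows = nValid,
            seq_length = nchar(as.character(seq)))
}

#' k-mer frequency matrix of a dataset
#'
#' One row per record, one column per oligonucleotide; rows are the
#' per-accession frequency profiles from which species OFRs are built.
#'
#' @param ds a gap-free (or aligned; gaps are removed) [BarcodeDataset-class].
#' @param k word size.
#' @inheritParams kmerFrequencies
#' @return numeric matrix, records x 4^k, rownames \code{species|accession}.
#' @export
kmerFrequencyMatrix <- function(ds, k, denominator = c("positions", "valid")) {
  denominator <- match.arg(denominator)
  k <- as.integer(k)
  ds <- if (any(Biostrings::letterFrequency(ds@seqs, .GAP) > 0)) degap(ds)
        else ds
  len <- Biostrings::width(ds@seqs)
  if (any(len < k))
    stop(sprintf("record '%s' shorter than k = %d",
                 names(ds@seqs)[len < k][1L], k), call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(ds@seqs, width = k,
                                                 step = 1L)
  den <- if (denominator == "positions") len - k + 1L else rowSums(counts)
  if (any(den == 0))
    stop("record with no usable k-mer window", call. = FALSE)
  freqs <- counts / den
  rownames(freqs) <- paste(ds@species, ds@accession, sep = "|")
  freqs
}

#' Export per-accession k-mer profiles as a data frame
#'
#' @inheritParams kmerFrequencyMatrix
#' @return data.frame with species, accession and one column per
#'   oligonucleotide, suitable for writing as TSV.
#' @export
profileTable <- function(ds, k) {
  m <- kmerFrequencyMatrix(ds, k)
  cbind(data.frame(species_id = ds@species, accession_id = ds@accession,
                   stringsAsFactors = FALSE),
        as.data.frame(m, row.names = seq_len(nrow(m))))
}
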
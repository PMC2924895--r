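#' @importFrom Biostrings readBStringSet writeXStringSet
#' @importFrom XVector subseq
NULL

.GAP <- "-"
.ACGT <- c("A", "C", "G", "T")

#' Construct a BarcodeDataset
#'
#' @param seqs DNAStringSet, character vector of sequences, or anything
#'   coercible by [Biostrings::DNAStringSet()]. Sequences are upper-cased and
#'   U is mapped to T on ingest.
#' @param species,accession character vectors, one label per sequence.
#' @param aligned logical or NA; when NA, the dataset is flagged aligned iff
#'   all (gapped) widths are equal.
#' @return A [BarcodeDataset-class] object.
#' @examples
#' ds <- BarcodeDataset(c("ACGT", "ACGA"), species = c("A_x", "A_x"),
#'                      accession = c("1", "2"))
#' averageLength(ds)
#' @export
BarcodeDataset <- function(seqs, species, accession, aligned = NA) {
  if (is.character(seqs))
    seqs <- chartr("U", "T", toupper(seqs))
  seqs <- Biostrings::DNAStringSet(seqs)
  names(seqs) <- paste(species, accession, sep = "|")
  if (is.na(aligned))
    aligned <- length(unique(Biostrings::width(seqs))) == 1L
  new("BarcodeDataset", seqs = seqs, species = as.character(species),
      accession = as.character(accession), aligned = aligned)
}

#' @describeIn BarcodeDataset-class the underlying DNAStringSet.
#' @param ds,object a BarcodeDataset.
#' @export
sequences <- function(ds) ds@seqs

#' @describeIn BarcodeDataset-class per-record species labels.
#' @export
speciesOf <- function(ds) ds@species

#' @describeIn BarcodeDataset-class per-record accession labels.
#' @export
accessionOf <- function(ds) ds@accession

#' @describeIn BarcodeDataset-class unique species labels, in first-seen
#'   order.
#' @export
speciesIds <- function(ds) unique(ds@species)

#' @describeIn BarcodeDataset-class number of species.
#' @export
nSpecies <- function(ds) length(unique(ds@species))

#' @describeIn BarcodeDataset-class named integer vector of accessions per
#'   species.
#' @export
accessionCounts <- function(ds) {
  tab <- table(factor(ds@species, levels = speciesIds(ds)))
  stats::setNames(as.integer(tab), names(tab))
}

#' @describeIn BarcodeDataset-class TRUE when the records form an alignment
#'   (equal gapped widths).
#' @export
isAligned <- function(ds) ds@aligned

#' @describeIn BarcodeDataset-class ungapped length (nt) of every record.
#' @export
ungappedLengths <- function(ds) {
  as.integer(Biostrings::width(ds@seqs) -
             Biostrings::letterFrequency(ds@seqs, .GAP))
}

#' @describeIn BarcodeDataset-class mean ungapped sequence length, the
#'   quantity \code{a} from which the OFR threshold is derived.
#' @export
averageLength <- function(ds) mean(ungappedLengths(ds))

#' @export
setMethod("show", "BarcodeDataset", function(object) {
  cat(sprintf(
    "BarcodeDataset: %d records, %d species, %s, mean ungapped length %.1f nt\n",
    length(object@seqs), nSpecies(object),
    if (object@aligned) sprintf("aligned (width %d)",
                                Biostrings::width(object@seqs)[1L])
    else "unaligned",
    averageLength(object)))
  invisible(NULL)
})

#' @export
setMethod("length", "BarcodeDataset", function(x) length(x@seqs))

#' Subset a BarcodeDataset by record index
#' @param x a BarcodeDataset.
#' @param i integer or logical record index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "BarcodeDataset", function(x, i, j, ..., drop = FALSE) {
  BarcodeDataset(x@seqs[i], x@species[i], x@accession[i], aligned = NA)
})

.parseHeaders <- function(headers, delim) {
  parts <- strsplit(headers, delim, fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad))
    stop(sprintf(
      "header does not match 'species%saccession' labelling rule: '%s'",
      delim, headers[bad][1L]), call. = FALSE)
  list(species = vapply(parts, `[[`, "", 1L),
       accession = vapply(parts, function(p) paste(p[-1L], collapse = delim),
                          ""))
}

#' Read a barcode dataset from FASTA
#'
#' Headers must encode species and accession identity, by default as
#' \code{"Genus_species|accession"}. Sequences are upper-cased and U is
#' mapped to T; gapped input is accepted and flags the dataset as aligned
#' when all gapped lengths are equal.
#'
#' @param path path to a (multi-)FASTA file, gapped or ungapped.
#' @param delim delimiter separating species from accession in the header.
#' @return A [BarcodeDataset-class].
#' @seealso [writeBarcodeFasta()], [datasetSummary()]
#' @export
readBarcodeFasta <- function(path, delim = "|") {
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e)
      stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
  if (length(seqs) == 0L)
    stop(sprintf("malformed FASTA '%s': no sequence records", path),
         call. = FALSE)
  labs <- .parseHeaders(sub("\\s.*$", "", names(seqs)), delim)
  BarcodeDataset(as.character(seqs), labs$species, labs$accession,
                 aligned = NA)
}

#' Write a barcode dataset to FASTA
#'
#' Headers are written as \code{species<delim>accession} so the file
#' round-trips through [readBarcodeFasta()].
#'
#' @param ds a [BarcodeDataset-class].
#' @param path output path.
#' @param delim header delimiter.
#' @return \code{path}, invisibly.
#' @export
writeBarcodeFasta <- function(ds, path, delim = "|") {
  out <- ds@seqs
  names(out) <- paste(ds@species, ds@accession, sep = delim)
  Biostrings::writeXStringSet(out, path, format = "fasta")
  invisible(path)
}

#' Trim an alignment to the window covered by every record
#'
#' Removes leading and trailing alignment columns until both boundary
#' columns are gap-free in all records, producing a dataset of equal aligned
#' length whose ends are covered by every accession. With
#' \code{coverage < 1} a boundary column only needs a non-gap character in
#' that fraction of records.
#'
#' @param ds an aligned [BarcodeDataset-class].
#' @param coverage minimum fraction of records that must be gap-free at the
#'   boundary columns (default 1: all records).
#' @return the trimmed [BarcodeDataset-class].
#' @export
trimCommonWindow <- function(ds, coverage = 1) {
  if (!isAligned(ds))
    stop("trimCommonWindow() requires an aligned dataset", call. = FALSE)
  covered <- 1 - colMeans(.charMatrix(ds) == .GAP) >= coverage - 1e-12
  if (!any(covered))
    stop("no alignment column is covered by the required fraction of records",
         call. = FALSE)
  first <- which(covered)[1L]
  last <- which(covered)[sum(covered)]
  BarcodeDataset(XVector::subseq(ds@seqs, start = first, end = last),
                 ds@species, ds@accession, aligned = TRUE)
}

#' Remove all gap characters from a dataset
#'
#' Produces the unaligned view used for oligonucleotide frequency
#' computation; the mean ungapped length is recomputed.
#'
#' @param ds a [BarcodeDataset-class].
#' @return an unaligned, gap-free [BarcodeDataset-class].
#' @export
degap <- function(ds) {
  chr <- gsub(.GAP, "", as.character(ds@seqs), fixed = TRUE)
  empty <- !nzchar(chr)
  if (any(empty))
    stop(sprintf("record '%s|%s' is empty after removing gaps",
                 ds@species[empty][1L], ds@accession[empty][1L]),
         call. = FALSE)
  BarcodeDataset(chr, ds@species, ds@accession, aligned = FALSE)
}

#' Per-species dataset summary
#'
#' @param ds a [BarcodeDataset-class].
#' @return data.frame with one row per species: number of accessions and
#'   mean/min/max ungapped length.
#' @export
datasetSummary <- function(ds) {
  len <- ungappedLengths(ds)
  sp <- factor(ds@species, levels = speciesIds(ds))
  data.frame(
    species_id = levels(sp),
    n_accessions = as.integer(table(sp)),
    mean_length = as.numeric(tapply(len, sp, mean)),
    min_length = as.integer(tapply(len, sp, min)),
    max_length = as.integer(tapply(len, sp, max)),
    row.names = NULL
  )
}

# character matrix view (records x alignment columns); aligned datasets only
.charMatrix <- function(ds) {
  stopifnot(isAligned(ds))
  m <- matrix(unlist(strsplit(as.character(ds@seqs), "", fixed = TRUE),
                     use.names = FALSE),
              nrow = length(ds@seqs), byrow = TRUE)
  rownames(m) <- paste(ds@species, ds@accession, sep = "|")
  m
}
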
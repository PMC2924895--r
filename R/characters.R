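#' Simple diagnostic characters for a species pair
#'
#' Scans every alignment column of two species. A state is a simple pure
#' character for the focal species when it is fixed in all focal accessions
#' and absent from every comparison accession; it is a simple private
#' character when it occurs in at least one (but not all) focal accessions
#' and is absent from the comparison species. Columns where any involved
#' accession carries a gap or ambiguity code are skipped; gaps never serve
#' as diagnostic states.
#'
#' @param ds an aligned [BarcodeDataset-class].
#' @param speciesA,speciesB species labels present in \code{ds}.
#' @return data.frame with columns \code{column} (1-based alignment
#'   position), \code{state}, \code{focal_species}, \code{kind}
#'   ("pure"/"private"); zero rows when the pair has no diagnostic
#'   character.
#' @examples
#' ds <- BarcodeDataset(c("ACGT", "ACGT", "ATGT", "ATGT"),
#'                      species = c("A", "A", "B", "B"),
#'                      accession = c("1", "2", "1", "2"))
#' diagnosticCharacters(ds, "A", "B")  # column 2: C pure for A, T pure for B
#' @export
diagnosticCharacters <- function(ds, speciesA, speciesB) {
  if (!isAligned(ds))
    stop("diagnostic characters require an aligned dataset", call. = FALSE)
  for (s in c(speciesA, speciesB))
    if (!s %in% ds@species)
      stop(sprintf("unknown species '%s'", s), call. = FALSE)
  chars <- .charMatrix(ds)
  ia <- ds@species == speciesA
  ib <- ds@species == speciesB
  out <- list()
  for (col in seq_len(ncol(chars))) {
    sa <- chars[ia, col]
    sb <- chars[ib, col]
    if (!all(c(sa, sb) %in% .ACGT)) next
    for (side in list(list(f = speciesA, fs = sa, cs = sb),
                      list(f = speciesB, fs = sb, cs = sa))) {
      states <- setdiff(unique(side$fs), side$cs)
      for (st in states) {
        kind <- if (all(side$fs == st)) "pure" else "private"
        out[[length(out) + 1L]] <- data.frame(
          column = col, state = st, focal_species = side$f, kind = kind,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(column = integer(), state = character(),
                      focal_species = character(), kind = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Character-based species resolution
#'
#' A species pair is resolved when at least one simple pure character exists
#' for either species (default), or at least one pure-or-private character
#' with \code{require = "pure_or_private"}.
#'
#' @param ds an aligned [BarcodeDataset-class] with >= 2 species.
#' @param require \code{"pure"} (default, conservative) or
#'   \code{"pure_or_private"}.
#' @return a [ResolutionMatrix-class]; pair evidence holds the diagnoses.
#' @export
characterResolution <- function(ds, require = c("pure", "pure_or_private")) {
  require <- match.arg(require)
  if (nSpecies(ds) < 2L)
    stop("at least 2 species are required", call. = FALSE)
  ids <- speciesIds(ds)
  n <- length(ids)
  cells <- matrix(0, n, n, dimnames = list(ids, ids))
  evidence <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      diag <- diagnosticCharacters(ds, ids[i], ids[j])
      hits <- if (require == "pure") diag[diag$kind == "pure", ] else diag
      cells[i, j] <- cells[j, i] <- as.numeric(nrow(hits) > 0L)
      evidence[[.pairKey(ids[i], ids[j])]] <- list(
        species_a = ids[i], species_b = ids[j],
        resolved = nrow(hits) > 0L, diagnoses = diag, evaluable = TRUE)
    }
  }
  new("ResolutionMatrix", speciesIds = ids, cells = cells,
      evidence = evidence, method = paste0("characters_", require),
      threshold = NA_real_)
}
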
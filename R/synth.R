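.mutateSites <- function(seq, rate, mask) {
  hit <- which(stats::runif(length(seq)) < rate)
  hit <- intersect(hit, mask)
  if (length(hit)) {
    alt <- vapply(seq[hit],
                  function(b) sample(setdiff(.ACGT, b), 1L), "")
    seq[hit] <- alt
  }
  list(seq = seq, positions = hit)
}

.applyIndels <- function(seq, rate, lenMean) {
  events <- list()
  starts <- which(stats::runif(length(seq)) < rate)
  if (!length(starts)) return(list(seq = seq, events = events))
  # apply right-to-left so earlier positions stay valid
  for (pos in rev(starts)) {
    len <- 1L + stats::rgeom(1L, prob = 1 / max(1, lenMean))
    if (stats::runif(1L) < 0.5) {
      stop_ <- min(length(seq), pos + len - 1L)
      if (stop_ - pos + 1L >= length(seq)) next  # never delete everything
      seq <- seq[-(pos:stop_)]
      events[[length(events) + 1L]] <- list(type = "deletion", pos = pos,
                                            length = stop_ - pos + 1L)
    } else {
      ins <- sample(.ACGT, len, replace = TRUE)
      seq <- append(seq, ins, after = pos)
      events[[length(events) + 1L]] <- list(type = "insertion", pos = pos,
                                            length = len)
    }
  }
  list(seq = seq, events = events)
}

#' Simulate a multi-species barcode dataset
#'
#' Draws a uniform-random ancestral locus, derives one ancestor per species
#' by independent per-site substitution (Jukes-Cantor-like: a substituted
#' site moves uniformly to one of the three alternative bases), and each
#' accession from its species ancestor at \code{intraDiv}. \code{interDiv}
#' is the expected total per-site substitution proportion separating an
#' accession from the root, so the species-ancestor branch carries the
#' excess over \code{intraDiv}: its rate is
#' \code{(interDiv - intraDiv) / (1 - 4 intraDiv / 3)}. Consequently
#' \code{interDiv == intraDiv} yields no species-level structure at all (a
#' null dataset whose labels carry no signal), and the species signal grows
#' with \code{interDiv - intraDiv}.
#' Substitutions can be confined to a \code{hotspot} region to
#' emulate loci whose variable sites cluster at one end; optional indels
#' (geometric lengths around \code{indelLenMean}) produce the
#' unequal-length datasets used by the indel-risk analysis. Deterministic
#' under a fixed \code{seed}.
#'
#' @param nSpecies number of species (>= 1).
#' @param accessionsPerSpecies accessions per species (>= 1).
#' @param locusLength ancestral locus length, nt (>= 50).
#' @param interDiv expected total per-site substitution proportion between
#'   the root and an accession (interspecific divergence level); either a
#'   single value or one value per species (a graded-divergence design).
#' @param intraDiv expected per-site substitution proportion on each
#'   species-ancestor-to-accession branch; \code{0 <= intraDiv <= interDiv
#'   <= 0.75} is enforced.
#' @param indelRate per-site probability that an indel event starts at a
#'   site of an accession (default 0: equal-length, gap-free output).
#' @param indelLenMean mean indel length, nt.
#' @param hotspot optional integer vector \code{c(start, end)} restricting
#'   substitutions to that 1-based region of the ancestral locus.
#' @param seed integer seed; when non-NULL the generator is deterministic.
#' @return list with \code{dataset} (a [BarcodeDataset-class], species
#'   labelled \code{Species01..}, accessions \code{A1..}) and \code{truth}
#'   (root sequence, species ancestors, per-accession substitution positions
#'   and indel events).
#' @examples
#' sim <- simulateBarcodeDataset(nSpecies = 3, accessionsPerSpecies = 2,
#'                               locusLength = 120, seed = 1)
#' sim$dataset
#' @export
simulateBarcodeDataset <- function(nSpecies = 10L, accessionsPerSpecies = 5L,
                                   locusLength = 600L, interDiv = 0.05,
                                   intraDiv = 0.005, indelRate = 0,
                                   indelLenMean = 3L, hotspot = NULL,
                                   seed = NULL) {
  if (nSpecies < 1L || accessionsPerSpecies < 1L)
    stop("species and accession counts must be >= 1", call. = FALSE)
  if (locusLength < 50L)
    stop("locusLength must be >= 50 nt", call. = FALSE)
  if (!length(interDiv) %in% c(1L, nSpecies))
    stop("interDiv must have length 1 or nSpecies", call. = FALSE)
  if (intraDiv < 0 || any(interDiv > 0.75) || intraDiv > min(interDiv))
    stop("divergences must satisfy 0 <= intraDiv <= interDiv <= 0.75",
         call. = FALSE)
  interDiv <- rep_len(interDiv, nSpecies)
  # species-ancestor branch rate such that root-to-accession substitution
  # probability compounds to interDiv (second branch can revert a site)
  branchRate <- (interDiv - intraDiv) / (1 - 4 * intraDiv / 3)
  if (indelRate < 0 || indelRate > 1)
    stop("indelRate must lie in [0, 1]", call. = FALSE)
  if (!is.null(hotspot) &&
      (length(hotspot) != 2L || hotspot[1L] < 1L ||
       hotspot[2L] > locusLength || hotspot[1L] > hotspot[2L]))
    stop("hotspot must be c(start, end) within the locus", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  mask <- if (is.null(hotspot)) seq_len(locusLength)
          else seq(hotspot[1L], hotspot[2L])
  root <- sample(.ACGT, locusLength, replace = TRUE)
  speciesIdsV <- sprintf("Species%02d", seq_len(nSpecies))
  ancestors <- list()
  seqs <- character(0)
  species <- character(0)
  accession <- character(0)
  truthAcc <- list()
  for (i in seq_len(nSpecies)) {
    anc <- .mutateSites(root, branchRate[i], mask)
    ancestors[[speciesIdsV[i]]] <- paste(anc$seq, collapse = "")
    for (j in seq_len(accessionsPerSpecies)) {
      acc <- .mutateSites(anc$seq, intraDiv, mask)
      rec <- list(substitutions = acc$positions, indels = list())
      s <- acc$seq
      if (indelRate > 0) {
        ind <- .applyIndels(s, indelRate, indelLenMean)
        s <- ind$seq
        rec$indels <- ind$events
      }
      seqs <- c(seqs, paste(s, collapse = ""))
      species <- c(species, speciesIdsV[i])
      accession <- c(accession, sprintf("A%d", j))
      truthAcc[[paste(speciesIdsV[i], j, sep = "|")]] <- rec
    }
  }
  list(
    dataset = BarcodeDataset(seqs, species, accession, aligned = NA),
    truth = list(root = paste(root, collapse = ""),
                 species_ancestors = ancestors,
                 accessions = truthAcc,
                 hotspot = hotspot, inter_div = interDiv,
                 branch_rate = branchRate,
                 intra_div = intraDiv, indel_rate = indelRate,
                 seed = seed)
  )
}
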
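test_that("threshold follows t = 1/(a - k + 1) and decreases with length", {
  expect_equal(tValue(ofrThreshold(651, 2)), 1 / 650)
  expect_equal(tValue(ofrThreshold(651, 3)), 1 / 649)
  grid <- seq(100, 1700, by = 37)
  t2 <- vapply(grid, function(a) tValue(ofrThreshold(a, 2)), 1)
  expect_true(all(diff(t2) < 0))
  expect_error(ofrThreshold(1.5, 3), "too short")
})

test_that("species OFR is the min/max over accession profiles", {
  ds <- BarcodeDataset(c("AAAA", "AAAT"), c("S", "S"), c("1", "2"))
  p <- speciesOFR(ds, "S", 2)
  r <- ofrRanges(p)
  expect_equal(r$lo[r$oligo == "AA"], 2 / 3)
  expect_equal(r$hi[r$oligo == "AA"], 1)
  expect_equal(r$lo[r$oligo == "AT"], 0)
  expect_equal(r$hi[r$oligo == "AT"], 1 / 3)

  single <- BarcodeDataset("ACGTT", "S", "1")
  ps <- speciesOFR(single, "S", 2)
  expect_equal(ps@lo, ps@hi)

  expect_error(speciesOFR(ds, "nope", 2), "unknown species")
})

test_that("species OFR matches per-accession oracle on seeded data", {
  sim <- simulateBarcodeDataset(nSpecies = 1, accessionsPerSpecies = 10,
                                locusLength = 300, interDiv = 0.05,
                                intraDiv = 0.05, seed = 99)
  p <- speciesOFR(sim$dataset, "Species01", 3)
  profiles <- t(vapply(as.character(sequences(sim$dataset)),
                       function(s) as.numeric(kmerFrequencies(s, 3)),
                       numeric(64)))
  expect_equal(unname(p@lo), unname(apply(profiles, 2, min)))
  expect_equal(unname(p@hi), unname(apply(profiles, 2, max)))
})

test_that("pair resolution applies the inclusive threshold rule", {
  mk <- function(lo, hi, id) {
    oligos <- allKmers(2)
    l <- stats::setNames(rep(0.5, 16), oligos)
    h <- l
    l["AA"] <- lo; h["AA"] <- hi
    new("OFRProfile", speciesId = id, k = 2L, lo = l, hi = h,
        nAccessions = 3L)
  }
  ts <- ofrThreshold(101, 2)  # t = 0.01
  pa <- mk(0.10, 0.12, "A")
  pb <- mk(0.20, 0.25, "B")
  pr <- resolvePair(pa, pb, ts)
  expect_true(pr$resolved)
  expect_equal(pr$max_gap, 0.08)
  expect_equal(pr$discriminating$oligo, "AA")

  # symmetric including the discriminating set
  pr2 <- resolvePair(pb, pa, ts)
  expect_equal(pr2$resolved, pr$resolved)
  expect_equal(pr2$discriminating, pr$discriminating)
  expect_equal(pr2$max_gap, pr$max_gap)

  # identical profiles are never resolved
  expect_false(resolvePair(pa, mk(0.10, 0.12, "B"), ts)$resolved)

  # 'separated by at least t' is inclusive: flip exactly at gap = t
  t <- tValue(ts)
  atT <- resolvePair(mk(0.1, 0.2, "A"), mk(0.2 + t, 0.4, "B"), ts)
  expect_true(atT$resolved)
  below <- resolvePair(mk(0.1, 0.2, "A"), mk(0.2 + t - 1e-6, 0.4, "B"), ts)
  expect_false(below$resolved)

  # insufficient accessions: not-evaluable, distinct from unresolved
  pc <- mk(0.2, 0.2, "C"); pc@nAccessions <- 1L
  ne <- resolvePair(pa, pc, ts)
  expect_false(ne$evaluable)
  expect_true(is.na(ne$resolved))
})

test_that("binomial matrix is symmetric with engineered resolved pairs", {
  same <- BarcodeDataset(rep("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC", 4),
                         rep(c("A", "B"), each = 2),
                         rep(c("1", "2"), 2))
  rmSame <- resolutionMatrix(same, 2)
  expect_true(all(resolutionCells(rmSame)[upper.tri(diag(2))] == 0))
  expect_equal(percentResolution(rmSame, "pairs"), 0)

  base <- strrep("ACGT", 25)
  far <- strrep("GGTT", 25)
  ds3 <- BarcodeDataset(c(base, base, base, base, far, far),
                        rep(c("A", "B", "C"), each = 2),
                        rep(c("1", "2"), 3))
  rm3 <- resolutionMatrix(ds3, 2)
  cells <- resolutionCells(rm3)
  expect_identical(cells, t(cells))
  expect_equal(cells["A", "C"], 1)
  expect_equal(cells["B", "C"], 1)
  expect_equal(cells["A", "B"], 0)

  sim <- simulateBarcodeDataset(nSpecies = 6, accessionsPerSpecies = 3,
                                locusLength = 400, seed = 3)
  m <- resolutionCells(resolutionMatrix(sim$dataset, 3))
  expect_identical(m, t(m))
})

test_that("percent resolution handles species and pairs modes", {
  mk <- function(cells) new("ResolutionMatrix",
                            speciesIds = rownames(cells), cells = cells,
                            evidence = list(), method = "ofr_k2",
                            threshold = 0.01)
  ids <- c("A", "B", "C")
  ones <- matrix(1, 3, 3, dimnames = list(ids, ids)); diag(ones) <- 0
  allOnes <- mk(ones)
  expect_equal(percentResolution(allOnes, "species"), 100)
  expect_equal(percentResolution(allOnes, "pairs"), 100)

  zeros <- matrix(0, 3, 3, dimnames = list(ids, ids))
  expect_equal(percentResolution(mk(zeros), "species"), 0)
  expect_equal(percentResolution(mk(zeros), "pairs"), 0)

  one <- zeros; one["A", "B"] <- one["B", "A"] <- 1
  expect_equal(percentResolution(mk(one), "pairs"), 100 / 3)
  expect_equal(percentResolution(mk(one), "species"), 0)

  nas <- matrix(NA_real_, 2, 2, dimnames = list(ids[1:2], ids[1:2]))
  expect_error(percentResolution(mk(nas)), "undefined")
})

test_that("adding accessions only widens ranges (anti-monotone sampling)", {
  set.seed(31)
  for (rep in 1:5) {
    sim <- simulateBarcodeDataset(nSpecies = 4, accessionsPerSpecies = 8,
                                  locusLength = 250, interDiv = 0.08,
                                  intraDiv = 0.03,
                                  seed = sample.int(1e6, 1))
    ds <- sim$dataset
    prevResolved <- NULL
    prevLo <- prevHi <- NULL
    for (nAcc in c(2, 4, 8)) {
      keep <- unlist(lapply(speciesIds(ds), function(s)
        which(speciesOf(ds) == s)[seq_len(nAcc)]))
      sub <- ds[keep]
      p <- speciesOFR(sub, "Species01", 2)
      if (!is.null(prevLo)) {
        expect_true(all(p@lo <= prevLo + 1e-15))
        expect_true(all(p@hi >= prevHi - 1e-15))
      }
      prevLo <- p@lo; prevHi <- p@hi
      rm <- resolutionMatrix(sub, 2,
                             averageLength = averageLength(ds))
      res <- resolutionCells(rm)[upper.tri(diag(4))]
      if (!is.null(prevResolved))
        expect_true(all(res <= prevResolved))
      prevResolved <- res
    }
  }
})

test_that("doubling construction length halves t, preserving fixed gaps", {
  t1 <- tValue(ofrThreshold(300, 2))
  t2 <- tValue(ofrThreshold(600, 2))
  expect_equal(t2, 1 / (2 * 300 - 1))
  expect_lt(t2, t1 / 1.9)
})
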
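test_that("FASTA reading populates species structure and average length", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A_x|1", "ACGT", ">A_x|2", "ACGA"), f)
  ds <- readBarcodeFasta(f)
  expect_equal(nSpecies(ds), 1L)
  expect_equal(unname(accessionCounts(ds)), 2L)
  expect_equal(averageLength(ds), 4)
  expect_true(isAligned(ds))  # equal widths form a trivial alignment
})

test_that("malformed input is rejected with informative errors", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readBarcodeFasta(empty), "FASTA")
  expect_error(readBarcodeFasta(file.path(tempdir(), "nope.fasta")),
               "not found")
  badhdr <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">just_a_name", "ACGT"), badhdr)
  expect_error(readBarcodeFasta(badhdr), "labelling rule")
  expect_error(
    BarcodeDataset(c("ACGT", "ACGT"), c("A", "A"), c("1", "1")),
    "duplicate")
})

test_that("read/write round-trips a simulated dataset", {
  sim <- simulateBarcodeDataset(nSpecies = 3, accessionsPerSpecies = 2,
                                locusLength = 80, seed = 11)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeBarcodeFasta(sim$dataset, f)
  back <- readBarcodeFasta(f)
  expect_equal(as.character(sequences(back)),
               as.character(sequences(sim$dataset)), ignore_attr = TRUE)
  expect_equal(speciesOf(back), speciesOf(sim$dataset))
  expect_equal(accessionOf(back), accessionOf(sim$dataset))
})

test_that("ingest upper-cases and maps U to T", {
  ds <- BarcodeDataset(c("acgu", "ACGT"), c("A", "A"), c("1", "2"))
  expect_equal(as.character(sequences(ds)), c("ACGT", "ACGT"),
               ignore_attr = TRUE)
})

test_that("trimCommonWindow keeps the window covered by every record", {
  ds <- BarcodeDataset(c("-ACGT-", "TACGTA"), c("A", "B"), c("1", "1"))
  tr <- trimCommonWindow(ds)
  expect_equal(as.character(sequences(tr)), c("ACGT", "ACGT"),
               ignore_attr = TRUE)

  ds2 <- BarcodeDataset(c("ACGT", "AGGT"), c("A", "B"), c("1", "1"))
  expect_equal(as.character(sequences(trimCommonWindow(ds2))),
               as.character(sequences(ds2)), ignore_attr = TRUE)

  expect_error(
    trimCommonWindow(BarcodeDataset(c("A---", "---T"),
                                    c("A", "B"), c("1", "1"))),
    "no alignment column")
})

test_that("trimmed boundary columns are gap-free in all records (seeded)", {
  set.seed(7)
  for (rep in 1:10) {
    seqs <- vapply(1:6, function(i)
      randSeq(40, c(ACGT, "-", "-")), "")
    seqs <- vapply(seqs, function(s) {  # keep at least one non-gap char
      if (!grepl("[ACGT]", s)) sub("-", "A", s) else s
    }, "")
    ds <- BarcodeDataset(seqs, paste0("S", 1:6), rep("1", 6))
    tr <- tryCatch(trimCommonWindow(ds), error = function(e) NULL)
    if (is.null(tr)) next
    m <- matrix(unlist(strsplit(as.character(sequences(tr)), "")),
                nrow = 6, byrow = TRUE)
    expect_false(any(m[, 1] == "-"))
    expect_false(any(m[, ncol(m)] == "-"))
    expect_true(all(nchar(as.character(sequences(tr))) <=
                    nchar(as.character(sequences(ds)))))
  }
})

test_that("degap removes gaps and preserves non-gap characters", {
  ds <- BarcodeDataset(c("A-C-G", "ACGT-"), c("A", "B"), c("1", "1"),
                       aligned = TRUE)
  dg <- degap(ds)
  expect_equal(as.character(sequences(dg)), c("ACG", "ACGT"),
               ignore_attr = TRUE)
  expect_false(isAligned(dg))
  expect_equal(averageLength(dg), 3.5)

  gapless <- BarcodeDataset(c("ACGT", "ACGA"), c("A", "A"), c("1", "2"))
  expect_equal(as.character(sequences(degap(gapless))),
               as.character(sequences(gapless)), ignore_attr = TRUE)

  expect_error(degap(BarcodeDataset(c("----", "ACGT"), c("A", "B"),
                                    c("1", "1"))),
               "empty after removing gaps")
})

test_that("trim + degap record lengths equal non-gap counts in the window", {
  set.seed(13)
  seqs <- replicate(5, randSeq(60, c(ACGT, "-")))
  ds <- BarcodeDataset(seqs, paste0("S", 1:5), rep("1", 5))
  tr <- trimCommonWindow(ds)
  dg <- degap(tr)
  manual <- vapply(as.character(sequences(tr)),
                   function(s) sum(strsplit(s, "")[[1]] != "-"), 1L)
  expect_equal(unname(nchar(as.character(sequences(dg)))), unname(manual))
})

test_that("datasetSummary reports per-species accession counts and lengths", {
  ds <- twoSpeciesDataset(c("ACGTAC", "ACGTAA"), c("ACGT"))
  s <- datasetSummary(ds)
  expect_equal(s$n_accessions, c(2L, 1L))
  expect_equal(s$mean_length, c(6, 4))
})
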
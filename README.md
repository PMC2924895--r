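# ofrbarcode

Species discrimination from DNA barcodes by **oligonucleotide frequency
ranges (OFR)** — an alignment-free criterion for deciding whether a barcode
locus (*COI*, *matK*, *rbcL*, ITS, or any locus) separates the species in a
reference dataset — together with the standard comparator criteria
(uncorrected p-distance and Euclidean composition-distance barcoding-gap
tests, simple pure/private diagnostic characters), an indel-driven
Type I/II error analysis, a mini-barcode trimming scan, and a seeded
synthetic-dataset generator.

## The method

For a gap-free sequence of length *n*, each k-mer frequency is its
sliding-window count over *n − k + 1* window positions (denominator *n − 1*
for dinucleotides, *n − 2* for trinucleotides). For every species, each
k-mer's frequency range [Min, Max] is taken across that species'
accessions. A species pair is **resolved** when at least one k-mer's ranges
do not overlap and are separated by at least the threshold

```
t = 1 / (a − k + 1)        # a = mean ungapped sequence length
```

— one window's worth of frequency at average length. Pair decisions fill a
symmetric 0/1 ("binomial") matrix; percent resolution is reported per
species (resolved against all others) or per pair. Species with a single
accession have zero-width ranges and are marked *not evaluable* rather than
resolved or unresolved.

The package is Bioconductor-style S4 on top of `Biostrings`: a
`BarcodeDataset` wraps a `DNAStringSet` with species/accession labels;
`OFRProfile`, `ResolutionMatrix`, `ThresholdSpec` and `LengthScanResult`
carry the analysis objects, each with accessors and `show()` methods.

## Worked example

```r
library(ofrbarcode)

sim <- simulateBarcodeDataset(nSpecies = 5, accessionsPerSpecies = 4,
                              locusLength = 600, interDiv = 0.05,
                              intraDiv = 0.005, seed = 42)
ds <- sim$dataset
ds
#> BarcodeDataset: 20 records, 5 species, aligned (width 600), mean ungapped length 600.0 nt

rm2 <- resolutionMatrix(ds, k = 2)
rm2
#> ResolutionMatrix (ofr_k2): 5 species, 10/10 evaluable pairs resolved, t = 0.00166945

head(pairEvidence(rm2, "Species01", "Species02")$discriminating, 3)
#>   oligo         gap
#> 1    AA 0.008347245
#> 2    AC 0.003338898
#> 3    AG 0.003338898

percentResolution(rm2)           # species mode
#> [1] 100

round(compareMethods(ds)$percent, 1)
#> p_distance  euclid_di euclid_tri characters     ofr_di    ofr_tri
#>        100         80        100        100        100        100
```

Reading this: the dinucleotide threshold is `t = 1/(600−1) = 0.00167`; the
pair Species01/Species02 is separated by the `AA` range gap of 0.0083 (five
windows' worth), so the pair is resolved. Every species is resolved against
every other by OFR, p-distance and characters; the dinucleotide Euclidean
barcoding-gap criterion misses one species (80%) — composition distances
compress 600 sites into 16 dimensions and are the weakest criterion here,
which is why the trinucleotide variant is also always reported.

Other entry points: `trimScan()` / `minLengthFullResolution()` (mini-barcode
search), `datasetIndelAudit()` / `minIndelForError()` (indel risk),
`pairwiseDeltas()` / `pearsonCorrelation()` (cross-method correlation),
`readBarcodeFasta()` / `writeBarcodeFasta()` (headers
`Genus_species|accession`). A command-line wrapper covering every stage is
installed at `inst/cli/ofr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ofr.R", package="ofrbarcode"))')" \
    simulate --out demo --n-species 6 --seed 1
```

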
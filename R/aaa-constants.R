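## Package-wide constants (file sorts first so every module sees them).

STOP_CODONS <- c("TAA", "TAG", "TGA")

## start-codon type weights: ATG 16, GTG 4, TTG 1
START_TYPE_SCORES <- c(ATG = 16, GTG = 4, TTG = 1)

## feature kinds and the flat-file keys they are written as
FEATURE_KINDS <- c(tile = "misc_feature", cds = "CDS", rna = "misc_RNA")

## symmetric 9-position triangle over RBS-to-start gaps of 3..11 bases,
## peak (weight 5) at gap 7, normalised to sum 1
TRIANGLE_GAPS <- 3:11
TRIANGLE_W <- c(1:5, 4:1) / 25

## all 61 non-stop codons (gene bodies in the synthetic generator)
NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  STOP_CODONS)
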
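Package: ancestryscan
Title: Sliding-Window Topology Weighting to Detect Shared Ancestry at
    Mimicry Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects narrow genomic intervals of shared ancestry between
    non-sister taxa (introgression or ancestral polymorphism) from a
    multi-sample SNP genotype matrix. Implements genotype-level quality
    masking and site filters, 100-SNP sliding-window tree building by
    neighbor joining (or ingest of externally built newick trees),
    six-group topology weighting with exact enumeration or iterative
    subtree sampling under a Wilson-interval stopping rule, genome tracks
    of summed shared-ancestry topology weights with overlapping-window
    smoothing and peak calling, a diagnostic fixed-SNP scan between
    phenotype-defined taxon groups, and cross-comparison delimitation of
    candidate cis-regulatory elements. Includes a block-wise introgression
    simulator with implanted tracts and truth-set recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    vcfR,
    IRanges,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
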
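Package: famvar
Title: Familial Variant Discovery by Haplotype Sharing and Case/Control Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering candidate disease variants in multiplex
    pedigrees. Implements Mendelian-inheritance haplotype phasing and
    enumeration of genomic segments shared among subsets of affected
    relatives; pedigree and marker quality control (call-rate filtering,
    nuclear-family Mendelian-error detection); capture-region construction,
    variant normalization, multi-caller consensus filtering and functional
    classification of coding variants; case/control allelic association with
    principal-component ancestry outlier detection, relatedness pruning,
    linkage-disequilibrium pruning and exact Hardy-Weinberg testing; variant
    prioritization and pedigree segregation reporting; and seeded generators
    of synthetic pedigrees and cohorts with planted risk haplotypes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
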
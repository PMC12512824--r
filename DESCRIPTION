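Package: svtopo
Title: Reconstruction and Visualization of Complex Structural Variants from Phased Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the sample-haplotype structure of complex germline
    structural variants from phased long-read alignments (BAM with SA, HP and
    PS tags) together with an SV VCF (breakend and symbolic alleles). Genomic
    break locations are extracted from SV calls, connected into breakpoint
    networks using split-read and phase-block evidence, ordered into oriented
    genomic blocks by traversal from a reference-consistent start break, and
    filtered for abnormal coverage, low mapping quality and simple (non-complex)
    events. Each resolved rearrangement is rendered as a block diagram with a
    reference-ordered axis, sample-ordered rows, support-scaled block thickness
    and a chain-plot track, and all images are indexed in a self-contained HTML
    table viewer with click-to-filter controls. A seeded simulator generates
    synthetic references, phased split-read alignments and truth VCFs for any
    scripted rearrangement so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
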
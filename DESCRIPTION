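Package: clonesv
Title: Clone-Based Discovery and Resolution of Mosaic Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery, local assembly, breakpoint resolution, genotyping and
    timing of somatic (mosaic) structural variants from clonally expanded cell
    populations sequenced at moderate coverage. Implements clone-to-clone
    somatic filtering, greedy overlap assembly of abnormal reads, segment-chain
    reconstruction of complex rearrangements under a replication
    (template-switch) model, junction microhomology measurement,
    pseudoreference genotyping with allele-fraction bounds, a read-depth CNV
    post-filter, extrachromosomal circular DNA detection, MDA chimera-artifact
    flagging, lineage timing from clone-unique SNV counts, and droplet digital
    PCR allele-frequency statistics. A paired-end clone-sequencing simulator
    with exact truth records makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
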
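Package: strandfit
Title: Overlap Fitness Metrics and Trajectory Statistics for ssDNA Ecosystems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats single-stranded DNA oligomers as individuals of a
    molecular ecosystem and scores their competitive affinity with a purely
    combinatorial fitness metric: the maximum consecutive complementary
    overlap (omega) over all antiparallel relative positions between two
    strands, alongside the total mixed overlap. Provides full overlap
    profiles with degenerate-window enumeration, constrained sequence
    design against a resource strand, readers and writers for the
    coarse-grained oxDNA text formats (topology, configuration,
    hydrogen-bond pair lists), per-frame trajectory statistics (MCO/TMO
    distributions, binding-event lifetimes, multi-strand complex and
    self-folding detection), and a seeded synthetic trajectory generator
    with known ground truth so the whole analysis pipeline can be validated
    without a molecular dynamics engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
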
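Package: numtdyn
Title: Detection, Dating and Turnover Dynamics of Nuclear Mitochondrial Pseudogenes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to annotate nuclear copies of mitochondrial DNA (numts) in
    genome assemblies and to study their evolutionary dynamics. Provides
    entropy-based low-complexity masking, seed-and-extend nucleotide similarity
    search with Karlin-Altschul E-values and HSP linking, merging of linked
    hits into numt annotations with classification of gross rearrangements
    (interruptions, deletions, inversions, internal duplications), maximum
    likelihood dating of insertions by exhaustive branch placement on a
    calibrated species tree under the F84 substitution model, paralog and
    ortholog identification by constrained tree tests with micro-synteny
    confirmation, and estimation of insertion, duplication and steady-state
    deletion rates. A coalescing simulator of mitochondrial and nuclear genome
    evolution with numt insertions at known times provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, SequenceMatching, Alignment, Software
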
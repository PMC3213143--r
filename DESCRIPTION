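Package: erisift
Title: Simulation and Analysis of ERI-Class Endogenous Small RNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing endogenous small interfering RNA (siRNA)
    sequencing libraries from Caenorhabditis elegans ERI-pathway mutants.
    Implements exact-match placement of collapsed small-RNA reads on both
    genome strands with fractional multi-mapper weighting and
    reads-per-million normalisation; length by 5'-nucleotide profiling and
    annotation-driven classification of 26G, 22G, miRNA, and piRNA (21U)
    classes; mutant versus wild-type depletion calling at the feature and
    individual-siRNA level with sliding-window genome tracks; inference of
    the ~19-nt passenger strand and inset geometry of 26G siRNA duplexes and
    of the 23-29 nt phasing register of 26G siRNA 5' ends; and clustering of
    target genes by nucleotide identity and perfect-match stretches to detect
    recent gene duplications. Includes a synthetic-data generator that
    emulates the library structure of such studies, with ground-truth tables
    for end-to-end recovery testing, and a single-command pipeline producing
    a reproducible JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
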
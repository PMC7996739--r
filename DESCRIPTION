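Package: mirhom
Title: Homology-Based Detection and Structural Validation of MicroRNA Precursors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annotation workflow for canonical animal microRNA precursors.
    Candidate loci are acquired from the tabular outputs of up to three
    homology search engines (blastn, nhmmer, cmsearch), filtered on E-value,
    coverage, HSP length and bitscore rules (including the log2(2N) genome-size
    cutoff and the 0.32*gathering-cutoff rescue), aggregated into extended
    regions with strand disambiguation, and validated structurally: mature
    miR/miR* placement on the precursor hairpin, minimum-free-energy and
    precursor-length filters, arm-consistency checks against the predicted
    secondary structure, and a Zhang-Shasha tree edit distance between the
    family consensus structure with and without the new candidate that
    determines High/Medium confidence. Includes a benchmark comparator
    (Match/Miss/Additional classification against a reference annotation) and
    a fully self-contained synthetic-data generator (implanted hairpins,
    dinucleotide-shuffled decoys, point-mutation series) so the entire
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: ViennaRNA (RNAfold; optionally RNAalifold); optionally
    NCBI BLAST+ (blastn, makeblastdb) and HMMER (nhmmer) for live searches.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
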
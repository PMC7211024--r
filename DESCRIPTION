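Package: titrasm
Title: Depth Titration and Completeness Metrics for Long-Read Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how sequencing depth and read length shape
    long-read genome assemblies, modeled on the maize NC358 titration
    design. Implements seeded serial downsampling of read sets (each depth
    a superset of the next), read-length distribution shifting by
    sample-and-clip, assembly contiguity statistics (N50, NG(x), assembled
    and gap percentages), effective assembly size by unique k-mer
    counting, repeat-space evaluation (tandem monomer scanning, array
    clustering with repeat/gap accounting, telomere and subtelomere
    reports, flank-based locus location), and four-parameter logistic
    compute-cost scaling curves. A synthetic-genome generator with
    maize-like repeat structure (knob180, TR-1, CentC, rDNA-like and
    subtelomere arrays, LTR elements, telomere motif runs) provides ground
    truth for every metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
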
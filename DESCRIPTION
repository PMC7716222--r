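Package: mitohap
Title: Forensic Mitogenome Haplotyping, Heteroplasmy Detection, and
    Population Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based variant and point-heteroplasmy calling from
    aligned mitochondrial reads or per-position pileups, quantitative
    length-heteroplasmy assessment by spanning-read motif counting,
    replicate/mixture/duplicate quality control, and lineage-marker
    population statistics (random match probabilities, haplotype
    diversity, Kimura 2-parameter Phi-st with permutation tests, and
    principal coordinate analysis), together with a seeded synthetic
    mitogenome population and read simulator used throughout the test
    suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
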
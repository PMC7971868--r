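Package: dfewave
Title: Emergent Exponential Fitness-Effect Distributions in Adapting Asexual Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of multi-site binary genomes
    under additive directional selection, mutation, linkage and drift;
    closed-form traveling-wave theory for the frequency of less-fit alleles
    and for the fixation probability of beneficial mutations under clonal
    interference; and an inference pipeline that estimates relative per-site
    selection coefficients from multiple-sequence alignments sampled at two
    or more time points. The package explains and exploits the emergence of
    an exponential distribution of beneficial fitness effects during
    adaptation, regardless of the intrinsic per-site distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
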
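Package: halonitro
Title: Genome-Based Profiling of Denitrification in Haloarchaea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the four marker enzymes of the denitrification pathway
    (respiratory nitrate reductase NarG/NarH, nitrite reductase NirK/NirS,
    nitric oxide reductase qNor, nitrous oxide reductase NosZ) in proteomes by
    exact affine-gap global alignment against a reference panel with a percent
    identity acceptance rule and genetic-context verification of NarG; builds
    16S rRNA neighbour-joining trees with bootstrap supports; classifies
    species as non, partial or complete denitrifiers with a theoretical
    end product (nitrite, NO, N2O or N2); and summarises marker co-occurrence
    and potential gas-emitter fractions by taxonomic family. Includes a
    synthetic community generator with known ground truth for end-to-end
    validation and a packaged synthetic cohort whose family-level counts match
    a published genome survey of the class Halobacteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
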
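Package: wgdtriplets
Title: Inferring the Ploidy of Successive Ancient Polyploidy Events from
    Syntenic Paralog Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes successive ancient whole-genome doublings (WGD)
    and triplings (WGT) from the genome-internal distribution of syntenic
    paralog similarities.  A discrete-time branching process with
    fractionation yields expected gene-triplet profiles for every ploidy
    sequence; a Gaussian mixture fitted to pair similarities and
    maximum-likelihood transition points dichotomize similarities by event
    of origin; trivariate-normal integration over the cutoff-defined
    octants turns underlying profiles into predicted ones, which are ranked
    against the observed triangle counts.  Includes a synthetic-data
    generator that simulates the full branching-plus-divergence model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
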
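Package: ordmotif
Title: Motif Spectra of Directed Ordered Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Motif analysis for directed networks whose nodes form a totally
    ordered set, such as food webs ordered by body mass. Enumerates the 54
    connected ordered 3-node substructures, counts their spectrum in arbitrary
    networks, computes analytic expectations under a directed ordered
    random-graph model, simulates niche-model food webs, and scores
    observed-versus-null deviations with Z-score significance profiles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
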
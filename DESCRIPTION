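Package: trichofe
Title: Diel Iron Allocation and Nitrogen Fixation in Trichodesmium
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An eco-physiological model of a Trichodesmium trichome over the
    12-hour light period, in which intracellular iron is dynamically
    re-allocated among photosystems, active and inactivated nitrogenase and a
    buffer pool. The package couples photosynthetic electron transport with an
    ATP/NADPH budget closure, carbon and dinitrogen fixation, respiratory
    protection and oxygen exchange; converts end-of-day pools to daily growth;
    calibrates against constant-light culture observations; and runs
    growth-maximizing multistart optimizations across an ambient inorganic
    iron gradient to quantify the benefit of dynamic iron allocation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
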
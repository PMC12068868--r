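Package: psmcgrowth
Title: Growth Statistics and Group Contrasts for PSMC Demographic Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing of pairwise sequentially Markovian coalescent
    (PSMC) demographic reconstructions for comparative paleodemography.
    Parses PSMC output files, rescales coalescent-unit step functions into
    effective population size trajectories in individuals and years using a
    per-year mutation rate and a generation time, truncates unreliable recent
    history, and derives per-lineage growth statistics: mean and coefficient
    of variation of Ne, degree of initial growth (1 - N_trough/N_peak), the
    duration of that growth (deltaT), and its rate (degree/deltaT). Screens
    variables for phylogenetic signal with the Abouheif-Moran permutation
    test and contrasts groups of lineages (e.g. seasonally migratory vs.
    resident) with an exact one-tailed Mann-Whitney U test. Includes a
    coalescent-style synthetic-data generator emitting valid PSMC files so
    the full pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
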
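Package: ligfish
Title: Ligand-Based Target Fishing and Bioactivity Profiling by
    Multi-Fingerprint Tanimoto Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse ligand-based virtual screening against a curated
    activity library. A query small molecule is compared to the known
    ligands of every protein target through a panel of 13 binary 2D
    molecular fingerprints; the per-target consensus score (0-13) counts
    the fingerprint kinds whose best Tanimoto similarity exceeds a
    threshold, and a nearest-neighbour model predicts quantitative
    bioactivity values (IC50, EC50, Ki, Kd) on the pActivity scale with a
    per-target variance sigma_p and per-neighbour precision tau. Includes
    ChEMBL-style activity-record curation, a persistent reference-library
    bundle, JSON and PDF report rendering, batch reverse screening, and a
    seeded synthetic fixture generator emulating congeneric ligand series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
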
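Package: helichir
Title: Chirality Quantification for Helical and Helix-Like Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signed, normalized chirality measures for helical structures
    built from scalar triple products of consecutive vectors: difference
    vectors between alpha-carbon atoms for polypeptide helices, and
    per-molecule dipole-moment vectors for helix-like supramolecular
    assemblies such as diphenylalanine peptide nanotubes. Includes readers
    and writers for per-molecule dipole tables, structure handling (PDB,
    mmCIF, PQR) with molecule partitioning, centers of mass, point-charge
    dipole estimation and helix-geometry fitting, seeded synthetic
    generators of dipole rosettes and alpha-carbon helices for property
    testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
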
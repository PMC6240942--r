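Package: srsmut
Title: Substrate Recognition Site Mapping and Variant Screening Analytics
    for Cytochrome P450 Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-rational engineering workflow for cytochrome P450
    enzymes. Maps the six substrate recognition sites (SRS1-SRS6) onto
    query P450 sequences by global alignment to reference-annotated CYPs
    and projection of annotated intervals, profiles per-SRS percent
    identity, enumerates mutation candidates by three selection rules
    (K-helix ExxR-offset hotspots in SRS5, reciprocal mutagenesis between
    homologues, structurally equivalent position transfer), parses and
    applies a compact protein variant notation including segment
    swaps/deletions, and quantifies in vivo variant screens from
    internal-standard normalised GC-MS peak tables: relative yields, fold
    changes, absolute titers via linear standard curves, and
    product-specificity metrics (percent oxygenated, percent target
    product). Ships ground-truthed simulators for homologous CYP families
    with planted SRS divergence and for replicate screening peak tables,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
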
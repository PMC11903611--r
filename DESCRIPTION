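Package: kidneyconcord
Title: Concordance of Kidney mRNA and Immunohistochemistry Protein Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Compares bulk kidney RNA-seq transcript abundance with
    semi-quantitative immunohistochemistry (IHC) protein levels on a shared
    four-level ordinal scale. Reads Human Protein Atlas style normal-tissue
    and consensus-RNA tables, filters IHC calls by antibody reliability and
    kidney compartment (glomeruli, tubules), discretizes nTPM by a
    zero/tertile rule, pairs genes per compartment, tabulates concordance and
    extreme discordance, tests mRNA-protein independence with a chi-square
    test, and cross-validates extreme-discordant pairs against
    compartment-resolved mass-spectrometry spectral counts and an external
    RNA-seq dataset. Ships a latent-Gaussian synthetic-data generator with
    recorded ground truth so the whole pipeline is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
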
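Package: rumenflux
Title: Methane Inhibition Analytics for Respiration-Chamber Cattle Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dose-response methane-inhibition studies in
    ruminants: open-circuit respiration-chamber gas flux (CH4, H2 production
    and yield per kg dry-matter intake), metabolic-hydrogen redirection
    stoichiometry from rumen short-chain fatty acid profiles (HUSr, HUFr,
    average chain length, non-carboxyl SCFA carbon), qPCR relative and
    absolute quantification of rumen microbes, taxon-ratio and alpha-diversity
    indices for 16S count tables, and dose-by-diet repeated-measures ANOVA
    with orthogonal polynomial contrasts and LSD letter displays. A synthetic
    study generator with known ground truth makes every stage testable
    without animal data.
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
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
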
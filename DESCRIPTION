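Package: cesdyn
Title: Stability Dynamics of Closed Microbial Ecosystems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sealed algae-bacteria microcosm
    experiments: temperature calibration and diel oscillation metrics for
    headspace pressure traces, molecular-formula assignment and van
    Krevelen chemodiversity analytics for ultrahigh-resolution mass
    spectrometry peak lists, ASV-table community statistics (Bray-Curtis,
    principal coordinates, PERMANOVA, dispersion), and the permutation
    statistics coupling community succession to dissolved-organic-matter
    chemistry, together with a seeded synthetic-data generator emulating a
    biphasic stability scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
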
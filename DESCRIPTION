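Package: pgpbscreen
Title: Statistical Screening and Selection of Plant-Growth-Promoting Rhizobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage statistical flow sheet for selecting plant-growth-promoting
    bacteria (PGPB) from rhizosphere isolate screening data. Stage 1 converts
    qualitative assay outcomes (phosphate solubilization, siderophore production,
    ammonium production, nitrification) to binary codes and clusters isolates into
    homogeneous phenotype groups with a PCA diagnostic. Stage 2 applies a
    coefficient-of-variation gate with Dixon outlier removal to quantitative
    replicates, codes each isolate against population medians and quartiles on an
    ordinal 0-3 scale, and selects candidates by quartile cut-offs refined with
    one-way ANOVA and Tukey HSD homogeneous groups. Stage 3 summarises
    growth-chamber validation (percent biomass and height change versus an
    uninoculated control, Tukey letters). A calibrated zero-inflated lognormal
    generator produces synthetic screening and growth-chamber datasets with the
    statistical structure the pipeline assumes, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
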
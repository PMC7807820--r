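Package: cecanova
Title: Management and Environment Effects on Rabbit Cecal Microbiota Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Downstream statistical analysis of 16S rRNA OTU count tables from
    growing meat rabbits raised under contrasting management (breeding farm,
    batch, in-feed antibiotics, ad libitum versus restricted feeding): count
    filtering, cumulative sum scaling normalization, rarefaction, alpha
    diversity contrasts on a combined design factor, per-taxon permutation
    analysis of variance with nested contrasts and false discovery rate
    control, taxonomy collapse to phylum and genus relative abundances, and
    sparse partial least squares discriminant analysis with cross-validated
    tuning and selection-stability scoring. Includes a Dirichlet-multinomial
    synthetic OTU table generator that emulates the 425-animal, 12-cell study
    design for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
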
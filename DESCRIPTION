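Package: specoccu
Title: Marker Taxa and Community Structure of Root Fungal Endophytes
    Across Plant Functional Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how root fungal endophyte (RFE)
    communities differ among plant functional groups (PFGs). Implements
    the specificity-occupancy (SPEC-OCCU) marker-OTU statistic with an
    inclusive dual 0.7 filter, rarefaction and alpha-diversity GLMs with
    compact letter displays, Bray-Curtis ordination (PCoA) with one-way
    and pairwise PERMANOVA, random-forest attribution of community
    turnover to trait and abundance distances with permutation
    significance, trophic-mode (FUNGuild-style) composition summaries,
    and a ground-truthed synthetic community generator so the whole
    pipeline can be exercised and validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
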
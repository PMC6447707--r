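Package: cellucoop
Title: Helper and Beneficiary Classification in Cellulolytic Microbial
    Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Culture-independent analysis pipeline for cellulose-rich
    microbial niches: simulation of synthetic communities with truth
    labels, 16S rRNA amplicon merging, quality filtering and naive-Bayes
    taxonomic classification with bootstrap confidence and iterative rank
    escalation, gene prediction and best-hit genus assignment, glycoside
    hydrolase (GH) and carbohydrate-binding module (CBM) domain detection,
    composition-signature contig binning with marker-gene overlay,
    classification of taxa into cellulolytic helpers and cross-feeding
    beneficiaries, and pepstats-style protein property analysis
    (composition, net charge, isoelectric point) for alkaline-adaptation
    assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
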
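Package: patentchem
Title: Drug-Likeness, Scaffold and Database-Coverage Profiling of Patent
    Compound Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles compound collections extracted from patent literature,
    in the style of the SureChEMBL compound-to-patent map dumps. Parses
    patent identifiers and section-source annotations, deduplicates
    compounds by InChIKey, desalts structures and computes physicochemical
    descriptors, classifies drug-likeness against the Lipinski/Veber rule
    of five and the beyond-rule-of-five window, reduces structures to
    Bemis-Murcko scaffolds with yearly novelty tracking, screens the
    published PAINS substructure alert catalog, cross-references compounds
    against external resources by exact InChIKey match with clinical-phase
    annotation, and generates synthetic patent-compound corpora with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
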
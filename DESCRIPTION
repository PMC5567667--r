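Package: adepatterns
Title: Mining Associated Adverse Drug Events with Pattern Structures and
    Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers association rules between adverse drug events (ADEs)
    in patient cohorts using formal concept analysis and its pattern-structure
    extension. ADEs are extracted from visit-level electronic health records
    or from spontaneous-report tables, represented as pairs of drug and
    phenotype sets, and compared through meet operators that generalize over
    drug (ATC) and phenotype (ICD-9-CM, SNOMED-like) class hierarchies via
    least common ancestors. Pattern-concept lattices are built with a
    CloseByOne enumeration, association rules are extracted and filtered for
    novelty, and drug-class co-association ratios are tested against their
    expected values with a Z-test. A synthetic cohort generator with planted
    associations makes the whole pipeline testable without access to any
    clinical database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
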
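Package: umlstidy
Title: Rewrite and Suppression Rules for UMLS-Style Biomedical Lexicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curates UMLS-dialect concept-term tables (MRCONSO/MRSTY RRF) for
    dictionary-based biomedical text mining. Implements nine lexical rewrite
    rules (syntactic inversion, possessive stripping, Schwartz-Hearst short
    form/long form pairing, angular-bracket and parenthetical removal, semantic
    type stripping) that generate new synonyms, and eight suppression rules
    (short tokens, dosages, at-signs, EC numbers, NEC/NOS classification and
    underspecification qualifiers, miscellaneous keywords, long terms) that
    remove strings undesired for term identification. A duplicate/homonym
    guard keeps generated synonyms from colliding with existing strings. Also
    provides a minimal case-insensitive, punctuation-ignoring dictionary
    recognizer with nested-match counting, corpus impact statistics, and a
    deterministic synthetic fixture generator so the whole pipeline is testable
    without a licensed terminology download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stringr,
    tibble,
    utils,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
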
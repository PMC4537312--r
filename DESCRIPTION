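Package: ademiner
Title: Rule-Based Detection of Adverse Drug Event Mentions in Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mentions of adverse drug events (ADEs) in free-text
    clinical notes with a gazetteer-driven rule cascade: candidate terms are
    located with case-insensitive longest-match dictionary lookup, demoted by
    eleven context removal stages (negation, monitoring, warnings,
    other-person references, organisation names, punctuation cues, diagnosis
    homonyms, drug-effect listings, hypotheticals), and rescued by retain
    rules keyed on definite articles, possessive pronouns and diagnostic
    phrases. Ships starter lexicons for the four extrapyramidal side effects
    of antipsychotic treatment plus eight unrelated ADEs, a mention-level
    evaluation protocol (precision/recall, cumulative-stage ablation, Cohen's
    kappa), patient-level stratified prevalence tables with Pearson
    chi-square heterogeneity tests, and a seedable synthetic note generator
    for end-to-end testing without access to clinical records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
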
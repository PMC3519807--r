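Package: fallnlp
Title: Rule-Based Detection and Surveillance of Inpatient Falls in Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines syntactic category decision rules -- small sets of lemmas
    joined by dependency ("+") and precedence ("->") relations -- from labeled,
    morphologically parsed clinical narratives, selects discriminative rules by
    chi-square and Fisher exact tests, and classifies documents with them.
    Also provides the surveillance analytics used to compare document sources
    for adverse-event detection: contingency-table metrics (sensitivity, PPV,
    specificity, F-measure), data-containing rates, fall rates per 1,000
    patient-days, submission lag-time summaries with Wilcoxon rank-sum
    comparisons, injury-severity contrasts, and source-overlap counts.
    Seeded generators for parsed corpora with planted rule patterns and for
    hospital fall-event streams make the full pipeline testable without access
    to protected medical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
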
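Package: traumagrade
Title: CT-Based Severity Grading and Validation for Blunt Splenic and
    Hepatic Trauma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic rule engines for the 1994 and 2018 revisions of
    the AAST Organ Injury Scale and for the CT severity index (CTSI,
    including a hepatic adaptation of the splenic index) applied to blunt
    splenic and hepatic trauma, with a traceable record of which grading
    criterion fired.  Provides mild/severe dichotomization, construction of
    severity-by-outcome contingency tables, diagnostic validation
    statistics (accuracy with Wilson score intervals, diagnostic odds
    ratio with Woolf logit intervals and Haldane-Anscombe correction,
    predictive values, chi-square and Fisher exact association tests,
    Cramer's V), reclassification matrices between grading systems, and a
    seeded synthetic cohort generator that emulates the structure of a
    single-centre blunt abdominal trauma registry so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
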
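Package: freekappa
Title: Agreement Beyond Chance for Free-Response Assessments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of inter-rater agreement beyond chance when raters
    report only positive (abnormal) findings and negative observations are
    not enumerated, as in many imaging studies.  Implements the free-response
    kappa statistic 2d/(b+c+2d) computed from discordant (b, c) and
    concordant-positive (d) finding counts, its limit relationship to Cohen's
    kappa as the number of double negatives grows, a weighted decomposition
    over patients, logit delta-method, Agresti-Coull and Clopper-Pearson
    confidence intervals, a patient-resampling cluster bootstrap, a
    Monte-Carlo coverage study of the interval methods, and a generative
    model of clustered free-response rating studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
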
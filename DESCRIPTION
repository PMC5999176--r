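Package: fhtriage
Title: Family History Triage for Lynch Syndrome and Familial Colorectal
    Cancer Referral
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A rule engine that maps a structured cancer family history
    (a proband and their first- and second-degree relatives, with tumor
    sites and ages at diagnosis) to an automated genetic-counseling
    referral recommendation for suspected Lynch syndrome or familial
    colorectal cancer, following the Dutch nationwide referral criteria.
    The engine ships with an independent brute-force oracle for
    verification, a synthetic cohort generator, JSON/CSV input-output for
    questionnaire records, and the stepped-wedge cluster-trial machinery
    used to evaluate such a tool in practice: two-proportion sample-size
    and design-effect calculations, a switching schedule builder, cohort
    simulation with a latent-scale intracluster correlation, and a
    logit-linear fixed-effects analysis of the binary primary outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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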
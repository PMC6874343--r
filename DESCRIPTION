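Package: sdtlatent
Title: Signal Detection Theory for Latent Item and Person Measures from
    m-Alternative Forced-Choice Responses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of item difficulty and person ability on a
    common d-prime axis from m-alternative forced-choice (m-AFC) response
    data, extending Signal Detection Theory to items whose locations on the
    measurement axis are latent.  Provides the m-AFC psychometric function
    and its inverse, item calibration against the "average" person with
    Wilson confidence intervals mapped into d-prime units, per-person
    maximum-likelihood ability estimates with Hessian-based standard
    errors, an alternating (EM-style) local maximum-likelihood refinement,
    a dichotomous Rasch comparator with joint maximum-likelihood
    estimation, a seeded generative simulator of blocked m-AFC study
    designs, and a command-line interface over CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
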
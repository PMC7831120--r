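Package: cortexpls
Title: Multimodal Cortical Structure Analysis with Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cortical thickness, surface area, and
    quantitative T1 relaxation time across groups of adolescents.
    Implements Erotic Response and Orientation Scale (EROS) vector
    scoring (attraction strength and androphilia-gynephilia phase),
    two-point variable flip angle T1 estimation with B1 correction via
    the method of slopes, histogram-spline mode extraction of regional
    T1 values, mean-centered Task and Behavior partial least squares
    with permutation tests and stratified bootstrap stability ratios,
    a univariate statistics battery (ANOVA, Levene, Welch,
    Brown-Forsythe, LSD and Games-Howell post hocs), and a synthetic
    cohort generator that plants known group and brain-behavior effect
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
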
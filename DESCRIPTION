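Package: ocscreen
Title: Exhaustive Screening of Class Orders with Ordinal Classifier Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a hypothesised total order of multi-class phenotypes
    (developmental stages, ages, gradings) is reflected in a multivariate
    feature representation such as gene-expression profiles. Binary base
    classifiers are trained once for every ordered class pair under a shared
    repeated stratified cross-validation, and their held-out prediction rates
    are memorised in a rate table. Proven upper bounds on the class-wise
    sensitivity of any ordinal classifier cascade turn the table into a fast
    certificate, so all factorially many class orders can be screened
    exhaustively with branch-and-bound pruning; surviving candidate orders are
    cross-checked by evaluating the full cascade. Includes generators for
    linear, curved and non-ordinal Gaussian benchmark data and a command-line
    front end for reproducible screening runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
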
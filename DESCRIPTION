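Package: mavcc
Title: Choice Consistency and Memory Models for Multi-Attribute Visual Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying choice consistency in memory-based
    multi-attribute visual choice (MAVC) experiments. Constructs
    budget-line choice sets of visual objects from attribute prices,
    scores revealed-preference consistency (GARP violations, Afriat's
    critical cost efficiency index, Houtman-Maks, money pump and minimum
    cost indices), simulates random and utility-based choosers as well as
    forgetting-curve and reconstruction-task data, and runs the Bayesian
    analyses of the design: a one-sided Kendall's tau Bayes factor,
    exponential-versus-null forgetting-model comparison by the product
    space method with a quadrature oracle, and replication Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
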
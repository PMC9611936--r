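Package: busmipd
Title: Model-Informed Precision Dosing of Intravenous Busulfan in Children
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Bayesian dosing engine for intravenous busulfan in children
    undergoing conditioning before hematopoietic stem cell transplantation.
    Implements closed-form one-compartment infusion pharmacokinetics, maximum
    a posteriori (MAP) estimation under a parametric allometric model and
    discrete-prior (nonparametric) Bayesian estimation under a reference
    model, AUC estimation from sparse therapeutic drug monitoring samples,
    dose individualization to a cumulative-AUC target, a virtual pediatric
    cohort simulator, and a cross-validation pipeline comparing two models
    with bias/imprecision metrics, linear regression and Bland-Altman
    agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
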
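Package: pcdenoise
Title: Confounder Noise Identification and Correction for Case-Control
    Microbiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies metadata factors that interfere with gut microbiome
    composition and separates their noise-associated from disease-associated
    roles in case-control studies. Genus count tables are filtered, rarefied
    to even depth and centered log-ratio transformed; discrete factors are
    screened with permuted random-forest AUC and mean-decrease-accuracy
    thresholds on principal-component scores, continuous covariates with
    identity-link Poisson regression and backward AIC elimination.
    Interfering principal components are regressed out of the CLR matrix,
    and the signed fold change of case/control classification AUC across an
    (n, p) parameter grid assigns each factor a noise or disease role.
    Downstream analyses cover indicator genera with permutation tests,
    alpha diversity, ANOSIM and NMDS community checks, differential clinical
    indexes, random-forest diagnostic models, and indicator-clinical
    correlations. A synthetic-study generator with planted disease effects
    and confounder roles makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    randomForest,
    pROC,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
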
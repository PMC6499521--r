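Package: prsforge
Title: Polygenic Risk Scores by Penalized Regression and Clumping+Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates polygenic risk scores (PRS) from
    individual-level SNP genotype data. Implements sparse elastic-net
    penalized logistic and linear regression fitted along a regularization
    path with sequential strong rules, warm starts and early stopping, and
    Cross-Model Selection and Averaging (CMSA) to choose the penalty
    automatically; a triple (additive/recessive/dominant) genotype encoding
    for capturing non-additive effects; the Clumping + Thresholding (C+T)
    baseline with its -all/-stringent/-max variants; a liability-threshold
    phenotype simulator over LD-structured synthetic genotypes; and
    ROC AUC / partial AUC evaluation with bootstrap uncertainty. Includes
    PLINK 1 binary (.bed/.bim/.fam) input and output and a scenario runner
    for Monte Carlo cross-validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
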
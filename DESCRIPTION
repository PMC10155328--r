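Package: eigenratio
Title: Eigenvalue-Ratio Estimation of the Number of Informative Principal
    Components in Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates how many top principal components capture latent
    population structure in large genotype count matrices. Genotypes are
    normalized marker-by-marker with binomial-variance scaling, the sample
    covariance spectrum is accumulated over memory-bounded column chunks,
    and the consecutive eigenvalue ratios are tested sequentially against
    critical values obtained by Monte-Carlo simulation of Gaussian
    Orthogonal Ensemble top eigenvalues. Includes a synthetic genotype
    generator under a latent-subpopulation model, a minimal VCF converter,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    parallel,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
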
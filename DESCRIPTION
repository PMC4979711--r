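Package: commsar
Title: Hierarchical Multispecies Models for Species-Area Relationships
    Under Incomplete Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates species-area relationships (SARs) from survey data in
    which patches are only partially covered by sampling plots and individuals
    are imperfectly detected.  Implements hierarchical community models of
    abundance (Poisson patch-level abundance with species-specific area
    scaling, binomial coverage thinning, and multinomial encounter-history
    detection) and of plot-based frequency (binomial occurrence over a plot
    tessellation with a logit-linear occurrence-area relationship), with
    parameter-expanded data augmentation for species never detected.  Models
    are fit by MCMC through JAGS.  Patch-level species richness, total
    abundance or frequency, regional richness, and SAR curves over an area
    grid are derived from the posterior; constant-density null models and the
    random-placement closed form are included, together with a synthetic
    community simulator and a density-area-relationship experiment linking
    species-level area scaling to community SAR shape.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
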
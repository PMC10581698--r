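Package: tmrcanet
Title: Simulation-Trained Convolutional Inference of Pairwise Coalescence
    Times and Allele Ages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Likelihood-free inference of locus-specific pairwise times to
    most recent common ancestor (TMRCA) and recombination breakpoints from
    phased haplotype data, using a multitask one-dimensional convolutional
    network trained on coalescent simulations. Includes a coalescent
    simulation engine (constant or piecewise-constant demography, variable
    genetic maps, SNP-array ascertainment, phasing and genotyping error
    models, non-crossover gene conversion, and Beta-coalescent multiple
    mergers) with exact genealogical ground-truth labels; per-pair genomic
    feature extraction; network training with homoscedastic multitask
    uncertainty weighting, imbalance-aware relatedness sampling and transfer
    learning; piecewise-constant TMRCA postprocessing; allele-age dating from
    concordant and discordant haplotype pairs with outlier rejection and
    multi-population aggregation; model interpretability analyses (saliency
    maps, input perturbations, hidden-channel probing); and construction of
    MAF-adjusted quantile-normalized allele-age genome annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with msprime (>= 1.0) and tskit on the
    PATH, used as the coalescent simulation backend.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
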
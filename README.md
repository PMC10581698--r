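# tmrcanet

Likelihood-free inference of locus-specific pairwise coalescence times
(TMRCAs) and recombination breakpoints from phased haplotypes, with
downstream allele-age dating and heritability-annotation construction.

## Who this is for

Population geneticists who need per-site pairwise TMRCA tracks — for
identity-by-descent analysis, allele-age estimation, or selection-related
genome annotations — in settings where coalescent HMMs are awkward:
nonrandomly ascertained SNP-array data, phasing/genotyping error,
non-crossover gene conversion, or multiple-merger (Beta) coalescents. The
whole pipeline runs at desk scale on one CPU; every stochastic stage is
reproducible from a single master seed.

## The method

For a haplotype pair, the TMRCA is a piecewise-constant function of genomic
position whose breakpoints are historical recombination events. A 1-D
convolutional network is trained entirely on coalescent simulations where
the genealogy — hence every pairwise TMRCA t(x) and breakpoint — is known
exactly. Six per-site input channels (XOR and AND of the alleles, MAF,
distance in bp and in cM to the previous site, and the identical-by-state
run length through the site) are mapped, through an input batch-norm and a
stack of (convolution, batch-norm, ReLU) blocks with a 1x1 head, to per-site
log t̂(x) and a breakpoint logit. The two tasks share a representation and
are combined with learned homoscedastic uncertainties:

    L = exp(-s_reg) · Huber(log t̂, log t) + exp(-s_cls) · wBCE(b̂, b) + s_reg/2 + s_cls/2

with inverse-class-frequency weights in the cross-entropy (breakpoints are
rare) and Adam (lr 0.001) on the weights. Each epoch simulates fresh data
(64 independent coalescent simulations, one pair each), alternating uniform
with relatedness-informed pair sampling to oversample recent coalescence;
model selection takes the checkpoint minimizing a density-weighted Huber
score on the closest 5% of held-out pairs. Raw tracks are refined to
piecewise-constant form by averaging t̂ between sites whose breakpoint
probability exceeds a threshold (defaults 0.7 sequencing / 0.55 array).

A variant with k ≥ 2 derived-allele carriers is dated from its pairwise
TMRCAs: tc = max over concordant pairs (both carry it) bounds the age from
below, td = min over discordant pairs from above, after rejecting outlier
pairs with the threshold that minimizes the number of rejections; the age
estimate is (tc + td)/2 and the rejected fraction is a quality proxy.
Estimates aggregate across populations by kept-pair-count-weighted averages
of the bounds. For heritability workflows, ages are MAF-binned (10 bins,
MAF ≥ 0.05) and quantile-normalized to N(0, 1) within bins, written in
S-LDSC `.annot` format.

The coalescent simulations run through msprime (bundled Python driver);
the network, backpropagation and optimizer are implemented in base R and
verified against finite differences.

## Worked example

Simulate 20 haplotypes over 500 kb under constant Ne = 10,000
(mu = 1.65e-8, crossover 1e-8), then date every non-singleton variant from
the exact genealogical TMRCAs:

```r
library(tmrcanet)

cfg <- sim_config(n_haplotypes = 20L, region_length = 5e5, seed = 42L)
ds  <- simulate_dataset(cfg, want_mut_times = TRUE)
ds$panel
#> haplotype_panel: 20 haplotypes x 1184 sites, 705-5e+05 bp (0.499 cM)

ages <- date_panel(ds$panel, ds$labels, seed = 1L)
head(ages[, c("site", "pos", "derived_count", "lower", "upper", "age",
              "rejected_fraction")], 5)
#>   site  pos derived_count     lower     upper       age rejected_fraction
#> 1    1  705            15 18979.362  44445.67 31712.516                 0
#> 2    3 2811             3  2099.787 110288.20 56193.992                 0
#> 3    4 3062             3  3787.467  11409.95  7598.711                 0
#> 4    5 3100             3  2099.787 110288.20 56193.992                 0
#> 5    6 3284            17 44445.671 110288.20 77366.934                 0
```

`lower`/`upper` are the concordant/discordant coalescent bounds in
generations, `age` their midpoint, and `rejected_fraction` the share of
pairs removed by the outlier filter (0 here — exact TMRCAs never need
filtering). With truth as input the true mutation time falls inside
[tc, td] for 100% of dated variants (827 of 827 above).

Training and inference follow the same grammar:

```r
tc <- train_config(sim = cfg, model = model_preset("desk", L = 512L),
                   epochs = 15L, master_seed = 11L)
ck <- train(tc)                                   # ~5 min on one CPU
track <- predict_pair(ck, ds$panel, c(1L, 2L))    # per-site t̂ and P(breakpoint)
segments <- make_piecewise(track, threshold = 0.7)
```

On held-out simulations this desk-scale model reaches a Spearman rank
correlation of ~0.87 between predicted and true log-TMRCA (printed by the
acceptance script below).

A thin command-line launcher (`inst/cli/tmrcanet`) exposes
`simulate | train | finetune | infer | date | annotate | interpret` over a
YAML run configuration with strict key checking.

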
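# qmpbench

Benchmarking microbiome count transformations against quantitative ground
truth.

## The problem

Metagenomic sequencing is compositional: each sample's reads are a
fixed-size draw from its *relative* taxon profile, so variation in total
microbial load (cells per gram) is invisible, and the fraction of a
community actually surveyed — the **sampling depth**, library size divided
by load — differs systematically across samples. Both effects corrupt the
analyses microbiome studies care about: richness estimation, taxon–taxon
association networks, and taxon–metadata (e.g. taxon–disease)
correlations. A zoo of remedies is in routine use, from simple
proportions to RNA-seq-style normalizations to experimentally informed
quantitative profiling, and they do not agree.

`qmpbench` is a simulation-first benchmark of thirteen such strategies.
It generates communities where the absolute truth is known, degrades them
through simulated sequencing and noisy load measurement, and scores each
transformation on how much of the truth it recovers. The package is for
microbiome methodologists and analysts choosing a normalization strategy,
and for anyone who wants a controlled sandbox where "the right answer" is
available.

## The model in brief

Ground-truth communities are multivariate negative binomials built from a
Gaussian copula: a 300-taxon latent correlation matrix with mostly
positive entries, 1000 samples of latent Gaussians mapped through NB
inverse CDFs with per-taxon parameters (size ∈ {1, 2}, probability
∈ (0, 0.1)). Per-sample loads (row sums) are scaled into the biological
window [1.9×10⁹, 1×10¹³] cells/g. Three ecological scenarios:

* **blooming** — an accepted matrix contains a *bloomer*, a taxon with
  Spearman ρ > 0.9 against loads;
* **succession** — the bloomer is replaced by a taxon of mild load
  correlation (latent r = 0.5);
* **dysbiosis** — half the cohort is downsampled to 20 % of its cells,
  the bloomer becomes an *opportunist* (r = −0.5) and 10–11 taxa become
  *unresponsive* (r = 0.01).

Sequencing draws multinomial reads at log-normal library sizes
(meanlog 10.3, sdlog 0.3; ≈30 000 reads median). Load measurement adds
log-normal noise tuned to a log-scale Pearson r in [0.85, 0.95].
Metadata matrices carry 100 covariates with a known truth map (designed
|Spearman| 0.3–0.6 to taxa or loads).

The thirteen transformations — Seq, Rel, RMP, AST, CLR, CSS, UQ, TMM,
RLE, GMPR, VST, QMP, ACS — are implemented from their published formulas
(`transformCounts()`), and recovery of diversity and of taxon–load,
taxon–metadata, taxon–taxon and taxon–disease associations is scored as
precision / sensitivity / false-positive rate against the ground truth,
with sign-discordant detections penalized on both sides. See the methods
vignette (`vignettes/methods.Rmd`) for every modelling decision.

## Worked example

```r
library(qmpbench)

community <- simulateBlooming(nSamples = 1000, nTaxa = 300, seed = 42)
community
#> CommunityExperiment: 300 taxa x 1000 samples [blooming]
#>   loads: 3.48e+10 - 5.47e+11 cells/g (spread 15.7)
#>   special taxa: taxon_234(bloomer)

ce <- subsampleSamples(community, 200, seed = 43)
se <- simulateSequencing(ce, seed = 44)
le <- simulateLoadMeasurement(loads(ce), seed = 45)
le
#> LoadEstimates: 200 samples, achieved log-scale r = 0.919 (target 0.913)

qmp <- transformCounts(se, "QMP", loads = le, seed = 46)

divTruth <- alphaDiversity(ce)
richnessCorrelation(divTruth$observed, alphaDiversity(qmp)$observed)
#>          R            p category
#> 1 0.867345 6.531513e-62   strong
richnessCorrelation(divTruth$observed,
                    alphaDiversity(transformCounts(se, "Seq"))$observed)
#>          R            p category
#> 1 0.716851 7.649151e-33 moderate
```

The bloom inflates cell density, so raw sequencing under-surveys exactly
the samples that are richest; QMP's even-sampling-depth rarefaction
restores a strong richness correlation (R = 0.87) where raw counts only
manage 0.72 — and in many replicate matrices raw counts drop to
non-significant or negative.

Association recovery makes the contrast starker. Of the 180 true
taxon–load associations in this matrix, QMP recovers 163 with no sign
flips, while raw counts recover 1, with 133 discordant (sign-flipped)
detections — the compositional signature of a bloom:

```r
ref <- detectAssociations(ce, loads(ce), family = "taxon_load")
classifyVsReference(ref, detectAssociations(qmp, estimatedLoads(le),
                                            family = "taxon_load"))
#>    TP FP FN TN discordant precision sensitivity       fpr
#> 1 163 49 17 71          0 0.7688679   0.9055556 0.4083333
classifyVsReference(ref, detectAssociations(se, estimatedLoads(le),
                                            family = "taxon_load"))
#>   TP  FP FN TN discordant   precision sensitivity       fpr
#> 1  1 119 46  1        133 0.003952569 0.005555556 0.9960474
```

`runBenchmark(benchmarkConfig(...))` orchestrates the full design — 10
replicate communities per scenario, all 13 methods, all association
families — and returns tidy metric tables; `spreadAnalysis()` and
`sweepBenchmark()` reproduce the load-spread disease analysis and the
depth/cohort-size sweeps.

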
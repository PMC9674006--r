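---
title: "Models and methods behind phyllodisturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyllodisturb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phyllodisturb analyses how a pulse disturbance — a foliar fungicide
application — reshapes paired fungal and prokaryote amplicon communities in
a factorial field design (tillage management x treatment x days post
fungicide, with replicate plots and plants), and how quickly those
communities recover. This vignette explains each statistical component, the
assumptions behind it, the tunable parameters that matter, and the design
choices made where the methodology was genuinely open.

## Input data and pre-filtering

All analyses start from taxa x samples count matrices (fungal and
prokaryotic OTU tables), a rank taxonomy, and per-sample metadata (crop,
management, treatment, dpf, replicate plot, compartment). Differential
abundance on sparse, noisy OTUs is dominated by stochastic presence, so two
pre-filters are applied before testing: taxa whose mean per-sample relative
abundance falls below `mean_rel_min` (default 1e-5) and taxa with zero
counts in at least `zero_sample_frac` (default 95%) of samples are removed,
and for treatment contrasts taxa never observed in fungicide-treated plots
are dropped as untestable. Two conventions here were open and are now
fixed and configurable: a taxon exactly at the abundance threshold is kept,
one exactly at the zero-fraction threshold is dropped; and mean relative
abundance is the mean of per-sample proportions (the compositionally
natural choice) rather than a pooled-count ratio, which is available via
`pooled = TRUE`. The filters are applied within each analysis subset (e.g.
per management stratum) rather than once globally, so every comparison is
filtered against exactly the samples that enter it.

## Ordination and permutation inference

Community contrasts use Bray-Curtis distances. PERMANOVA (`permanova()`)
partitions the Gower-centred distance matrix by the design factors and
compares pseudo-F to label permutations with the +1 convention, so p-values
are never zero; term order follows the sequential (Type I) strategy by
default, with marginal testing available. Dispersion differences are
checked separately (`beta_dispersion()`): samples are embedded by principal
coordinates, distances to group centroids combine the real and imaginary
parts in the standard way, and group labels are permuted. A significant
PERMANOVA with a non-significant dispersion test supports a genuine
location shift.

Treatment effects at a single time point are isolated with partial
constrained analysis of principal coordinates (`cap_partial()`): the
distance matrix is embedded, the management factor is partialled out, the
residual variation is regressed on the treatment factor, and the
constrained inertia fraction is tested with 1000 permutations of residuals
under the conditioned model. Negative PCoA eigenvalues are retained
untouched by default; a Lingoes correction is available but changes total
inertia and is therefore opt-in. Permutations are unrestricted by default;
plot-level blocking (`block = "replicate_plot"`) is available for designs
where plot is the natural exchangeable unit — with four replicate plots per
cell the unrestricted test has far better resolution, which is why it is
the default rather than an endorsement of ignoring the blocking.

## ANCOM differential abundance

Counts are compositional: only relative information survives sequencing.
ANCOM sidesteps the unknown scaling by testing every pairwise additive
log-ratio. For taxon i, each of the m - 1 ratios log((c_i + pc)/(c_j + pc))
is compared between treatment groups with the rank-sum test (normal
approximation with tie and continuity correction); the m - 1 p-values are
Benjamini-Hochberg adjusted within the reference taxon, and W_i counts the
rejections. A taxon is called differentially abundant when W_i exceeds 70%
of the taxa tested — the conventional decision threshold for this
statistic. The pseudocount (default 1) is the zero-handling policy;
structural-zero detection and covariate adjustment are deliberately out of
scope. Direction is the sign of the median CLR difference, so "reduced by
fungicide" is well defined even though absolute abundances are not.
The W statistic is exactly invariant to jointly rescaling counts and
pseudocount, and invariant up to a sign to swapping the group labels.

## Recovery classification

Within a stratum, ANCOM is run at every time point (the pre-spray point
serves as a negative control) over one shared taxon universe. Each taxon's
trajectory is then classified by a pure rule on its evidence tuple:
significant at the first post-spray point but not thereafter = recovered
(transient effect); significant at the first point and at every later
point = non-recovered; non-recovered taxa that were present pre-spray,
kept zero counts in every post-spray fungicide sample, and persisted in
controls = locally extinct; significant only at the final point =
indirect; anything else = unaffected. With exactly two post-spray points
"every later point" collapses to the final one; with more, non-recovery
requires significance at all of them. The recovery percentage divides each
class by the taxa significantly *reduced* at the first post-spray point
(recovered + non-recovered + locally extinct); a denominator that ignores
direction is also reported, since either reading of "affected" is
defensible.

## Core microbiome

The core is defined by abundance-occupancy: taxa are ranked by occupancy
(ties by mean relative abundance, then taxon id, making the ranking fully
deterministic and input-order invariant). Because Bray-Curtis similarity of
two relative-abundance profiles decomposes additively over taxa
(1 - d = sum_i min(x_i, y_i)), each taxon's contribution to mean community
similarity is its mean min-share over all sample pairs. The core is the
minimal ranked prefix that captures all but the final 2% of that total —
taxa beyond it contribute only the "last 2% increase". The 2% threshold is
exposed; callers restrict the table to the undisturbed samples of one
management before calling, since the core is defined per management from
non-disturbed plots.

## Co-occurrence networks

The meta-network is estimated by Meinshausen-Bühlmann neighborhood
selection: each taxon's CLR profile is lasso-regressed on all others over a
log-spaced path of 100 penalties spanning two decades below the smallest
penalty that zeroes every coefficient. CLR is applied within each domain
separately because compositional closure acts per sequencing library. The
penalty is chosen by StARS stability selection — 20 subsamples of size
floor(10 sqrt(n)), selecting the densest graph whose monotonized edge
instability stays at or below 0.05. Edges exist under the OR rule (either
directed neighborhood suffices; AND is available) and carry the mean of
the two directed standardized coefficients as a signed weight.

Per-sample subnetworks are induced subgraphs on the taxa present (count
> 0) in that sample, and network complexity is linkage density: edges per
node, 0 for an empty sample. Cross-group involvement (e.g. the
Bulleribasidiaceae yeasts against a prokaryote genus) is summarized as the
cumulative signed weight of bipartite edges inside each subnetwork.
Complexity and related metrics are compared between treatments within each
(management, dpf) cell by the unpaired two-sample rank-sum test; the
phrase "ranked sign test" is ambiguous between the paired and unpaired
variants, and since the compared groups are distinct plots the unpaired
test is the default, with the paired signed-rank variant available.

One meta-network is fitted per crop with control and fungicide samples
pooled; subnetworks then differ purely through composition. This mirrors
treating the meta-network as the pool of possible associations, with
disturbance acting by removing nodes.

## Random-forest linkage

To probe indirect effects of yeast loss on prokaryotes, per-sample richness
of a fungal family (default Bulleribasidiaceae) is predicted from
prokaryote relative abundances in the fungicide-treated samples of one
management. Relevant features are found by a shadow-feature (Boruta-style)
all-relevant search: each iteration appends per-column permutations of the
features, fits a forest, scores a hit when a real feature's permutation
importance beats the best shadow, and settles features by a
Bonferroni-corrected binomial test on cumulative hits. mtry is then tuned
by the OOB-guided outward search (start at p/3, multiply/divide by 2 while
relative OOB-MSE improvement is at least 5%), and the final forest reports
OOB percent variance explained, 100 x (1 - MSE_oob / Var(y)) — which can
be negative — alongside the squared observed-vs-OOB-predicted correlation;
the two summaries differ by construction and both are reported. Model
significance is a permutation test: the response is permuted and the
forest refitted, and the p-value is the +1-corrected fraction of
permutations matching the observed percent variance. The selected features
are finally refitted on the control samples of the same stratum; under a
disturbance-mediated coupling they should not transfer.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the field design and
plants every effect the pipeline is supposed to detect, so the entire
analysis chain can be validated against known truth.

Latent structure: per-sample log-abundances are drawn from a multivariate
normal whose precision matrix carries the planted co-occurrence edges.
The precision matrix is strictly diagonally dominant (margin 0.1), which
guarantees positive definiteness while keeping planted partial
correlations at the 0.2-0.4 magnitudes the co-occurrence literature treats
as detectable structure; a larger dominance margin attenuates the partial
correlations of well-connected nodes to the point where no estimator could
recover them. A configurable fraction of fungus-prokaryote edges is
negative.

Disturbance: fungicide samples at post-spray time points receive
multiplicative effects per planted recovery class — defaults recovered
(x0.1 at 13 dpf, x1 at 33), non-recovered (x0.1, x0.1), locally extinct
(x0, x0), indirect (x1, x4), target pathogens (x0.05 throughout). The
magnitudes are the generator's own calibration, chosen to be detectable at
the design's replication (n = 12 per comparison); the directions are the
biology. A multiplier of zero forces exact zeros, so local extinction is
planted literally. A configurable fraction (default 60%) of
non-recovering taxa instead recover under no-till, encoding
management-dependent resilience.

Coupling: selected prokaryotes gain latent abundance proportional to the
realized deficit of Bulleribasidiaceae richness below the control-sample
median — a competition-release model in which the niche opens only when
yeasts drop below their undisturbed level. This matters for the transfer
test: control samples hover at baseline richness, so the coupled
prokaryotes carry almost no signal there, while disturbed samples span a
wide richness range.

Counts: within each domain, latent log-abundances are closed by softmax
and drawn multinomially at a negative-binomial sequencing depth (defaults
~30,000 reads for fungi, ~47,600 for prokaryotes, dispersion 10 —
realistic uneven libraries). Core taxa are planted by boosting base
log-abundance (default 20 taxa, +3 log units), which makes them both
abundant and near-ubiquitous.

What the generator does not emulate: taxonomic correlation of effects
beyond the planted classes, read-level error, chimeras or contaminants,
spatial autocorrelation among plots, and temporal autocorrelation within
plants. Passing the synthetic checks therefore demonstrates that the
estimators recover the structures they target at field-realistic size and
noise — not that real phyllosphere data satisfies the model.

## Validation problem sizes and numerical choices

The end-to-end checks run at deliberately chosen sizes: ANCOM calibration
and power at m = 50 taxa with n = 12 + 12 over 100 replicates; permutation
calibration (PERMANOVA, dispersion, forest) over 200 null simulations
each; graph recovery on 60-node models with n = 200 over 10 replicates;
the StARS null-sparsity calibration at n = 300, chosen so the subsample
ratio (b/n ~ 0.5) sits inside the regime the stability argument assumes
(at n = 200 it would be 0.7, where the subsample graphs are too close to
the full-data graph to measure instability well); the
management-resilience network pattern over 20 scenario replicates; the
richness-coupling pattern over 10. Replicate counts balance the stochastic
acceptance thresholds against a test suite that completes in minutes.

Numerical conventions worth knowing: permutation p-values use the +1
convention everywhere; the rank-sum test uses the normal approximation
with tie and continuity corrections (matching `wilcox.test(exact =
FALSE)`); BH adjustment happens within each ANCOM reference taxon; CLR
uses pseudocount 1; lasso fits standardize columns once globally and run
with a shared penalty path across nodes; all stochastic steps take
explicit seeds and restore the caller's RNG state.

## Command-line use

`inst/cli/phyllodisturb.R` is a thin Rscript front end over
`run_pipeline()`: stages (simulate, filter, ordinate, ancom, recovery,
core, network, rflink, report — or all) write TSV/JSON artifacts into a
run directory, each stage reads its inputs from disk so any stage can be
rerun in isolation, and a structured log records seeds and thresholds.

## Known limitations

ANCOM here is the W-statistic formulation with a fixed pseudocount; it
does not implement structural-zero detection or bias correction, so its
null behaviour on data with many systematic zeros differs from
bias-corrected variants. The recovery classifier inherits ANCOM's power:
at n = 12 per group, taxa with mild declines are classified unaffected.
StARS instability is calibrated for sparsistency, not edge-weight
accuracy; weights should be read as association signs and rough
magnitudes. The forest transfer test compares significance, not effect
sizes, and a richly structured control community can legitimately yield a
significant transfer if the coupling is not disturbance-specific.
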
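---
title: "Models and methods behind poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The experiment being modeled

poolscreen analyzes chemogenomic screens in which a pool of several
thousand homozygous deletion strains competes in liquid culture under
compound treatment. Each strain carries two unique barcodes (an UP and a
DOWN tag); after a fixed number of population doublings ("generations"),
genomic DNA is harvested and the tags hybridized to a barcode microarray,
so the log2 hybridization signal of a tag tracks the log2 abundance of its
strain. The design this package targets has, per compound and generation
point, 12 untreated control chips and 3 replicate chips at each of three
doses calibrated to 25%, 50% and 100% of the concentration inhibiting
wild-type growth by 20% (the IC20), with harvests after 5 and 15
doublings. A strain whose deleted gene is needed to tolerate the compound
grows slower than the pool and its signal drops on treated chips; one
blocked doubling costs roughly one log2 unit relative to unaffected
competitors.

## The synthetic-data generator

`generate_pool()` simulates this design directly on the log2 scale with an
additive model per measurement:

    Y(strain, tag, chip) = baseline(strain) + chip_effect(chip)
                           + tag_offset * [tag = DOWN]
                           - depletion(strain, dose, generation) + noise

A planted strain's growth-rate defect `d` (fraction of growth lost per
doubling) maps to an expected depletion of `d * generations` log2 units,
which makes the truth analytically checkable: the 15 g depletion is
exactly three times the 5 g depletion for the same defect. No
scanner-level intensity model is simulated, because every analysis stage
operates on log2 signals.

Default settings are the study conditions: 4,607 strains, 12 controls and
3 replicates per dose per generation point, generations 5 and 15,
measurement noise SD 0.3 log2, chip random-effect SD 0.2 log2, and a
systematic DOWN-minus-UP tag offset of 0.5 log2. The noise and chip scales
are chosen as values typical of replicated two-channel-style array data;
the tag offset only needs to be non-zero so the tag term of the dose model
is exercised. Control chips are simulated per generation point (the
12-vs-3/3/3 comparison is within a generation); the sharing structure is a
generator parameter because either choice is defensible.

What the generator deliberately does not emulate: intensity-dependent
dye/hybridization bias beyond what normalization tests inject explicitly,
saturation, probe cross-hybridization, and outlier chips. Tests passing on
these simulations therefore validate the statistical machinery under the
stated noise model, not robustness to every array artifact.

Pathway graphs, scored interaction networks (preferential attachment, so
node degrees are heavy tailed like curated protein-interaction data, with
edge scores uniform in 700-1000) and lagged-logistic growth curves sampled
every 15 min for 24 h (97 points per well) round out the inputs, each with
planted, seed-independent truth.

## Normalization: faster cyclic loess

`fastlo_normalize()` removes intensity-dependent chip effects. Per sweep,
the reference pseudo-chip `A` is the row mean across chips; each chip's
deviation `M = chip - A` is smoothed against `A` (robust local regression,
tricube weights, two robustifying iterations, span 0.4 by default) and the
fitted trend subtracted. One fit per chip per sweep — instead of one per
chip pair — is the "faster" in faster cyclic loess. UP and DOWN tags are
normalized as separate rows and averaged afterwards (`regroup_tags()`),
mirroring how the arrays are processed in practice.

One numerical subtlety is worth recording. The fitted curves of all chips
can share a common component; subtracting it from every chip shifts `A` by
the same amount and leaves every `M` unchanged, so a naive cyclic update
re-applies it sweep after sweep and the matrix drifts without converging.
poolscreen therefore centers the per-sweep adjustments across chips before
applying them. Centering leaves all between-chip corrections intact (for
any genuine difference the fitted curves sum to approximately zero) and
makes the iteration contractive; convergence is declared when the largest
absolute adjustment falls below `tol` (default 0.01 log2, `max_iter` 10).
Span, tolerance and iteration cap are exposed because the original
analysis does not record them.

On data whose chip differences are smooth (offsets, intensity-dependent
trends), the procedure converges in a few sweeps and is idempotent. On
pure noise the local regression also fits some wiggle per sweep; with few
hundred rows this can keep the maximum adjustment above a tight tolerance
even though the fit is harmless on average. At genome-scale row counts the
wiggle amplitude shrinks roughly with the square root of rows-per-window
and the issue disappears; the planted-recovery simulations run the full
pipeline at 1,000+ strains for this reason, and the false-discovery
inflation seen when normalizing very small pools is documented as a
limitation rather than hidden.

## Differential strain sensitivity analysis

The fitness score of a strain under a condition is

    score = mean(log2 treated) - mean(log2 control)

over chip-level (tag-averaged) values; negative scores mean depletion,
i.e. the gene is required for tolerance. Significance per strain is a
two-sample t test of treated against control chips with
Benjamini-Hochberg q-values within each condition, significant at
q < 0.05.

The t statistic pools the group variances by default (df = 13 for 3 vs 12
chips). The unequal-variance (Welch) statistic is available as an option
but is a poor default here: with three treated chips it has about two
effective degrees of freedom, so even a 4-log2 depletion cannot reach a
BH-corrected q below 0.05 among thousands of strains — no hit would ever
survive, which is incompatible with how such screens are actually scored.
The generative model gives both groups equal variance by symmetry, so
pooling is also the better-specified choice. The original screen's
significance procedure lives in prior work and is not reproduced here;
this transparent stand-in is calibrated by simulation instead (type-I
error at nominal level; sensitivity 0.9+ and false-discovery proportion
below 0.1 for planted -2 log2 effects under the study design).

`consensus_filter()` implements the cross-treatment consensus rule: a gene
is a consensus hit if it is significant in at least `k_min = 3` of a
compound's six conditions. Significance of either sign counts by default,
since published consensus tables can include resistant (positive-score)
genes; `sign = "negative_only"` restricts to the sensitive-gene framing.
The package ships curated TSV transcriptions of three published
consensus-hit tables (hydroquinone, catechol, benzenetriol; 31, 33 and 12
genes) as fixtures; empty cells mean "not significant in that condition"
and Unicode minus signs are normalized on read.

## Gene-wise mixed-effects dose models

For each gene, `fit_gene_model()` fits by maximum likelihood

    Y_ij = mu + u_i + delta * [tag_j = DOWN] + beta_d(i) + e_ij

with chip random intercepts `u_i ~ N(0, sigma_chip^2)` capturing the
correlation of the two tag measurements on a chip, a fixed tag offset
`delta`, and categorical dose effects `beta_25, beta_50, beta_100`
relative to control. The reduced model drops the dose effects. ML rather
than REML is used so likelihoods are comparable across fixed-effect
structures; generations are analyzed separately; masked measurements are
dropped, never imputed.

For complete data the ML problem separates exactly: chip means carry
`mu + delta/2 + beta` with variance `sigma_chip^2 + sigma_res^2/2`, and
within-chip tag differences carry `delta` with variance `2 sigma_res^2`.
Estimates are therefore closed form (the boundary `sigma_chip = 0` is
handled explicitly by pooling the two variance components), which is what
makes the 100,000+ fits of the calibration suites feasible; the fits agree
with `nlme::lme(method = "ML")` to numerical precision, and chips missing
one tag are handled by a one-dimensional profile of the variance ratio.

The dose test is the likelihood ratio `LRT = 2(l_full - l_reduced)`,
clipped at zero. Two p-values are computed. The large-sample reference
(chi-square, df 3) is exposed as `p_chisq`, but at 21 chips it is
measurably anticonservative: the LRT is `n * log(1 + 3F/(n - 4))`, a
monotone transform of a statistic that is exactly F(3, 17) under the null,
and the chi-square tail of that transform yields about 8% of p-values
below 0.05. The default `p_raw` therefore inverts the exact finite-sample
F distribution of the same statistic, which is calibrated at any chip
count (and identical to the chi-square answer asymptotically). Holm
step-down correction across genes at 0.05 selects the gene set for network
analysis; with the exact p-values the family-wise error stays at its
nominal level.

`kruskal_wallis()` supplies the rank-based alternative used as the
gene-level statistic for pathway enrichment: a tie-corrected H comparing
the four dose groups (12/3/3/3 replicates). Note that the chi-square
approximation to H is conservative at these small group sizes (about 3%
of null p-values below 0.05); this does not affect the pathway test,
which permutes H values directly and never consults their chi-square
p-values.

## Pathway and category enrichment

Category over-representation (`hypergeom_enrich()`) is the upper-tail
hypergeometric test `P(X >= k)` for an overlap of `k` query genes with a
`K`-gene category in an `N`-gene population, reported below a 0.01 cutoff
by default. The population defaults to the union of annotation members and
is overridable, since the appropriate universe depends on the array.

The graph-aware pathway test (`sepea_test()`) rewards pathways whose
perturbed genes are close in the pathway graph. The observed statistic is

    T = mean_g s_g + mean_{(g,h) in E} min(s_g, s_h)

where `s` are the gene-level statistics (Kruskal-Wallis H by convention):
an edge contributes only when both endpoints are perturbed, so
concentrated perturbations score higher than scattered ones of equal
magnitude. The null draws the pathway's statistics without replacement
from the universe pool, assigns them to node positions at random, and
recomputes T; `p = (1 + #{T* >= T_obs})/(n_perm + 1)` with ties counted
conservatively, so p is never zero and is reproducible under a fixed seed.
This statistic is this package's own concrete proximity-rewarding variant
— the originally used statistic is specified in a separate methods paper
not reproduced here — and it is validated by its own properties:
exhaustive-assignment agreement on tiny pathways, null uniformity, and
topology sensitivity (clustered beats scattered perturbations on path
graphs). The default permutation count is 10^5 for analyses; tests use
999-9,999 for speed.

Pathways are first filtered to those with measured data for at least 60%
of their genes (inclusive boundary). For the retained pathways,
`cluster_pathways()` transforms the pathway-by-condition p-value matrix to
-log10 p, computes `1 - Spearman correlation` distances between pathway
profiles, and clusters with average linkage; missing p-values impute to 1
with a warning and constant profiles are placed at the maximum distance 2
with a warning. The tree is exportable as Newick.

## Sub-network detection on the interaction network

`load_network()` reads a scored edge list (scores 0-1000) and keeps edges
at or above the high-confidence cutoff 700 (inclusive). Candidate clusters
(`detect_clusters()`) are the connected components of the subgraph induced
by the significant genes — Holm-selected dose-model genes by default, DSSA
consensus genes if preferred — plus their neighbors within one hop;
components with fewer than two significant nodes are discarded. This
seed-and-expand definition is a transparent reconstruction: the original
clustering methodology was unpublished at the time, and no claim of
equivalence is made.

Cluster significance must respect hub bias: a random gene is more likely
to neighbor a hub than a peripheral node, so a null that ignores degrees
overstates enrichment near hubs. `cluster_significance()` counts the
significant nodes in the cluster and compares against draws of an
equal-sized node set matched to the significant set's degree distribution
within log2-degree bins (sparse bins are widened with a warning). Because
only the in-cluster count matters, each bin's contribution is drawn
exactly as a hypergeometric count — equivalent to explicit degree-matched
node sampling, which is retained as `draw_degree_matched()` and verified
against the shortcut in the tests. The add-one permutation convention is
used, and the per-bin construction preserves the degree histogram by
construction. Because the observed count is a small integer, the p-value
is discrete and conservative; calibration tests therefore use clusters of
varying sizes so the pooled null distribution is close to uniform.
`annotate_clusters()` reports each cluster's top four categories by
hypergeometric enrichment against the network's node universe.

## Growth curves and dose selection

`growth_auc()` integrates background-corrected OD over time by the
trapezoid rule (exact for the constant and linear test curves, and within
0.5% of the analytic integral of a logistic curve at 15-minute sampling).
Background correction subtracts the well's first reading by default — the
pre-inoculation reference — because the original protocol says only
"background corrected"; a numeric blank or no correction are options, and
negative corrected values are flagged rather than clamped (heavily
inhibited wells can dip below their blank). `percent_of_control()` is
`100 * mean(treated AUC)/mean(control AUC)` with a delta-method standard
error. `icx()` finds the dose at which the mean response first crosses
`100 - x` percent by linear interpolation on the dose ladder — no
four-parameter fit, matching how the screen's IC20 was chosen from a dose
ladder — and `dose_ladder()` expands an IC20 into the 25%/50%/100%
treatment doses (IC20 4 mM gives 1, 2, 4 mM). Statistical comparison of
AUCs is deliberately plain (Welch tests with Bonferroni) and flagged as a
simplification of the original ANOVA-plus-post-tests workflow.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains simulate, normalize, dssa, dosemodel, enrichment,
network and growth, writing each stage's table plus a manifest of seeds,
row counts and file hashes; identical configuration and seed give
identical hashes. Thresholds collected in `pipeline_config()` carry the
screen's conventional values: DSSA q 0.05, category p 0.01, Holm 0.05,
coverage 0.6, score cutoff 700. Every random routine takes an explicit
seed and restores the global RNG state (`withr::with_seed`), so
interleaved runs cannot perturb each other.

The shipped test and acceptance simulations use deliberately modest
problem sizes — pools of 300-2,000 strains, networks of 500 nodes, 999 to
9,999 permutations, 50-seed replications — chosen so the whole suite
completes in about a minute while keeping Monte-Carlo error well inside
the asserted bounds (binomial 99% confidence intervals at 2,000 genes,
medians over 20-50 seeds). Scaling any of them up is a matter of the
corresponding argument.

## Known limitations

* The SEPEA-style statistic and the sub-network procedure are documented
  reconstructions of methods whose exact original definitions are not
  public; they are validated by their own properties, not by equivalence.
* The loess normalization can overfit very small pools (hundreds of
  strains), inflating downstream false discoveries; use genome-scale pools
  or a larger span in that regime.
* Chi-square references for the Kruskal-Wallis statistic are conservative
  at 12/3/3/3 group sizes; rely on the permutation machinery (as the
  pathway test does) when absolute calibration matters.
* The mixed model assumes a single random chip intercept and categorical
  dose effects; no dose-response trend, random slopes, or empirical-Bayes
  variance moderation are provided.
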
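---
title: "Methods: from gel fingerprints to a phosphate-response optimum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gel fingerprints to a phosphate-response optimum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phosnet analyses the link between the solubility of a phosphate fertilizer
source (its %P2O5), the co-occurrence structure of the soil bacterial and
fungal communities around sugarcane roots, and the plant's total dry matter.
The observational unit is a pot; the community data are DGGE gel
fingerprints — each gel band acts as an operational taxon, and its intensity
in a sample's lane as that taxon's abundance signal. The experimental design
the package targets is 4 phosphate sources (Control 0%, Catalão rock
phosphate 2.93%, Bayóvar rock phosphate 14%, simple superphosphate 18%
P2O5) × with/without mycorrhizal inoculum × 4 replicate pots = 32 samples,
with a panel of 157 bands (90 bacterial, 67 fungal).

This vignette explains the statistical machinery, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the design
choices made where the protocol left room.

## Band filtering and community structure

Bands present (intensity > 0) in fewer than 25% of samples are removed
(`filter_low_frequency()`, inclusive boundary: 2 of 8 samples at the default
25% is kept). This eliminates singleton bands that would otherwise produce
degenerate correlations downstream.

Between-sample dissimilarity is Bray–Curtis,
$d(x,y) = 1 - 2\sum_i \min(x_i,y_i) / \sum_i (x_i + y_i)$. Because gel lanes
differ in total signal, each sample row is rescaled to unit sum first by
default (`normalize = FALSE` disables this; the original protocol does not
state lane normalization either way). Ordination is classical principal
coordinates (`pcoa()`): eigendecomposition of the Gower-centered matrix of
$-d^2/2$; negative eigenvalues (Bray–Curtis is non-Euclidean) are reported
but carry no coordinates. Cluster analysis is UPGMA (`upgma()`, average
linkage, exact on ultrametric input); tie-breaking among equal candidate
merges follows `stats::hclust`.

`permanova()` partitions the distance matrix by the sequential model
`distance ~ source + inoculum` — sequential because the model formula is
ordered; the default balanced design makes the order immaterial. Sums of
squares are trace increments $\mathrm{tr}(H_k G)$ over nested hat matrices
against the Gower-centered $G$; the p-value permutes sample labels freely
with the add-one estimator $(1 + \#\{F^* \ge F\})/(1 + n_\mathrm{perm})$
(9999 permutations by default, explicit seed required). When $n! \le 10{,}000$
the implementation switches to exhaustive enumeration and the p-value is
exact. The test suite checks the F, SS and R² against `vegan::adonis2` to
10 decimal places and the exhaustive p against full enumeration fed to the
same oracle.

## Dual-correlation network inference

For every pair of retained bands, `correlate_pairs()` computes Pearson's r
on intensities and Spearman's rho on midranks (ties averaged), each with a
two-sided p-value from the t transform on $n-2$ df. The t approximation is
poor at the per-source group size of $n = 8$, so with 10 or fewer samples
the p-values switch to permutation: all $n!$ sample orderings are enumerated
exactly for $n \le 8$ (40,320 orders), Monte-Carlo with the add-one
estimator otherwise. Permutations are shared across the pair panel, which
keeps each pair's p-value marginally exact at a fraction of the cost. A band
constant within the subset yields `valid = FALSE` pairs rather than an
error, and such pairs are simply never edges.

`build_network()` applies the edge rule: a pair becomes an edge iff **both**
p-values fall below `edge_alpha` (default 0.05) **and** the two coefficients
agree in sign; the edge carries that shared sign. Sign agreement is the only
rule that leaves every edge unambiguously signed; pairs where the two
statistics disagree in sign are dropped (an `edge_rule = "either"`
sensitivity mode relaxes the conjunction but keeps the sign requirement).
No multiple-testing correction is applied by default, mirroring the raw
p < 0.05 protocol; `p_adjust = "BH"` applies Benjamini–Hochberg within each
correlation's p-vector before thresholding, and exists because the raw rule
cannot control false edges over a ~12,000-pair panel (see *Recovery
benchmarks* below). All filtered bands stay in the graph as nodes whether or
not they gain edges — the distinction between the full 157-band panel
("total nodes") and degree ≥ 1 nodes ("interacting nodes") is itself a
reported quantity.

Per-group networks pool samples sharing a treatment level over the shared
filtered panel: one network per source (8 samples each) and one per inoculum
level (16 each), so every network has the same total node set.

## Topology report

`topology_report()` mirrors a column of the published topology panel:
node/edge counts, kingdom percentages among interacting nodes,
positive/negative counts and their ratio, and the kingdom partition of edges
(bacteria–bacteria, fungi–fungi, bacteria–fungi; these sum to the edge
count, as do positives + negatives — both identities are enforced by tests).
Two published columns use *different* formulas for average degree
(2E/N vs E/N) and for density (E over ordered pairs of all nodes vs of
interacting nodes), so the report always emits **both** conventions
side by side (`avg_degree_2e_over_n`, `avg_degree_e_over_n`,
`density_total_nodes`, `density_interacting`) and the configuration only
chooses which is labelled primary.

Communities come from the spinglass algorithm (`igraph::cluster_spinglass`),
run per connected component because spinglass requires connectivity;
components under 3 nodes count as single communities. The reported
modularity is Newman–Girvan modularity of the combined partition on the
interacting subgraph; the suite verifies it against a hand-rolled evaluator
and, on ≤ 8-node graphs, against exhaustive maximization over all set
partitions. Average clustering coefficient, average path length and diameter
are computed on the largest connected component (shortest-path diameter; the
published footnote for diameter repeats the path-length wording and is
treated as a typo).

## Phenotype statistics

Total dry matter is analysed by two-factor ANOVA with interaction
(source × inoculum) — the design is factorial, so this is preferred over a
one-way ANOVA on 8 cells; unbalanced data fall back to Type II sums of
squares (`car::Anova`). Normality is checked by Shapiro–Wilk and reported,
never enforced. Tukey HSD runs on the 8 cell means with the studentized
range distribution (Tukey–Kramer SE under unequal sizes) plus a compact
letter display; the significance level is a parameter because the protocol
quotes p < 0.05 in its methods and p < 0.001 in its dry-matter figure.
The colonization decline versus %P2O5 is ordinary least squares
(`linear_fit()`), with the slope p from the t distribution — checked in the
suite against an exhaustive permutation oracle at n = 6.

## Response surface and optimum

`fit_exponential()` fits one of four forms by Levenberg–Marquardt
(`minpack.lm::nlsLM`, 500 iterations, tolerances 1e-12), initialized by
profiling the conditionally-linear parameters over a grid of rate constants
(robust when log-linearization is impossible, e.g. nonpositive responses):

| form id          | model                   | parameters |
|------------------|-------------------------|-----------|
| `exp`            | $a e^{bx}$              | 2 |
| `exp_offset`     | $a e^{bx} + c$          | 3 |
| `peaked`         | $a x e^{bx}$            | 2 |
| `peaked_offset`  | $a x e^{bx} + c$        | 3 |

The family includes peaked forms because a monotone exponential cannot place
a maximum inside the dose range, while the study's reported optimum is
interior. Model selection minimizes the residual standard error
$\sqrt{SS_{res}/(n-k)}$ (the protocol's own criterion), ties to fewer
parameters. Fits use replicate-level points, not the four treatment means.
Non-convergence returns a failure object that selection skips.

`compose_surface()` evaluates the selected dry-matter fit and the
bacteria–fungi edge-count fit on a common %P2O5 grid (default step 0.01),
reports a bivariate exponential trend R², and `find_optimum()` takes the
grid argmax of predicted dry matter (ties to the smallest dose). With a
noise-free generating curve the located optimum lands within one grid step
of the analytic argmax $-1/b$.

A caveat the user should know: at realistic noise the RSE criterion is
genuinely ambiguous between a peaked curve and a saturating monotone one —
on default synthetic data about three quarters of seeds recover an interior
optimum near 11% P2O5 and the rest select a monotone form whose argmax is
the upper dose bound. This instability is a property of per-dataset RSE
selection, not of the optimizer.

## The synthetic-data generator

No raw gel data are deposited for this study, so `generate_study()` creates
a synthetic counterpart and is itself first-class, tested code. Its defaults
*are* the study conditions: 32 pots (4 × 2 × 4), 157 bands (90 + 67),
colonization intercept 43% with slope −1.5 per %P2O5 (reproducing the
printed means of 43% at the control and 16% at 18% P2O5), and a dry-matter
curve equal to the study's fitted response (peaked with maximum 6.57 g/pot
at 11.09% P2O5 over an offset of 2.2 g), with noise sized so the
replicate-level fit explains roughly two thirds of the variance. The
dry-matter curve deliberately follows the study's *fitted* curve rather than
its observed treatment means (~12 g), which the study's own predicted
maximum contradicts; the package treats the fitted curve as the quantitative
statement of record.

Band intensities use a latent Gaussian copula. Each planted edge
$(i, j, \text{sign}, w)$ gets a shared standard-normal factor $F$:

$$\log x_i = \mu_i + \sigma\,(\sqrt{w} F + \sqrt{1-w}\,\varepsilon_i),$$

with band $j$ loading on $F$ with the edge's sign, so the log-scale
correlation is exactly $\pm w$, monotone, and hence visible to both Spearman
and Pearson after exponentiation. Treatment structure enters as per-band
random offsets by source (both kingdoms) and by inoculum (bacterial bands
only, echoing the finding that inoculation restructured the bacterial but
not the fungal community); a Bernoulli presence mask (default 10%) creates
the zero inflation that exercises Spearman's tie handling. The default
45 planted edges are vertex-disjoint at strength 0.8, so no correlation is
induced between bands that do not share an edge.

Two defaults deserve their rationale. The lognormal log-scale SD is 0.35:
lognormal marginals attenuate *negative* Pearson correlations asymmetrically
($(e^{-w\sigma^2}-1)/(e^{\sigma^2}-1)$; a −0.8 latent correlation realizes
only −0.64 at σ = 1), and larger σ would defeat the construction's purpose
of making planted dependence detectable by both coefficients. The treatment
offset SDs (0.55/0.6 by source, 0.6 for bacterial inoculum) are calibrated
so PERMANOVA attributes roughly 36% (bacteria) and 45% (fungi) of
Bray–Curtis variance to the source — the scale the study reports — with a
significant bacterial but non-significant fungal inoculum term. A caveat:
an additive partition cannot simultaneously assign ~39% to source and ~41%
to a one-df inoculum term as the published percentages suggest; the
generator reproduces the source share and the significance pattern, not
that arithmetic.

What the generator does **not** emulate: gel electrophoresis physics
(co-migration of distinct taxa into one band, saturation, lane warping),
primer or abundance bias, compositional closure of real profiles, and
taxon-specific dose-response shapes. Passing recovery tests on this
generator therefore demonstrates the inference machinery is correct under a
clean monotone-dependence model — not that the dual-correlation protocol
would recover true interaction networks from real gels.

## Recovery benchmarks

The planted-edge benchmark runs the network stage on generator output with
treatment offsets and zero-inflation off (pure planted correlation,
strength 0.8, n = 32) and Benjamini–Hochberg edge calling, and requires
precision and recall ≥ 0.9 averaged over 20 seeds. Raw p < 0.05 cannot meet
this precision bar on any realistic panel: ~12,000 null pairs at a joint
dual-test false-positive rate of a few percent produce hundreds of false
edges against 45 planted ones. That arithmetic is why the BH mode exists;
the default pipeline keeps the raw rule for fidelity to the protocol.

## Problem sizes and numerical choices

Simulation-based tests run at the study's own scale (32 × 157) with seed
loops of 20–100; permutation-heavy checks use 99–999 permutations except
where exhaustive enumeration applies, and the null-calibration check uses
two groups of 6 so the permutation p-distribution is fine-grained enough to
measure type-I error meaningfully. Correlation permutation tests enumerate
all 40,320 orders at n = 8. Comparisons against oracles use 1e-10..1e-12
tolerances for deterministic algebra and binomial-width bands for
Monte-Carlo quantities. Degenerate inputs are contracts, not crashes:
constant bands → invalid pairs; constant responses → mean fits with R² = 0;
all-zero samples → an explicit undefined-distance error; empty pair lists →
empty networks.
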
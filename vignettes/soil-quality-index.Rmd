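---
title: "Methods: the composite soil quality index and its companion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the composite soil quality index and its companion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqiome)
```

This vignette is the package's own account of what it computes and why
the open design choices were made the way they were. The running
example is a 4-treatment (bare control CK; tall wheatgrass GF; chicory
JA; alfalfa CP) × 3-replicate revegetation trial on severely
saline–alkaline soil, with six chemistry indicators (SOM g/kg, AN, AP,
AK mg/kg, pH, EC mS/m) and paired bacterial/fungal OTU tables.

## 1. The index

### Membership functions

Each indicator is rescaled to [0, 1] over the entities being compared
by a min–max membership function, ascending for "more is better"
indicators and descending for "less is better":

$$F(x_i) = \frac{x_{ij} - x_{i\min}}{x_{i\max} - x_{i\min}}
\qquad\text{or}\qquad
F(x_i) = \frac{x_{i\max} - x_{ij}}{x_{i\max} - x_{i\min}}.$$

On saline–alkaline soil the nutrients (SOM, AN, AP, AK) and the
diversity indices (Chao1, Shannon, per domain) ascend; pH and EC
descend, because the soil improves as alkalinity and salinity fall.
`default_directions()` encodes this; any direction map can be passed
instead. Flipping a direction maps $F \mapsto 1-F$ exactly.

Degenerate indicators (max = min over the entities) cannot rank
anybody; they are set to the neutral membership 0.5 with a warning, so
they shift every entity equally and can never reorder the ranking.
This is the continuity-preserving choice; dropping the indicator
outright would change the weight normalization discontinuously.

### PCA factor-loading weights

`pca_weighting()` standardizes the entity × indicator table and
eigendecomposes its correlation matrix. Component $j$ carries a
variance contribution rate $K_j = 100\,\lambda_j/\sum\lambda$ (%).
Loadings follow the factor-loading convention, eigenvector ×
$\sqrt{\lambda_j}$ (a raw-eigenvector mode exists for sensitivity
analysis; because the weights take absolute values and normalize
within a component, the two conventions coincide there — the scaling
cancels). Within each component the absolute loadings $C_i$ give
weights $W_i = C_i / \sum_i C_i$, so $\sum_i W_i = 1$ per component.
Weights are per-component ($W_{ij}$): the loading of indicator $i$ *in
a certain principal component* is what gets normalized, which is the
only reading under which all retained components' loadings matter.

Eigenvector sign is immaterial (absolute values); for determinism the
largest-magnitude entry of each eigenvector is made positive. A
component with $\lambda = 0$ has no loadings to weight; it receives
uniform weights (and contributes $K_j = 0$, so it cannot affect the
index) purely to keep the $\sum_i W_i = 1$ invariant.

### Aggregation

$$\mathrm{SQI} = \sum_{j=1}^{m} K_j \Big\{ \sum_{i=1}^{n} W_{ij}\,F(x_i) \Big\}$$

with $K_j$ in percent. With all memberships at 1 the index attains
exactly $\sum_{j \le m} K_j \le 100$, which is what puts treatment
scores on the familiar 0–100 scale; this bound is tested exactly.
$m = 4$ components are retained by default (a cumulative-contribution
threshold can be used instead; $m$ is clamped to the number of
indicators). Entities are ranked by descending SQI; exact ties share
order by label and are flagged.

Because memberships are min–max normalized and the PCA operates on the
correlation matrix, the whole pipeline is invariant under positive
affine transforms of any indicator column — changing the unit of AK
from mg/kg to g/kg cannot change anyone's score. This is tested at
1e-9.

### Entity mode

Whether the membership extremes and the PCA are taken over the four
treatment means (default) or over the twelve replicate samples is
genuinely open; both are first-class (`entity_mode = "treatment"` /
`"sample"`) and the result records which was used. Treatment-means
mode is the default because the index is reported per treatment; note
that with 4 entities the correlation matrix has rank ≤ 3, so the
fourth component carries $K_4 = 0$ and the first three components
explain everything. Sample-level mode is what feeds the
distance-vs-SQI regression, which needs a score per sample.

Which alpha indices enter the index is configurable
(`alpha_metrics`, per domain); the default uses Chao1 and Shannon of
both bacteria and fungi, giving 6 chemistry + 4 diversity indicators.

## 2. Chemistry statistics

Treatment summaries report the sample mean and the $n-1$ sample sd
(the convention behind "±" in field-trial tables). Treatment effects
use classical one-way fixed-effects ANOVA, $F = MS_b/MS_w$ on
$(k-1, N-k)$ df. With one observation per treatment × replicate cell,
a model with treatment and replication effects has no replication
information beyond this at the treatment level, so one-way ANOVA is
the estimable equivalent; no REML machinery is used. Zero
within-group variance is reported as degenerate rather than an error
($p = 0$ if means differ; $F = 0, p = 1$ if everything is identical).

Pairwise comparisons use Tukey HSD via the studentized-range
distribution (Tukey–Kramer under unequal $n$, as provided by
`stats::TukeyHSD`). The compact letter display is computed as the
maximal cliques of the non-significance graph, ordered so "a" marks
the largest mean. This realizes the letter semantics exactly: two
treatments share a letter if and only if their pairwise adjusted
$p \ge \alpha$ — a property the test suite checks against the raw
pairwise tests.

Percent and fold changes are computed from treatment means
($100(\bar x_n - \bar x_d)/\bar x_d$ and $\bar x_n/\bar x_d$), so
`fold = 1 + pct/100` holds to 1e-9 and reciprocal folds multiply to 1.
When published percent-change statements disagree with the published
mean table they were derived from, the package computes from the means
and leaves the reconciliation to the analyst.

## 3. Community statistics

* **Alpha diversity.** Observed OTUs; bias-corrected Chao1
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (defined even when no doubletons
  exist); Shannon in natural log (the common default in ecology
  toolkits; base configurable); Pielou $H/\ln S_{obs}$, defined as 0
  for a single-OTU sample.
* **Bray–Curtis** on relative abundances by default, so library size
  does not masquerade as turnover; a raw-count mode exists. No
  rarefaction by default.
* **PCoA** by eigendecomposition of the Gower-centered $-d^2/2$
  matrix. Negative eigenvalues are excluded from both the coordinates
  and the explained-variance denominator; no Lingoes/Cailliez
  correction is applied by default. On distances that are exactly
  Euclidean the embedding round-trips the inputs at 1e-9.
* **RDA** regresses Hellinger-transformed relative abundances on
  standardized indicators (vegan); the headline number is the total
  constrained fraction of inertia. Collinear indicators are dropped
  deterministically with a warning.
* **Mantel tests** use the Pearson correlation of lower-triangle
  entries and a seeded one-sided (positive association) permutation
  of one matrix's labels, $p = (1 + \#\{r^* \ge r\})/(B+1)$, $B = 999$
  by default — the conventional reporting choice. Type-I calibration
  is tested.
* **Spearman panels** collapse to a rank (genus by default), keep the
  top-$n$ taxa by mean relative abundance, and use average-rank ties
  with the two-tailed $t$ approximation. The statistic is invariant
  under strictly monotone transforms of either variable.
* **Distance-vs-SQI regression.** How to regress community distance on
  soil quality is genuinely open. The default reading regresses
  pairwise Bray–Curtis on pairwise $|\Delta \mathrm{SQI}|$ with
  Mantel-style permutation inference (pairs share samples, so OLS
  p-values would be anticonservative); an alternative reading —
  per-sample distance to the control centroid against the sample's own
  SQI — is implemented as `mode = "to_control"`. Neither is asserted
  as canonical.

## 4. Co-occurrence networks

Top-abundance OTUs (100 per domain by default; "top 100 bacterial and
fungal OTUs" is ambiguous between per-domain and combined, so both are
selectable; ties at the boundary break lexically by OTU id) are
correlated pairwise (Pearson, on relative abundances; raw mode by
flag). Two-tailed $p$ comes from $t = r\sqrt{n-2}/\sqrt{1-r^2}$; an
edge requires $|r| > 0.9$ **and** $p < 0.05$, both strict. No
multiple-testing correction is applied by default because the
threshold pair is the field's stated rule; a BH-FDR mode exists.

The topology panel: links by sign, average degree $2E/V$, density
$2E/\binom{V}{2}$, Louvain modularity of the unweighted unsigned graph
(seeded, hence reproducible), mean local clustering coefficient with 0
for degree < 2, and mean shortest-path length over connected ordered
pairs (the common convention in graph toolkits; harmonic/giant-component
variants would be alternatives).

With only 3 samples in a treatment, $p < 0.05$ already requires
$|r| \ge 0.997$, so per-treatment networks at the default thresholds
are near-vacuous at $n = 3$; the function emits a loud caveat rather
than an error, and a pooled all-sample network is built alongside.

## 5. The scenario simulator

`scenario_spec()` + `generate_scenario()` emulate the trial's
statistical structure, not its biology:

* **Chemistry**: each replicate draws each indicator from a normal law
  with the treatment's (mean, sd); defaults are the trial's published
  treatment means and sds. Draws outside the physical domain
  (non-positive concentrations, pH outside (0, 14)) are *resampled*,
  not clipped — clipping would bias the means the downstream tests
  compare against. sd = 0 degenerates to exact means.
* **Communities**: per sample, counts are Dirichlet-multinomial around
  a treatment-level expected composition. The Dirichlet concentration
  is parameterized per taxon (total mass = `concentration` × number of
  active OTUs, default 50), giving mild overdispersion beyond the
  multinomial; a total-mass-50 reading would inject so much noise that
  planted correlation structure could not survive to the abundance
  scale.
* **Richness** is controlled by support size: treatment $t$ activates
  `round(n_otus_base × multiplier[t])` OTUs. Chao1 responds to support
  size, so realized Chao1 fold-changes vs the control track the
  multipliers; the defaults encode the published increases (bacteria
  +50.43/55.09/45.24 %, fungi +118.07/138.91/136.95 % for GF/JA/CP).
  Library sizes default to the study's mean per-sample depths (46,026
  16S reads; 68,464 18S reads), at which detection is near-complete
  and the realized fold-changes sit within a few percent of target.
  Shannon rises with the multipliers as a side effect; the simulator
  does **not** calibrate Shannon or evenness to any published value.
* **Composition**: OTUs carry a fixed phylum assignment (interleaved
  so any prefix of the pool keeps the phylum mix); per treatment,
  within-phylum masses are rescaled to the treatment's target profile.
  The published per-treatment percentages for the four dominant
  bacterial phyla are not jointly consistent as compositions (they sum
  to 67–118 %), so the defaults complete them with an "Other" fraction
  floored at 5 % — minor phyla are reported present everywhere — and
  renormalize. Full fungal per-treatment compositions are not
  published; the defaults are fixed profiles honoring the qualitative
  ordering (Ascomycota dominant everywhere but reduced under plants;
  Mortierellomycota peaking under chicory; Basidiomycota under tall
  wheatgrass).
* **Planted correlation blocks**: each block shares one latent
  Gaussian factor added on the log-abundance scale; `sign =
  "positive"` loads all members alike, `"negative"` alternates signs.
  The loading is $\sigma_b\sqrt{\rho/(1-\rho)}$ against a residual
  scale $\sigma_b = 0.1$: keeping the absolute scale small keeps
  $\exp(\cdot)$ near-linear, so the latent correlation $\rho$ survives
  onto the abundance scale. Block OTUs get a baseline log-abundance
  boost so they are well sampled. One structural limit is worth
  knowing: for lognormal abundances the Pearson correlation of an
  anti-loaded pair is bounded by $-e^{-\lambda^2}$, and the
  loading/noise tradeoff caps attainable negative $|r|$ around 0.87 —
  below the 0.9 edge threshold. Strongly negative edges in real (and
  default-scenario pooled) networks come from treatment-level
  composition gradients instead; the test suite therefore checks
  *sensitivity* on positive blocks at $\rho = 0.99$ (above the
  detection boundary) and *sign recovery* at a permissive threshold
  where both signs are detectable.
* **Seeding**: one integer seed; every stage derives its stream by a
  fixed offset, so end-to-end runs are byte-identical under a fixed
  seed (tested).

What the simulator does **not** emulate: read-level artifacts
(chimeras, primers), phylogeny, spatial autocorrelation between plots,
taxon–taxon interactions beyond the planted blocks, and any real
taxonomic identity below phylum (genus labels are synthetic). Passing
tests on this generator therefore demonstrate that the *procedures*
are correct and that the pipeline recovers structure it is known to
contain — not that the field study's specific biological conclusions
would be recovered from raw reads.

## 6. Problem sizes and tolerances

The test suite runs the rank-recovery check on 100 generated scenarios
(4 × 3 samples, 300 bacterial / 150 fungal base OTUs at the study's
depths), the ANOVA calibration on 10,000 null simulations, the Mantel
calibration on 1,000 null pairs with 99 permutations each, Chao1
against brute force on 1,000 random samples, and network recovery
on pooled 12-sample scenarios with 300 OTUs — sizes chosen so the full
suite completes in well under a minute per family while keeping Monte
Carlo error far from the asserted bounds. Exact identities (membership
endpoints, weight sums, the all-ones SQI bound, PCoA round-trips,
affine invariance) are asserted at 1e-9; statistical rates at the
intervals stated in the tests.

## 7. Known limitations

* Exact published index values for the original trial are not
  reproducible from published information alone (the PCA loadings and
  the absolute diversity values behind them are not printed); the
  reproducible surface is the procedure and the treatment ranking, and
  that is what is tested.
* The compact-letter display is exponential in the worst case
  (maximal clique enumeration) — irrelevant at field-trial sizes but
  not meant for hundreds of groups.
* Louvain modularity is seed-stable but not canonical; different
  seeds may give slightly different partitions on large graphs.
* `per_treatment_networks` at $n = 3$ replicates is reported with a
  caveat, not suppressed: the thresholds make such networks unstable,
  and pooling across treatments (also provided) is usually the better
  reading.
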
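---
title: "Methods: models, parameters and design choices in woundarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in woundarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundarray)
```

# The experimental design

woundarray analyzes a four-condition one-channel microarray design built
around wound healing in *Drosophila* wing imaginal discs.  Healing-engaged
cells activate JNK signaling (reported by a *puckered* enhancer), so four
cell populations can be sorted and profiled: JNK-positive and JNK-negative
cells from wounded discs (`JNK+W`, `JNK-W`) and from non-wounded discs
(`JNK+`, `JNK-`), each in replicate (three arrays per condition by
default; 12 arrays in all).

Three contrasts over the per-gene condition means $\mu_{g}$ carry the
biology:

* $W = \mu_{JNK+W} - \mu_{JNK-W}$: the JNK+/JNK- difference in wounded
  discs;
* $NW = \mu_{JNK+} - \mu_{JNK-}$: the same difference in non-wounded
  discs;
* $D = W - NW$: the interaction, i.e. how the JNK+/JNK- difference itself
  changes upon wounding.

Two derived per-population contrasts, `dJNKpos` $= \mu_{JNK+W} -
\mu_{JNK+}$ and `dJNKneg` $= \mu_{JNK-W} - \mu_{JNK-}$, say *which*
population moved between disc states; they drive the subset
classification.

# Preprocessing

`nonspecific_filter()` removes low-signal and low-variability probes on
the **linear** intensity scale: a row survives iff (a) it exceeds 40
intensity units (strict `>`) in at least 25% of samples (`>=`), and (b)
its inter-quartile range strictly exceeds the 10th percentile of the
distribution of row IQRs.  The last clause is the only self-consistent
reading of "IQR larger than the 10% percentile": an IQR is compared
against a quantile of IQRs, not of intensities.  The filter runs before
normalization, on raw intensities; this ordering is configurable but is
the default because the thresholds are stated in raw units.

`quantile_normalize()` forces every array onto the common reference
distribution (the across-array mean of sorted values).  Ties receive the
mean of the reference values at the tied ranks — the standard dialect —
which keeps the transform rank-preserving and idempotent.

`summarize_probesets()` collapses probes to probe sets by Tukey median
polish (at most 10 sweeps or a 1e-6 tolerance), reporting overall + column
effect per sample — the robust summarization RMA uses.  The full
RMA background correction is out of scope: the pipeline starts from an
intensity matrix.

# The moderated t model

Per gene the cell-means model gives four condition means, a pooled
residual variance $s_g^2$ on $d_g = n - 4$ degrees of freedom.  Variances
are shrunk by empirical Bayes toward a prior $s_0^2$ with $d_0$ degrees of
freedom:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  \tilde t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{v_c}},$$

with $v_c = \sum_j c_j^2 / n_j$ the contrast's unscaled variance, and
two-sided p-values from a Student t on $d_0 + d_g$ df.  The prior is
estimated by the method of moments on $\log s_g^2$ (digamma/trigamma
equations, Newton inversion of the trigamma function); when the empirical
spread of $\log s_g^2$ does not exceed its pure-sampling value the prior
is degenerate ($d_0 = \infty$) and $s_0^2$ is the pooled mean variance.
The limits are exact: $d_0 = 0$ recovers the classical t, $d_0 = \infty$
a fixed-variance z statistic; both are asserted to machine precision in
the tests, and the whole path is cross-checked against the limma
implementation as an independent oracle.

The log-odds (B) statistic uses the two-component prior: with prior
probability `prior_de` a gene's contrast effect has additional unscaled
variance $v_0$.  With $r = (v_c + v_0)/v_c$,

$$B = \log\frac{\pi}{1-\pi} - \tfrac12\log r
      + \frac{1+df}{2}\,\log\frac{\tilde t^2 + df}{\tilde t^2/r + df},$$

monotone in $|\tilde t|$ at fixed df.  $v_0$ is nowhere stated by the
analysis regime this package reimplements, so `v0 = "auto"` uses a simple
moment estimate from the top `prior_de` fraction of $|\tilde t|$:
$\hat v_0 = \max(\overline{\hat\beta^2/\tilde s^2} - v_c,\ v_c)$ over
those genes.  It affects only the B ranking's scale, never the ordering
in $|\tilde t|$ at fixed df, and is documented rather than asserted.

Multiplicity is controlled by the Benjamini–Hochberg step-up, implemented
directly from the definition and verified against a literal brute-force
min-over-tails oracle.

## Selection regimes

Thresholds mirror the published regimes: the *global* comparison selects
at $|FC| \ge 2$ (or 1.5 relaxed) with **raw** p < 0.05; the *dual*
comparisons at $|FC| \ge 1.3$ with **FDR-adjusted** p < 0.05.  Fold
change is the signed linear ratio $\mathrm{sign}(\hat\beta)\,
2^{|\hat\beta|}$; the FC cut uses `>=`, the p cut strict `<`.

# Set logic and subset classification

Membership in the W, NW and D subpopulations uses the dual regime; the
three booleans define seven non-empty Venn regions.  Two sets get special
names: **WO** (in W and D but not NW — wound-specific response) and
**W/NW/D** (in all three — responding in both disc states, but
differently).

Subsets are assigned from the sign pattern of the per-population
contrasts, where a sign is declared only when the contrast passes the same
FC/alpha rule as membership (the source tables never state their
significance rule for the +/−/0 codes; tying it to the membership rule is
the one choice that makes the codes reproducible from the published
thresholds).  WO genes: `1A` (up in JNK+), `1B` (down in JNK−), `2A`
(down in JNK+), `2B` (up in JNK−), systematic `C:<s+><s−>` codes when
both populations moved, `other` when neither sign is declared.  W/NW/D
genes: autonomous codes `A1`–`A6` when only JNK+ moved, mirrored
`B1`–`B6` when only JNK− moved, from the signs of $\hat\beta_W$ and
$\hat\beta_{NW}$ and, at equal signs, the order of their magnitudes
(point estimates; D-significance guarantees they differ detectably).
Complex codes are generated, not hard-coded: the published inventories
(9C/15C) are observed samples of the combinatorial space, not its
definition.

**Power note.** The interaction contrast D has unscaled variance
$v_D = 4/n_r$ — twice that of W or NW — so recovering a planted subset
label requires clearing the FC *and* FDR thresholds on D.  At noise SD
0.25 and 3 replicates, a 2-fold planted change ($\beta = 1$) is only
~85% powered for D-membership; the recovery tests therefore plant
$\beta = 1.5$ (6x the noise SD, still within the generator's stated
1.3x–8x fold-change world).  This is a property of interaction testing,
not of the implementation.

# Template-matching clustering

Genes significant (FDR p < 0.05) in at least one of W/NW/D are
discretized: a 4-condition profile whose range is below `flat_eps = 0.5`
log2 units is flagged flat; otherwise it is min–max scaled and binned
into thirds (half-open edges).  The 3^4 = 81 level-vector templates are
enumerated in lexicographic order; the three constant templates are
degenerate (zero variance — Pearson correlation against them is
undefined) and excluded from matching.  A gene joins the template
maximizing squared Pearson correlation when $R^2 > 0.95$ (strict), ties
to the lexicographically smallest id.

Two caveats are inherent to the stated method and documented here rather
than hidden:

* **Affine degeneracy.**  $R^2$ cannot distinguish templates related by
  an affine map or reflection (e.g. `1.1.2.2`, `2.2.3.3` and `3.3.2.2`
  correlate at $|r| = 1$ with exactly the same profiles).  The matcher's
  tie-break makes assignments deterministic (the class's lexicographic
  representative), and the synthetic generator plants only such canonical
  representatives (`canonical_templates()`), so planted labels are
  recoverable.  Recovery tests count a gene as recovered when its
  assigned template lies in the planted template's $|r|=1$ class.
* **Continuous vs discretized matching.**  Whether the original analysis
  correlated templates with continuous means or with replicate-expanded
  values is unstated; both modes are provided (`use_replicates`), the
  continuous-means mode is the default, and neither is asserted as "the"
  published variant.

The discretization rule itself (per-gene min–max scaling, equal thirds,
`flat_eps` = 0.5 log2 units) is this package's choice: the source names
only the three levels.

# Positional clustering

Regulated genes are mapped to chromosome arms (first transcript per gene;
0-based half-open coordinates; BED6 and UCSC refGene are both read).  For
each arm and direction a window of `window_genes = 10` consecutive genes
(counting *all* annotated genes) slides along the arm; windows holding at
least `min_de = 3` co-directional regulated genes seed a cluster, and
overlapping/adjacent seed windows merge into maximal clusters — groups of
neighboring, not necessarily consecutive, co-regulated genes.  Up- and
down-regulated sets are clustered separately, and clusters never mix
directions, per the definition of a cluster as genes with the same
expression behavior.  Window size and the membership minimum are nowhere
stated by the source analysis; 3-in-10 is the package default and both are
exposed.

Significance is empirical: `expected_clusters()` redraws `n_rand = 100`
random directed sets preserving the observed set's size, per-arm counts
and up/down split (stratified within arms — the strict reading of "same
size and chromosomal gene distribution"), re-runs the finder, and reports
$p = (1 + \#\{\text{rand} \ge \text{obs}\})/(n_{rand}+1)$ — the add-one
convention that avoids zero p at finite n.  Arm-level enrichment uses the
exact hypergeometric tail plus a 1000-draw empirical check.  The cluster
finder is verified against a brute-force window-scan oracle on random
arms, and the hypergeometric tail against exhaustive draw enumeration for
all population sizes up to 12.

# GO enrichment at level 3

An OBO 1.2 parser builds the is_a DAG (cycles rejected; every term must
reach exactly one namespace root); a term's level is 1 + the minimum is_a
path from its root, the convention of the era's tooling, with `part_of`
edges ignored.  Annotations are projected up to level-3 ancestors (a
level-3 term projects to itself, shallower terms to nothing), and each
level-3 term is tested by the hypergeometric upper tail
$P[X \ge k]$ with the **annotated** filtered gene population as the
universe (the source is silent on the universe; `annotated` is the
default and `all` is available).  Enrichment p-values are reported raw
(p < 0.01 for the global set, p < 0.05 for WO and W/NW/D), matching the
published reporting; BH adjustment is available but off by default.
Level-3 projection is applied uniformly per namespace — the source
annotates "at level 3 of the molecular function tree" yet reports BP and
CC enrichments too, so a uniform rule is the only consistent
generalization.

# The synthetic world

Because the study's microarray data were never deposited, every stage is
validated against `simulate_dataset()`, whose defaults state the
emulated world once: 4 conditions x 3 replicates; baseline log2
intensities Normal(8, 1.5) (a typical microarray dynamic range; the
source gives none); i.i.d. Normal(0, 0.25) replicate noise on the log2
scale with an optional per-array shift (off by default) to exercise
quantile normalization; planted fold changes uniform in 1.3x–8x; five
arms (X, 2L, 2R, 3L, 3R) with near-even gene counts, intergenic gaps
Uniform(100, 10000) bp and gene lengths Uniform(500, 20000) bp; planted
runs of co-directional genes at consecutive genome slots; planted
canonical 4-condition level profiles; and a molecular-function ontology
DAG of depth >= 5 whose designated level-3 term annotates planted-DE
genes at a 0.5 rate versus 0.05 background.

Two structural notes:

* The Venn regions significant in exactly one contrast (`W` only, `NW`
  only, `D` only) are only *realizable* when the other components stay
  below the threshold; since $D = W - NW$, this forces their planted
  fold changes into $(fc_{cut}, fc_{cut}^2)$ regardless of `fc_range`.
  That is arithmetic, not tuning.
* Planted clusters and template genes are carved out of the
  `de_fraction` budget, so `de_fraction = 0` plants nothing anywhere.

What a green test does establish: calibration of the null (uniform
p-values, KS at alpha 0.01), >= 90% recovery of planted 2-fold effects at
the relaxed global regime, >= 95% recovery of planted template classes at
low noise, detection of a planted 5-gene cluster against a sparse
background, and exact agreement with enumeration/brute-force oracles.
What it does not: anything about probe-level artifacts, array batch
structure beyond a global shift, correlated noise between genes, or the
real study's gene counts — those depend on data that no longer exist.

The positional-cluster power experiment deserves a note on its stated
world: the null probability of a chance 3-in-10 run grows quickly with
the density of the directed set (at 15% DE a window is "significant" by
chance ~18% of the time), so the detection experiment uses a sparse
directed set (2000 genes, 1% DE, one planted 5-gene run).  An earlier
draft used 2% DE, under which chance runs appear in ~10% of null draws
and the count-based empirical p cannot reach 0.05 reliably — a property
of the count statistic, recorded here for honesty.

# Numerical conventions

* Strict `>` for the 40-unit intensity and the IQR percentile; `>=` for
  the 25% sample fraction and FC cuts; strict `<` for all p cuts and the
  $R^2$ threshold.
* Contrast SEs treat zero posterior variance as exact: $\beta = 0$ gives
  $t = 0$, $p = 1$; nonzero $\beta$ over zero SE gives signed infinity.
* Empirical p-values always use the add-one convention.
* All randomness flows from explicit seeds; fixed seed means
  bit-identical output for every generator and permutation test.

# Known limitations

* The pipeline starts from an intensity matrix; CEL-level background
  correction and mismatch-probe handling are out of scope.
* The B statistic's `v0 = "auto"` is a pragmatic estimator, not the
  limma `tmixture` machinery; B values are comparable within a run, not
  across packages.
* Template matching inherits the $R^2$ degeneracies described above; 78
  non-degenerate templates collapse into fewer identifiable classes.
* Positional clustering assumes a total gene order per arm; overlapping
  loci are ordered by start and never split.
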
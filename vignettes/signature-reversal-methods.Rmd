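---
title: "Methods: connectivity scoring and cross-species reversal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity scoring and cross-species reversal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`revsig` implements a desk-scale version of a two-armed analysis that is
common in transcriptomic drug repurposing for inflammatory liver disease
(NASH) and similar indications:

1. **Prediction.** A disease state is summarized as a *directional
   signature* — paired lists of the most up- and most down-regulated
   features. Compound-induced expression profiles (robust z-scores over
   a 978-feature landmark space, as produced by L1000-style assays) are
   scored against the signature with a weighted Kolmogorov–Smirnov
   connectivity statistic; a compound whose profile significantly
   *opposes* the disease signature (negative score) is an inverse
   connectivity hit and a repurposing candidate.
2. **Validation.** In a three-group animal experiment
   (healthy / disease / treated), differential expression is computed
   for the disease-vs-healthy and treated-vs-disease contrasts. The
   model's disease signature is compared with a human disease signature
   through an ortholog map (directional concordance), treatment
   reversal of the human signature is tested the same way, per-pathway
   percent reversal is quantified, and the histology (NAFLD activity
   score), qPCR (comparative Ct) and group-comparison statistics of the
   accompanying in-vivo endpoints are computed.

Everything operates on validated in-memory types (`ExpressionMatrix`,
`DEResultTable`, `DirectionalSignature`, `OverlapResult`, ...) with
plain-text interchange formats (TSV, GMT, GRP, JSON, YAML). Gene
identifiers are opaque, case-sensitive strings; cross-species joins only
ever happen through an explicit `ortholog_map()`, because silent symbol
case-folding corrupts exactly the joins this analysis depends on.

## The connectivity score

Features are ranked by z-score descending (ties broken by feature id so
results are platform-independent). For an arm with $t$ members among
$n$ features, the running sum after rank $k$ is

$$D(k) = \frac{\#\{\text{members} \le k\}}{t} -
         \frac{k - \#\{\text{members} \le k\}}{n - t},$$

and the arm's enrichment $ES$ is $D$ at the position of maximum $|D|$.
The connectivity score is $(ES_{up} - ES_{down})/2$ when the two arms'
enrichment signs differ and $0$ otherwise, giving a score in $[-1, 1]$:
positive when the profile mimics the signature, negative when it
opposes it. Three numerical choices matter:

* Deviations are compared in exact integer arithmetic (common
  denominator $t(n-t)$), so the decision between the positive and
  negative extreme never depends on floating-point rounding.
* When the extreme positive and negative deviations tie exactly, the
  arm's $ES$ is 0 — the only value consistent with the score's exact
  antisymmetry under ranking reversal, which the test suite checks.
* The score has an **atom at zero**: under a null (random) profile the
  two arms' enrichment signs agree with probability about one half, and
  the score is then 0 by definition. Consequently the permutation
  p-value of the KS score is valid (its false-call rate is at most the
  nominal level) but *not* uniformly distributed — it has matching mass
  at $p = 1$. A Spearman scorer restricted to signature members
  (`method = "spearman"`) is provided both as a sensitivity analysis —
  the literal "inverse correlation" reading of connectivity — and as
  the continuous scorer for which permutation p-values are exactly
  uniform; the test suite checks uniformity with it and validity with
  the KS scorer.

The permutation null re-draws random arms of the observed sizes from
the profile's feature space; $p = (1 + \#\{|s^*| \ge |s_{obs}|\}) /
(n_{perm} + 1)$, two-sided because direction is assessed separately by
the score's sign. Because the score is rank-based, this null depends
only on the feature count and arm sizes, so `screen_collection()`
computes one shared null per screen instead of one per compound; this
makes screens linear in collection size at no statistical cost (the
compound p-values share a null sample and are therefore slightly
dependent, which BH tolerates).

**Screen size and permutation resolution.** With $B$ permutations the
smallest attainable p-value is $1/(B+1)$, so after BH adjustment across
$m$ compounds the smallest attainable adjusted p is $m/(B+1)$. At the
default $B = 499$ and $\alpha = 0.05$ an inverse call is only possible
when $m \le 25$; the simulator's default collection size (20) is chosen
inside that bound. For larger screens, raise `n_perms` proportionally.

## Differential expression stand-in

The DE stage is a deliberately simple, self-contained stand-in, because
externally produced DE tables (from any engine) are accepted as
first-class inputs: counts are normalized by median-of-ratios size
factors (per-sample median of count over gene-wise geometric mean,
restricted to genes positive in all samples, rescaled to geometric mean
1), shifted by a pseudocount of 1 (defined behavior at zero counts),
log2-transformed, and tested per gene with a Welch t-test; p-values are
BH-adjusted. Genes with all-zero counts get $p = p_{adj} = 1$ and
log2FC 0 so the table stays complete for universe accounting. This
stand-in makes no attempt to reproduce the gene tallies of a
negative-binomial Wald engine; it exists so the pipeline's set
constructions, overlap tests and reversal quantification can be
exercised end-to-end with known ground truth.

Signature construction defaults follow the standard practice the
pipeline emulates: 250 genes per arm for cross-species RNA-seq
signatures, 500 per arm for compound-screen (CMAP-style) disease
signatures, and threshold sets at $|log2FC| \ge \tau = 0.5$ with
inclusive comparisons. Zero log2FC genes enter neither arm (zero is
neither positive nor negative); top-N ties break by ($|$value$|$
descending, id ascending). Genes filtered before testing (missing
adjusted p) never enter signatures or threshold sets. Robust z-scoring
uses $z = (x - \mathrm{median}) / (1.4826 \cdot \mathrm{MAD})$, the
standard normal-consistent scaling.

## Cross-species overlap tests

The concordance and reversal tests build a 2×2 table over the declared
universe — genes measured in *both* studies and mappable 1:1 (anything
larger inflates the both-absent cell and the odds ratio). Many-to-many
orthologs are handled by an explicit policy: `one2one_only` (drop every
gene involved in a multi-mapping; default) or `first_alphabetical`.
The p-value is the exact hypergeometric tail (`greater` by default —
enrichment; `two_sided` by flag); the odds ratio is the plain sample OR
$ad/bc$ with a Haldane 0.5 correction iff any cell is zero, matching
how such ORs are conventionally reported to one decimal, rather than
the conditional-MLE estimate some software prints.

**Calibration, and why exact tests run conservative here.** Under a
true independence null the rejection rate of an exact conditional test
is at most the nominal level, for two reasons that both apply to gene
lists:

1. discreteness — $P(p \le \alpha) < \alpha$ strictly;
2. heterogeneous inclusion probabilities — under negative-binomial
   counts the log-fold-change noise variance depends on a gene's
   baseline mean, so lowly expressed genes are more likely to enter
   *any* threshold set. Even when the two lists are independent, this
   heterogeneity under-disperses the overlap count relative to the
   hypergeometric law the test conditions on, pushing rejection below
   nominal.

With this simulator the measured null rejection rates at
$\alpha = 0.05$ over 1000 simulated cohort pairs are about 4.2%
(reversal test), 4.2% (down-arm concordance) and 3.4% (up-arm
concordance; the up/down asymmetry tracks the skew of log counts at low
expression, which makes the up threshold set smaller and hence more
discrete). This conservativeness is a property of Fisher's exact test
on heterogeneous gene lists — real data behave the same way — and is
reported as measured rather than recalibrated away. Note also that
calibration must be measured with *independent* lists
(`concordance = 0`): with concordant human effects implanted but no
reversal, the human up-arm maps to mouse genes whose expression level
is disease-shifted, which couples list memberships through the
mean–variance relation and makes the reversal test conservative for a
different, generator-specific reason.

## Reversal quantification

A gene is a disease DEG iff its adjusted p in the disease-vs-healthy
contrast is at most $\alpha = 0.05$. A disease DEG counts as *reversed*
("returned towards the healthy state") iff its treated-vs-disease
log2FC opposes the sign of its disease log2FC **and** that treated
change is itself significant at `treated_alpha` (default $\alpha$).
The significance gate is the package's resolution of a genuinely open
definition: under a plain sign rule, a treatment with *no* effect still
"reverses" half of the disease genes, because a pure-noise contrast
sign-opposes by coin flip — the expected percent reversed of a
treatment that truly reverses a fraction $r$ of disease genes is
$100r + 50(1-r)$, not $100r$. Gating on significance of the treated
change recovers the implanted fraction ($\approx 100r$), which the
parameter-recovery test verifies (estimates within ±10 points of the
implanted 70% in ≥18/20 seeds at 8 samples/group). The ungated sign
rule remains available (`treated_alpha = 1`) and shows the expected
coin-flip behavior as treatment strength goes to zero; a stricter
magnitude variant (`rule = "strict"`, treated state must land closer to
healthy than disease did) is also provided. Percent reversed is
reported per pathway over the pathway's disease DEGs only, so it is
invariant to padding a pathway with unperturbed genes; pathways with no
disease DEGs are reported with an undefined percent rather than
dropped.

The marker heatmap matrix reports, per marker and group, the log2 ratio
of group mean normalized expression (pseudocount 1) to the reference
(healthy) group mean, so the reference column is identically zero.

## Endpoint statistics

* **NAS rubric**: steatosis 0–3 for $<5$, $[5,33)$, $[33,66]$,
  $>66$ percent fatty hepatocytes; lobular inflammation 0–3 for none,
  $<2$, 2–4, $>4$ foci per 200× field; ballooning 0/1/2 for
  none/few/many; total 0–8. The printed bands leave 33 and 66
  ambiguous; the package reads band 3 literally as "greater than 66",
  so 66 scores 2, and any positive focus count below 2 scores 1.
* **Rank-sum test**: exact by full enumeration of same-size subsets of
  the pooled midranks for $n_A + n_B \le 12$ (ties handled exactly),
  normal approximation with tie and continuity correction otherwise.
* **One-way ANOVA + Fisher LSD**: ANOVA via `stats::aov`; LSD pairwise
  $t = (m_i - m_j)/\sqrt{MSE(1/n_i + 1/n_j)}$, $df = N - k$,
  unadjusted, as is conventional after a significant omnibus F.
* **Comparative Ct**: $\Delta Ct = Ct_{target} - Ct_{ref}$ per sample,
  $\Delta\Delta Ct$ as the difference of arithmetic group means, fold
  change $2^{-\Delta\Delta Ct}$. The reference gene is a *required*
  argument — assay designs legitimately differ (Rplp0, 18S, ...), so no
  default is assumed.
* **Outlier rule**: a value is excluded iff outside mean ± 2·SD (sample
  SD), computed once on all values; the rule is deliberately
  single-pass and is not re-applied to the retained values.

## The simulator

`sim_config()` fixes the study conditions; all generators draw from
named substreams of one global seed, so outputs are bit-reproducible
and adding a generator never perturbs an existing stream.

* Counts are negative binomial with gene-wise log-normal baseline means
  (meanlog 4, sdlog 1 — median ≈ 55 counts), one shared dispersion
  (0.1, a realistic value for in-vivo cohorts), and per-sample library
  size factors uniform on [0.7, 1.3]. Default 4 samples per group, the
  typical size of a small in-vivo RNA-seq arm; the parameter-recovery
  experiments use 8 to give the treated-contrast gate adequate power.
* A fraction π = 0.1 of genes get signed disease effects (magnitude
  ≈ N(2, 0.25²) log2 units); a fraction r = 0.7 of those are returned
  a fraction ρ = 1 of the way to the healthy mean in the treated group.
  Reversal is implanted on the *mean* scale, so ground-truth direction
  is exact rather than an artifact of resampling.
* The human cohort shares a fraction c = 0.8 of mapped mouse disease
  effects with the same sign; the ortholog map covers 90% of mouse
  genes with 10% one-to-many pairs to exercise resolution policies.
* The compound collection holds 20 standard-normal z-profiles over 978
  landmark features; one compound has `inverse_strength` (default 2)
  subtracted from the disease signature's up-tags and added to its
  down-tags.
* Endpoint tables draw per-animal steatosis (truncated normal), foci
  (Poisson) and ballooning (categorical) from group-specific
  distributions chosen so expected NAS totals track a
  healthy ≈ 0.7 / vehicle ≈ 4.4 / treated ≈ 2.6 design with group
  sizes 7/16/7, treatment improving inflammation and ballooning more
  than steatosis; Ct tables include the reference gene and injected
  outliers at mean + 5 SD.

What the simulator does *not* emulate: batch effects, gene–gene
correlation, dispersion trends, probe-level structure, dose–response,
or read-level noise. Passing tests therefore demonstrate that the
statistics behave as designed under a clean over-dispersed count model
with known truth — not that any particular biological dataset will
reproduce specific published effect sizes, which depend on the original
cohorts, DE engine and pathway database.

## Problem sizes used by the test suite

Unit and property tests run on matrices of tens to hundreds of genes.
The calibration experiments use 1000 simulated cohort pairs of 2000
genes at the default 4 samples per group; parameter recovery uses 20
seeds at 8 samples per group; screen power uses 20 seeds of a
20-compound collection at 499 permutations; the exact-test oracles
enumerate all 2×2 tables with universe ≤ 30 and all rank-sum subsets
with $n_A + n_B \le 10$.

## Known limitations

* The DE stand-in is not a count model; its p-values are approximate at
  very low counts and it applies no dispersion shrinkage or independent
  filtering.
* The KS permutation p is conservative at the score's zero atom (see
  above); report the score alongside the p-value.
* `percent_reversed` depends on the power of the treated-vs-disease
  contrast through the significance gate; at very small group sizes it
  under-counts reversal. Use `treated_alpha = 1` to see the ungated
  upper bound.
* Fisher overlap tests inherit the conservativeness described above
  whenever list-inclusion probabilities vary across genes, which is the
  norm for expression data.
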
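---
title: "Models and methods behind crisprmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprmeta)
```

`crisprmeta` implements the statistical core of a multi-omic workflow for
CRISPRi FACS modifier screens: parsing dual-sgRNA screen reads, pooling
gene-level evidence across heterogeneous screens, estimating protein
turnover from single-timepoint dynamic SILAC, calling cryptic splice
junctions from PSI tables, and normalizing bulk RNA-seq counts. This
vignette explains each model, its assumptions, the tunable parameters, and
the choices made where the design was genuinely open. Nothing here asserts
an empirical result that the package's tests and acceptance script do not
themselves compute.

## Dual-guide read parsing and recombination

Compact dual-sgRNA CRISPRi libraries place two guides against the same
gene on one lentiviral cassette. During packaging, template switching can
recombine cassettes, producing virions whose guide-A and guide-B target
different genes; such reads are uninformative about any single knockdown
and must be discarded before counting.

`match_read_pair()` detects guides by **exact substring match** within a
configurable window (default: the whole read). A pair is *matched* when
read 1 carries a known guide-A and read 2 a known guide-B from the same
construct, *recombined* when both guides are known but belong to different
constructs, and *unmapped* otherwise. Exact matching is the conservative
default because the amplicon architecture fixes guide positions but the
exact offsets and error profile vary by protocol; tolerance for mismatches
would trade specificity for a sensitivity gain the downstream statistics
do not need. "Paired guides for the same target gene" is interpreted
strictly as *same construct*; the `same_gene_ok` flag relaxes this to
same-gene-different-construct for libraries with multiple constructs per
gene.

`score_genes_permutation()` is deliberately simple plumbing so the
synthetic pipeline runs end to end without external screen software (real
screens are scored by dedicated rank-aggregation tools). Counts are
normalized per bin to counts-per-million, each construct gets
`log2((cpm_high + 1)/(cpm_low + 1))`, a gene's effect is the median over
its constructs, and the two-sided p-value is a permutation tail over
random same-size construct sets with the `(b + 1)/(n + 1)` correction
that guarantees sub-uniform null p-values. The pseudocount of 1 and
library-size normalization are standard practice, not derived from any
screen-specific calibration. Constructs with fewer than
`min_total = 10` reads across bins are dropped; the cutoff is a
convention, as "low count" has no canonical value.

## Cross-screen fixed-effect meta-analysis

Different FACS screens report effects on incompatible native scales.
Harmonization (`harmonize_screen()`) maps every screen to a common scale:

* **beta** — the effect column standardized across the screen's genes to
  zero mean and unit variance. An alternative reading would take the
  screen's test z-score itself as beta, but then the prescribed standard
  error `se = |beta|/|z|` would be identically 1 and carry no
  information; the z-scored effect column is the only reading under which
  the derived SE is informative. `beta_mode = "raw_effect"` disables the
  standardization for effects already on a common scale.
* **p truncation** — p-values are clamped to
  `[p_floor, 1 - p_ceiling_margin]` (defaults `1e-300`, `1e-16`) so the
  normal quantile stays finite in both tails; this makes extreme genes
  slightly conservative. The z magnitude is computed on the lower tail
  and floored at `1e-15`, because at `p = 1` the ceiling margin itself is
  lost to floating-point rounding in `1 - p/2`.
* **z** — the truncated p converted to a normal quantile, signed by beta;
  **se** = `|beta|/|z|`. Genes with beta exactly 0 get
  `se = epsilon_beta/|z|` (`epsilon_beta = 1e-8`) and a `zero_beta` flag
  rather than an undefined SE.

`fixed_effect_pool()` then combines k screens per gene with
inverse-variance weights `w_i = 1/se_i^2`:
`beta_pooled = sum(w*beta)/sum(w)`, `se_pooled = 1/sqrt(sum(w))`,
`z = beta_pooled/se_pooled`, two-sided normal p, Cochran's
`Q = sum(w*(beta - beta_pooled)^2)` on `k - 1` degrees of freedom and
`I² = max(0, (Q - df)/Q)`. The fixed-effect model assumes one common true
effect per gene across screens; heterogeneity is *reported* via Q and I²
but never used to drop genes, since the workflow prescribes testing
heterogeneity without attaching an action to it.

`run_meta()` evaluates every screen combination of size ≥ 2 (or an
explicit list), intersecting gene universes per combination without
imputation, and adjusts p-values by Benjamini–Hochberg within each
combination. A gene is **novel** (`assess_novelty()`) when it clears the
meta FDR at `alpha = 0.05` while clearing it in *no* constituent screen —
the definition of a hit that only pooled power can see. Directional
**hit classification** (`classify_hits()`) compares the pooled beta with
a population reference; the reference defaults to the mean pooled beta
over all genes in the combination ("the average of the population"),
with `population_ref = "hits"` switching to the mean over FDR-significant
genes, since both readings of the reference are defensible. The departure
threshold defaults to 1 (on the standardized scale, mirroring the
|LFC| ≥ 1 convention) with inclusive boundaries, so a gene exactly at
−1 is called *down*.

## Single-timepoint dSILAC turnover

After a switch to heavy lysine/arginine media, a protein at steady state
accumulates heavy label at a rate set by its turnover. For labeling time
`ts` and heavy/light ratio `R`, the half-life is

$$t_{1/2} = \frac{t_s \cdot \ln 2}{\ln(1 + R)},$$

the exact inverse of `R = 2^(ts/t½) − 1`. The quotient form is the
standard steady-state single-timepoint estimator; a product reading of
the formula would make half-life *increase* with label incorporation,
contradicting the physics of labeling. Peptides are filtered first:
contaminant-flagged entries, intensities below 1000, and ratios outside
`[0.01, 100]` are removed with a per-criterion removal log; all
comparisons are strict inequalities mirroring "below"/"lower
than"/"higher than", so a ratio of exactly 0.01 is retained.

Protein half-lives (`protein_half_life()`) are the **harmonic mean** over
unique peptide sequences — duplicates (charge states, replicate
re-observations) collapse to their median first. The harmonic mean is the
natural average for rates and is always ≤ the arithmetic mean, damping
occasional slow-turnover outlier peptides. By default peptides are pooled
within a condition before rollup; `by_replicate = TRUE` rolls up per
replicate, which is what `differential_features()` needs for its Welch
t-test on log2 half-lives (thresholds 0.5 log2 units and BH 0.05 for
half-life; 1 and 0.05 for abundances and phosphosites). The two labeling
timepoints of a typical design (e.g. day 7 and day 15) are independent
runs of the same pipeline — no joint kinetic fit is attempted, as a
single-timepoint design cannot constrain one. `density_shift_summary()`
reports the median paired log2 half-life ratio and a Wilcoxon signed-rank
p over proteins quantified in both conditions.

## Cryptic splice-junction calling

Loss of a splicing repressor admits normally silenced exons; the
signature of such a *cryptic* junction is usage that appears in knockdown
samples while being essentially absent from controls. Working from
per-sample PSI tables (PSI estimation itself is a quantifier's job):

* `delta_psi()` is the difference of group means (KD − control), missing
  values excluded per group;
* `control_presence()` is the fraction of control samples with
  PSI ≥ `detect_psi_min` (default 0.01 — quantifiers differ in what they
  emit for unused junctions, so the detection floor is configurable);
* `call_cryptic()` flags significance at `|ΔΨ| > 0.10` and calls cryptic
  when `(ΔΨ > 0.10 AND presence < 0.05) OR (ΔΨ < −0.10 AND presence >
  0.10)`. All inequalities are strict, as the thresholds are worded. The
  asymmetric negative clause is implemented verbatim even though its
  presence condition reads oddly; the thresholds are all arguments, so a
  different convention is one call away.

`categorize_junctions()` resolves each record against an exon annotation
(0-based half-open, BED convention): both ends on annotated boundaries is
*canonical* (adjacent exons) or *exon skipping* (≥ 1 annotated exon
inside the junction); one novel end inside an annotated intron is a
*cryptic exon*; a record lying wholly within one intron is *intron
retention*; anything unresolvable is *other*. Categories are
strand-symmetric — strand is carried but not interpreted.

## RNA-seq normalization and noise filtering

`normalize_chain()` applies, in order: gene-length normalization (reads
per kilobase), counts-per-million scaling, an additive pedestal of 2,
log2, and cyclic loess across samples. The order follows the method's
own narration; the pedestal before log2 maps zero counts to exactly 1
and stabilizes low counts. Cyclic loess is the pairwise variant
(`limma::normalizeCyclicLoess(method = "pairs")`, 3 iterations): for
every sample pair a loess curve of M (difference) on A (average) is
subtracted half from each member, removing smooth intensity-dependent
distortions; on identical samples the fit is identically zero, so the
step is a no-op.

`fit_noise_model()` captures the mean–variance structure per condition:
per-gene CV on the linearized scale against mean log2 expression, a
loess fit, and a threshold at the smallest mean where the fitted CV
drops below `cv_cutoff = 0.5`. The smoother and the cutoff are
implementation choices (neither has a canonical definition), both
exposed as arguments; the condition-wise thresholds are combined by
maximum so a surviving gene clears the noisier condition's floor.
`filter_noise()` keeps genes whose best per-condition mean reaches the
threshold and always partitions the input into kept plus removed.
Differential testing is Welch's t on the normalized log2 values with BH
adjustment — with typical replicate counts (n = 3–4) a moderated test
would gain power, but the plain Welch test makes no cross-gene
exchangeability assumption and is the package default. `ddct()` is the
classic qPCR `2^−ΔΔCt` fold change.

## The synthetic-data generators

Every pipeline input can be generated with planted ground truth
([sim_config()] holds the conditions), which is what the test suite and
the acceptance script exercise:

* **Screens** — null genes draw effects from a standard normal with
  `p = 2(1 − Φ(|effect|))`, so null p-values are uniform and the effect
  column is already on the z scale the harmonizer targets (the null
  distribution of real screens is not published; the standard normal is
  a modeling convention). Shared hits shift every screen by a
  gene-specific effect (mean 2, spread 0.25), specific hits shift one
  screen. *Distributed-weak* genes — the novelty test bed — draw
  per-screen effects around 2.5 but clipped at |z| ≤ 3.2: with 5,000
  genes and ~50 planted weak genes, Benjamini–Hochberg at 0.05 cannot
  reach `p = 2Φ(−3.2)`, so weakness in every single screen holds by
  construction, not just in expectation. The mean of 2.5 was fixed by an
  a-priori power calculation targeting decisive pooled evidence
  (expected novelty sensitivity ≈ 94% at these conditions).
* **Reads** — read pairs embed guides behind short random flanks; a
  configured fraction swaps guide-B to a construct targeting another
  gene. Truth records per-construct clean counts and the realized
  recombined count, so the parser can be checked exactly at rate 0 and
  against exact binomial bands elsewhere.
* **Peptides** — ratios are the noiseless `2^(ts/t½) − 1` under
  mean-preserving multiplicative log-normal noise (`ratio_cv`, default
  5%), because ratios are positive and heavy-tailed; contaminants and
  out-of-range ratios are injected at low rates to exercise the filters.
* **Junctions** — one three-exon toy gene model per junction on a single
  forward-strand chromosome; each planted category follows its defining
  geometry exactly, and PSI noise (default sd 0.02) is truncated to
  [0, 1]. Strand is a field, not an assumption.
* **Counts** — negative binomial with log-normal baselines, counts
  proportional to gene length (so length normalization matters),
  per-sample size factors in [0.8, 1.2], dispersion 0.05, and 10% of
  genes shifted by |log2FC| = 2.

One global seed drives everything; each generator derives an independent
substream from the seed and its stage name, so a stage is reproducible in
isolation and the whole run is byte-identical under a fixed seed.

What the generators do *not* emulate matters for interpreting green
tests: real screens have guide-efficacy variation within genes,
correlated off-target structure, and non-normal effect tails; real
peptide data have missingness correlated with intensity; real junctions
share splice sites across overlapping transcripts; real counts have
gene–gene correlation. Passing on synthetic data shows the statistics
are implemented correctly under the stated model, not that the model
captures every feature of a given dataset.

## Problem sizes and numerical conventions

The test suite and acceptance script run at deliberately desk-scale
sizes — 2,000–5,000 genes, 20 global-null replicates, 50,000 read pairs,
200 proteins, 500 junctions, 5 replicate power simulations — chosen so
the full suite completes in about a minute while keeping every statistical
check well-powered. Key numerical conventions collected in one place:
p truncation `[1e-300, 1 − 1e-16]` with a `1e-15` floor on |z|;
`epsilon_beta = 1e-8` for zero-beta genes; `I² = 0` when `Q = 0`;
permutation p-values carry the +1 correction; inclusive boundaries for
hit directionality but strict boundaries for all splicing thresholds and
peptide filters; ties in duplicate-peptide collapse resolved by median.

## Known limitations

The meta-analysis is fixed-effect only — under real cross-screen
heterogeneity the pooled SE is optimistic (Q and I² are reported so users
can see this). The permutation gene scorer is not a replacement for
dedicated screen-analysis tools. The noise-model threshold depends on the
loess span at the sparse ends of the expression range. The cryptic
definition consumes per-sample PSI means and does not model PSI
estimation uncertainty. No protein inference or PTM localization is
attempted; peptide-to-protein assignment is taken from the input table.
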
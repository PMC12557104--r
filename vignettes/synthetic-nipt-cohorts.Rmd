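---
title: "Synthetic cfDNA cohorts and aneuploidy classifiers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic cfDNA cohorts and aneuploidy classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptsynth)
```

## The problem

Non-invasive prenatal testing (NIPT) screens for fetal chromosomal
aneuploidies — trisomies 13, 18 and 21 (ACA) and the sex-chromosome
aneuploidies XO, XXX, XXY and XYY (SCA) — by counting low-coverage
sequencing reads of cell-free DNA (cfDNA) from maternal plasma. A fraction
FF of those reads ("fetal fraction") is of placental origin; a trisomic
fetus therefore inflates the read share of the affected chromosome by
roughly FF/2. Real positive samples are rare, which starves classifier
development of training data. This package implements a synthetic-data
route around that scarcity: generate unlimited negative samples, transform
them into positives with closed-form count arithmetic, train logistic
models on the synthetic data, and quantify what that buys over classical
z-score screening as the evaluation sets approach true population
prevalence.

## Synthetic negatives

Two generation pathways are provided.

**FASTQ merging** (`merge_fastq_sets()`). Two or more nonoverlapping read
sets of the same fetal sex are pooled, shuffled with a seeded RNG, and
subsampled without replacement to a target depth. The fetal fraction of the
pool is the read-count-weighted mean of the components,

$$FF_{pool} = \frac{\sum_i M_i \, FF_i}{\sum_i M_i},$$

computed exactly and never rounded. The weighted mean is associative, so
any grouping of components gives the same pooled FF; this conservation
property is tested. "Nonoverlapping" is enforced as read-id disjointness —
colliding ids raise an error rather than being renamed, so the conservation
contract (every output read is exactly one input read) stays checkable. The
GC content of a merged set is recomputed from its emitted sequences, not
averaged from metadata, because GC is a downstream model feature and must
match the reads actually written. Fragment-length similarity between
fixture and merged sets is measured by the product-moment correlation of
their length-frequency vectors, aligned on the union of supports
(`length_distribution_correlation()`, reported in percent).

**Count-level simulation** (`simulate_negative_cohort()`). Each sample is a
row of per-chromosome read counts plus FF, GC and fetal sex. Defaults, and
why:

* Total read count TRC ~ Normal(3.3M, 0.4M), truncated below at 2M reads —
  the depth profile of a low-coverage screening run with a 2M-unique-read
  inclusion floor.
* GC content ~ Uniform(0.395, 0.43) — the inclusion window; only a range is
  known, so the least-informative choice inside it.
* FF ~ Lognormal(meanlog = log 0.10, sdlog = 0.35) truncated to
  [0.04, 0.30] — median 10%, a typical first-trimester profile, with the 4%
  screening floor applied by truncation.
* Chromosome proportions default to hg19 chromosome-length fractions,
  weighted by maternal and fetal copy number mixed as (1 − FF, FF); a male
  fetus contributes one X and one Y copy, so the chrX share falls and the
  chrY share rises with FF.
* Per-chromosome GC tilt: the expected proportion of chromosome *c* is
  multiplied by $\exp(\kappa_c (GC - 0.4125))$ and renormalized — a minimal
  monotone bias model with one knob per chromosome. The default sets
  $\kappa_{13} = -3$ and all others to 0, reproducing the strong negative
  GC–count coupling that makes chromosome 13 the hard case for a plain
  z score (at n = 500 the induced GC~chr13 correlation is clearly negative
  and highly significant).
* Female-fetus chrY reads are pure misassignment background,
  `max(0, round(50 + 2e-4 * TRC + Normal(0, 10)))` reads — tens to hundreds
  of reads growing linearly with depth, orders of magnitude below a male
  fetus's true chrY signal.

Counts are drawn multinomially (via sequential binomial thinning, so row
sums match the drawn TRC exactly). The fixture FASTQ generator
(`simulate_fixture_fastq()`) draws fragment lengths from a two-component
mixture — maternal mode 166 ± 9 bp, fetal mode 143 ± 8 bp, weights
(1 − FF, FF), support 100–220 bp — the standard bimodal cfDNA fragmentomics
picture; sequences are substrings of a random background genome at a
configurable GC rate. These reads exist to exercise the merge pathway; they
carry no alignment semantics.

**What the simulator does not emulate.** Counts are per whole chromosome:
no per-bin coverage, mappability structure, sequencing error, or
overdispersion beyond the multinomial; no mosaicism, twins, microdeletions
or partial aneuploidies. Passing tests therefore demonstrate the internal
consistency of the framework under iid counting noise, not performance on
real sequencing data.

## Synthetic positives

All synthesis operations change only the documented chromosome, the label
and (through it) TRC; FF and GC are preserved.

* **Trisomy / XXX**: the target count becomes
  $C + C \cdot FF/2$ (`synthesize_trisomy()`, `synthesize_xxx()`) — the
  extra fetal chromosome copy adds half a fetal-fraction's worth of reads.
* **XO**: a male-fetus sample's chrY count is replaced by the misassignment
  background predicted from the female-fitted regression
  $CyRC = \beta_0 + \beta_1 TRC + \varepsilon$
  (`fit_y_misassignment()`, `synthesize_xo()`); chrX is untouched, because
  an XO fetus has the same single-X dosage as a male fetus.
* **XYY**: the true fetal chrY signal (observed count minus background)
  doubles: $2 \, C_{Y} - CyRC$ (`synthesize_xyy()`).
* **XXY**: a female-fetus sample gains a male-like chrY count predicted
  from the male-fitted regression
  $C_{Y} = \beta_0 + \beta_1 TRC + \beta_2 FF + \varepsilon$
  (`fit_y_count_model()`, `synthesize_xxy()`), using the female sample's
  TRC and FF as proxy covariates — valid because chrY reads are a
  negligible share of TRC.

Residuals are sampled from a normal distribution with the *fitted* residual
mean and standard deviation (the mean is ~0 for least squares), so
synthetic positives carry the dispersion of the negatives the fit came
from.

Numerical choices: counts are rounded half-to-even after each equation
(integer reads, deterministic oracles); the sampled background CyRC is
clipped to [0, C_Y] inside XYY (it can be neither negative nor exceed the
observed count) and to [0, ∞) elsewhere — negative sampled values are not
otherwise addressed by the equations; FF is left unchanged even though a
trisomy adds a few percent of one chromosome's reads (no FF correction is
applied anywhere).

## Classifiers

Counts are first normalized to a 3,000,000-read baseline
(`normalize_counts()`): each chromosome count is scaled by `baseline/TRC`
and rounded, so totals land within 24 reads (one rounding per chromosome)
of the baseline and classifiers see chromosome *shares*, not depth.

* **Binary ACA model** (`train_aca_classifier()`): ridge-regularized
  logistic regression on (target count, GC, FF), features standardized with
  training-set mean/sd. The penalty (default `lambda = 1e-4`) is weak and
  exists to stabilize the fit under near-separability; the solver
  warm-starts from heavy regularization (a cold start at a near-zero ridge
  penalty can diverge on separable data). The fit is deterministic for
  fixed training data.
* **Multiclass SCA model** (`train_sca_classifier()`): multinomial
  logistic regression on (chrX, chrY, GC, FF) over the six classes
  {NEG_XX, NEG_XY, XO, XXX, XXY, XYY}; prediction is argmax probability
  with ties broken by fixed class order.
* **z-score baseline** (`zscore_reference()`, `zscore_classify()`): the
  classical rule — positive iff the normalized target count exceeds the
  reference mean by strictly more than 3 reference SDs. No GC correction is
  applied, which is precisely what makes the z score vulnerable to
  GC-driven count shifts the logistic model absorbs through its GC feature.

**Outlier removal** (`remove_outliers()`): the removal rule is a
per-label-group robust z-score — |x − median| / (1.4826 · MAD) > k, default
k = 4 — on the model features. Zero-MAD features contribute no outliers.
The rule is deliberately conservative (well under 1% removed on a clean
cohort) and is applied to training sets and to the evaluation negative pool
before use.

## Evaluation design

`run_comparison_experiment()` runs the full comparison. Per trisomy:
training negatives and positive-source negatives are simulated separately
(20,000 per class by default); a held-out negative pool (50,000 after
outlier filtering) is simulated with its own seed and reused across
upscales, like a fixed screening cohort; at each upscale
u ∈ {1, 5, 10, 20, 40} the evaluation set adds
`round(n_neg · prevalence · u)` freshly synthesized positives
(half-to-even rounding — printed cohort tables elsewhere round
differently, and those exact integers are deliberately not chased). Default
prevalences are 0.55, 1.07 and 8.27 per 10,000 for T13, T18 and T21.
Train/eval disjointness is asserted, not assumed. Sensitivity and PPV are
computed from exact confusion counts; undefined ratios are `NA`, never a
silent zero. The SCA arm trains on 35,000 and evaluates on 9,000 samples
per class. These desk-scale sizes keep a full run in the low minutes on one
CPU; every size is configurable upward.

Each stage derives its own RNG stream from one master seed, so a report is
reproducible bit-for-bit from `(config, seed)`.

## Known limitations

* At a 3M-read baseline the counting-noise SD of the chr21 share is ~0.45%
  of its count, while the trisomy boost at the 4% FF floor is 2%. The
  lowest-FF positives and the upper tail of the negatives therefore overlap
  irreducibly under iid simulation: even an oracle classifier built from
  the generator's true conditional means commits a handful of false
  positives per 50,000 negatives on chr21, which caps the achievable PPV at
  1× prevalence. This is a property of iid counting noise — frameworks that
  recombine a small, finite reference cohort bound their tail exposure and
  can appear perfectly separable at the same scale. chr13 and chr18 are
  larger chromosomes (the same 2% boost is 5–8 SDs), so their models do
  separate perfectly at this scale.
* FF is taken as known metadata. Estimating FF from reads, and its error
  propagation, is out of scope; in practice FF estimation error would widen
  every margin above.
* The z-score baseline is computed on uncorrected normalized counts; other
  NIPT pipelines apply bin-level GC correction (LOESS/PCA), which would
  narrow the gap to the logistic model on GC-confounded chromosomes.
* Mosaicism, which dilutes the effective fetal signal below FF/2, is not
  modelled.
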
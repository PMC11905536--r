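---
title: "Open-set methylation classification with methylosr: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-set methylation classification with methylosr: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylosr)
```

# The problem

Genome-wide DNA methylation profiles measured on Illumina Infinium arrays
(450K/EPIC) have become a reference tool for classifying CNS tumours into
molecularly defined methylation classes. Two practical obstacles stand
between a reference cohort and a deployable classifier:

* **Class imbalance.** Reference cohorts contain a few hundred samples of
  common entities and a handful of samples of rare ones. A classifier
  trained naively learns the common classes at the expense of the rare.
* **The open world.** A diagnostic sample may belong to none of the
  reference classes — a novel entity, a low-purity specimen, an artefact.
  A closed-set classifier is forced to pick a known class anyway, which
  in a diagnostic setting is the worst possible failure mode.

`methylosr` implements a pipeline that addresses both: SMOTE oversampling
equalises class sizes before feature selection; an OpenMax layer on top
of a multilayer perceptron recalibrates SoftMax probabilities into a
92-way output whose extra label, `"unknown"`, absorbs inputs that are far
from every known class in the network's representation space.

# Pipeline stages

## Preprocessing

Beta values $\beta \in [0,1]$ (methylated fraction per CpG probe) are the
input. Probes are removed if they sit on a sex chromosome, lack a unique
hg19 alignment, contain a SNP, or are absent from the EPIC chip — the
four standard exclusion categories for cross-platform classifier
construction. Values are transformed by $\log_2(\beta + 1)$, a gentle
variance stabilisation that maps $[0,1]$ to $[0,1]$; batch effects are
then removed by fitting, per probe, an ordinary least-squares model with
the batch factor as covariate (sum-to-zero contrasts) and subtracting the
estimated batch terms (`limma::removeBatchEffect` is the engine). The
inverse transform $2^v - 1$ restores the beta scale; correction can push
a few cells slightly outside $[0,1]$ and those are clipped with a logged
count. A PCA-based report quantifies batch-associated variance before and
after correction, both on PC1 alone and as a variance-weighted mean
$R^2$ over the top components, because "fraction of batch variance"
is ambiguous between the two conventions.

Correction is estimated from all supplied samples jointly, without class
labels; single-batch data pass through unchanged. Missing beta values are
rejected by default, with optional per-probe median imputation.

## Balancing and probe selection

SMOTE creates synthetic minority samples by interpolation: a minority
sample $x$ and one of its $k = 5$ nearest same-class neighbours
$x_{nn}$ yield $x + u\,(x_{nn} - x)$ with $u \sim U(0,1)$, until every
class reaches the majority size ("not majority" strategy; a 2801-sample,
91-class cohort with majority 143 lands at exactly $91 \times 143 =
13{,}013$). Synthetic points are convex combinations, so bounded features
stay bounded; originals are never altered, and each synthetic row's
provenance (base, neighbour, $u$) is recorded. For classes smaller than
$k + 1$, $k$ is reduced per class with a message; singleton classes are
an error since they cannot be interpolated.

Probes are then ranked by random-forest mean-decrease-in-impurity
importance (4000 trees, `mtry = sqrt(p)`, single-threaded for
reproducibility), normalised to sum to one, with deterministic
lexicographic tie-breaks. The panel is the top $K$ probes; $K = 1000$ is
the tool default and $K = 767$ a comparison mode matching an existing
767-probe classifier. Selection runs on the SMOTE-balanced matrix, so
rare classes contribute to importance on equal terms. A documented
discrepancy in the source workflow (a figure caption citing 2000 probes
against methods text citing 1000) is resolved in favour of 1000, with
the panel size fully configurable either way.

For desk-scale cohorts the pipeline also offers `n_probes = "auto"`:
keep every probe whose normalised importance exceeds twice the uniform
share $1/P$. On data where a minority of probes carry class signal this
adapts the panel to the informative set without hard-coding its size;
see *The synthetic study configuration* below for why a selective panel
matters to open-set behaviour.

## The MLP

A single-hidden-layer perceptron with leaky-ReLU activation (slope 0.01)
is trained by minibatch SGD (learning rate 0.01, momentum 0.9, batch 32)
on the cross-entropy, with per-feature standardisation estimated from
training data. A stratified validation split (10%) drives early
stopping: after `patience = 10` epochs without improvement the weights
of the best epoch are restored, so the returned model never has worse
validation loss than any epoch seen. The published architecture used an
80,000-unit hidden layer; the layer width is a plain configuration value
and the package defaults to 128 units, which is ample at panel sizes of
a few hundred probes — the quantities OpenMax consumes are hidden-layer
activations, and their geometry, not their dimension, is what matters.
Training is deterministic under a seed, single-threaded.

The optimiser hyper-parameters above are not stated in the source
methodology and are declared defaults, all configurable. A sentence in
the source about "semi-supervised learning leveraging unlabeled data"
describes no procedure and is not implemented; the supervised path is
canonical here.

## OpenMax

Let $z_k$ be the logits and $P(k\mid x) = \mathrm{softmax}(z)_k$
(computed with max-subtraction). For each class $k$ the *mean activation
vector* $\mu_k$ is the average penultimate-layer activation over
correctly classified training samples of that class (falling back to all
samples of the class if none are correct). Distances
$d_k(x) = \mathrm{dis}(a(x), \mu_k)$ from a sample's activation to each
$\mu_k$ feed a per-class Weibull model that converts distance into an
atypicality weight $w_k(x) \in [0,1]$, and the recalibration is

$$f_k(x) = P(k \mid x)\,\bigl(1 - w_k(x)\bigr), \qquad
  f_u(x) = \sum_{k=1}^{K} P(k \mid x)\, w_k(x),$$

$$P'(k \mid x) = \frac{f_k(x)}{\sum_j f_j(x) + f_u(x)}, \qquad
  P'(u \mid x) = \frac{f_u(x)}{\sum_j f_j(x) + f_u(x)},$$

with $\hat y$ the argmax over the $K$ known classes plus *unknown* (ties
resolved toward the lowest class index, unknown last). Since
$\sum_k f_k + f_u = \sum_k P(k\mid x) = 1$, the normalisation is an
identity, but it is performed as written so the contract holds for any
weight vector.

Two weight modes are first-class:

* **`weibull_cdf`** (default): $w_k = 1 - \exp(-(d_k/\sigma_k)^{\kappa_k})$,
  the Weibull CDF of the distance — $w$ grows with atypicality, the
  standard open-set construction.
* **`as_printed`**: $w_k = \exp(-(d_k/\sigma_k))$ with $\kappa = 1$ and
  $\sigma_k$ the exponential MLE (tail mean). This survival-form weight
  equals 1 *at* the class centroid and decays with distance — under the
  recalibration above it pushes typical samples toward *unknown*, the
  inverse of the stated intent. It is retained verbatim as an alternative
  mode rather than silently corrected; the CDF mode is the default.

The distance is Euclidean by default with cosine available by
configuration. `SNUH-MC`-style closed-set operation ("91 mode": SoftMax
argmax, no unknown) and open-set operation ("92 mode") are both exposed,
and the calibrated score reported for downstream decisions is the
maximum recalibrated probability over the known classes (maximum SoftMax
in 91 mode).

### Calibrating the tails: why and how

The classical construction fits the Weibull to the `tail_size` (default
20) largest within-class training distances and uses its CDF directly.
That behaves well when classes have hundreds of members, so that 20
distances are a genuinely extreme top fraction. At desk scale it breaks
down for two measurable reasons:

1. With tens of samples per class, the 20 largest distances are the
   upper *half* of the distribution, so the fitted CDF crosses $1/2$
   around the 70th percentile of perfectly ordinary within-class
   distances, flagging a third or more of honest samples as unknown.
2. Distances measured on the training samples themselves systematically
   understate the distances of fresh samples — partly a small-sample
   effect visible in the input space already, partly because SMOTE
   interpolations lie inside the class hull.

The pipeline therefore estimates tails differently by default (the
module-level functions `fit_mavs()`/`fit_weibull_tails()` keep the
classical behaviour so either construction can be used):

* **Held-out calibration.** A stratified 15% of the training originals
  is withheld from SMOTE and the MLP; together with the original samples
  of the early-stopping validation split they form a calibration cohort
  that never contributed gradient updates. Each correctly classified
  calibration sample contributes a *studentised ratio* — its distance to
  its class MAV divided by the class's median training distance — and
  the ratios are pooled across classes, so classes with very few
  calibration samples still borrow strength. Each class's distance list
  is rebuilt as anchor × pooled ratios, where the anchor is the class
  median floored at the cohort-median anchor (anchors estimated from a
  handful of original samples are biased small; the floor widens only
  those classes and errs in the protective direction).
* **Extreme-value tails** (`tail_method = "extreme"`). A single
  distribution is fitted to *all* calibration distances of the class by
  maximum likelihood, with the family (Weibull, lognormal or gamma)
  chosen by AIC — on activation-distance ratios the lognormal usually
  wins decisively. The class's tail model is then the law of the
  *maximum of $n$ fresh draws* from that fit, $F^n$, re-expressed as a
  Weibull by matching its quartiles (closed form), so the weight keeps
  the required CDF form. Reading $w_k(d)$ as "the probability that even
  the most atypical member of a fresh class-sized cohort would fall
  below $d$" puts the $w = 1/2$ crossing *beyond* the plausible range of
  the class rather than inside its upper tail. With $n$ set to the
  training-cohort size, the expected number of false "unknown" calls in
  a cohort-sized known test set is $\ln 2 \approx 0.7$ regardless of
  cohort size — a familiar-range control at the cohort level.

Both choices are about *estimating* $\sigma_k, \kappa_k$; prediction
still evaluates exactly the recalibration equations above.

## Evaluation protocol

Evaluation runs over the fixed label set of the $K$ known classes plus
`"unknown"` (92 labels in the reference setting). Foreign designations
for deferred calls ("not applicable") are harmonised to `"unknown"`. The
*filtered* evaluation drops samples whose true label is unknown but
leaves predictions untouched, so an `"unknown"` call on a known-truth
sample still counts against the classifier; its macro F1 averages over
the known-class label set (a flag switches to the 92-label set). Classes
absent from the truths contribute $F1 = 0$ to the macro — the fixed-set
convention that keeps scores comparable across evaluations. Micro F1
aggregates counts and equals accuracy for single-label prediction.

The **noise-injection experiment** adds increasing numbers of
novel-class samples to a known-class test set and tracks both F1s over
the 92-label set. Two readings matter. A closed-set model must misfile
every noise sample into a known class, so its macro F1 falls
monotonically as noise grows — the behaviour that motivates open-set
recognition. For an open-set model that detects the noise well, the
micro F1 rises (each detected noise sample is a correct prediction),
and the macro F1 over the fixed label set rises too, because the unknown
label starts empty (contributing $F1 = 0$) and fills with correctly
flagged samples. A *decreasing* macro for the open-set model would
indicate noise bleeding into known classes; on the package's synthetic
cohorts detection is near-perfect and no decrease occurs. The
experiment exposes both modes so either behaviour can be measured.

**Decisions.** Calibrated scores are binned as printed
($\ge 0.9$; $[0.5, 0.9)$; $< 0.5$, both cut points closed on the left)
and integrated with an evidence status supplied by expert review —
concordant, discordant, indeterminate, or control — into five
categories: *Match* (score $\ge 0.9$, concordant), *Likely match*
(score $< 0.9$, concordant), *Uncertain* (indeterminate, any score),
*No match* (discordant), *Control (No match)*. Evidence is an input
annotation, never computed: it encodes histopathology/NGS/clinical
concordance that software cannot reproduce.

**t-SNE.** An exact-gradient t-SNE embedding (perplexity 30, 1000
iterations, early exaggeration, deterministic under seed) supports
visual inspection of where a query sample falls relative to reference
clusters. Coordinates are for eyes only and never feed classification.

# The synthetic cohort generator

Real reference cohorts cannot ship with the package, so every stage is
exercised on seeded Infinium-like cohorts. Each probe has a bimodal
background state (hypomethylated mean ≈ 0.2 or hypermethylated ≈ 0.8,
the canonical two-mode shape of array beta values); each class — known
and novel — owns a disjoint block of informative probes whose state is
flipped in that class's samples. Values are drawn from Beta
distributions with mean $m$ and concentration $c = 20$ (shapes $mc$,
$(1-m)c$), giving realistic within-probe scatter. Batch effects are
per-probe, per-batch offsets injected on the logit scale and mapped
back, so they survive the pipeline's log-scale handling non-trivially
and are identifiable (offsets centred per probe). Novel classes share no
informative block with known classes and are withheld from training.

The default spec is the package's study condition: 8 known classes with
sizes 40/30/20/15/12/10/8/6 (≈7:1 imbalance, making SMOTE
consequential), 2 novel classes of 15 samples, 300 probes with 10
informative per class, 2 batches with logit-scale offset SD 0.5. Novel
class size and batch SD are the package's choices where no external
anchor exists: 15 novel samples give a stable recall estimate without
dominating the test set, and offset SD 0.5 produces a clearly visible
PC-level batch signal that correction must actually remove.

What the generator does *not* emulate: probe type I/II chemistry bias,
dye bias, detection failures, FFPE degradation, copy-number
contamination of methylation signal, and correlated probe blocks beyond
the planted ones. Passing tests on synthetic cohorts therefore
demonstrate the pipeline's *mechanics* — balancing, selection, open-set
geometry, seeded reproducibility — not clinical-grade accuracy on real
arrays.

## The synthetic study configuration

The synthetic study (tests and the acceptance script) runs the pipeline
with `n_probes = "auto"` and cosine activation distance. Both choices
are consequential and deliberate:

* With 80 informative probes among 300, a fixed 1000-probe panel keeps
  everything and the 220 noise probes dilute activation distances: the
  margin between fresh known samples and novel samples nearly vanishes.
  The selective panel restores it. This mirrors the published setting,
  where 1000 probes from 428,230 is a 0.2% selection — the *point* of
  feature selection is concentration.
* Cosine distance is invariant to activation magnitude, which varies
  strongly (and heavy-tailedly) with classifier confidence; Euclidean
  distance conflates that magnitude variation with genuine atypicality.
  Euclidean remains the default of the module functions.

With this configuration, held-out known-class macro F1 on the default
cohort is ≥ 0.9 and novel-class "unknown" recall is 1.0 at every
generator seed the maintainers have exercised (ten seeds including the
study seed); the suite asserts the study-seed case.

# Numerical and degenerate-input policy

* SoftMax always subtracts the row maximum; infinite logits are an
  error, overflow is impossible.
* All stochastic steps (SMOTE draws, forest growth, weight
  initialisation, shuffling, splits, t-SNE initialisation) consume an
  explicit seed; a global pipeline seed fans out to per-stage derived
  seeds (stage-name hashing, kept below $2^{31}$) so stages can be rerun
  independently. Seeded helpers restore the caller's RNG state.
* Importance ties break lexicographically by probe id; prediction ties
  break toward the lowest class index with unknown last.
* Constant feature matrices yield a well-defined uniform importance
  vector rather than an error; all-zero distance tails, singleton
  classes, empty filter results, unannotated probes, and out-of-range
  scores are errors with actionable messages.
* Weibull/lognormal/gamma fits guard against zero distances with a
  floor of $10^{-12}$; distances are non-negative by construction.
* Problem sizes in the shipped tests: cohorts of 100–300 probes and
  40–200 samples, forests of 200–4000 trees, MLPs of 8–128 hidden
  units, 1000-draw parameter-recovery samples, and a 2801-sample SMOTE
  arithmetic check. The acceptance script's pipeline run uses the
  default synthetic spec above.

# Known limitations

* The open-set guarantees are calibration-based, not adversarial: a
  novel class whose activation signature happens to mimic a known
  class's will not be flagged.
* The extreme-value tail construction assumes the pooled studentised
  ratios are exchangeable across classes; classes with radically
  different internal heterogeneity would violate this, and per-class
  calibration would need more held-out samples than desk-scale cohorts
  provide.
* The `as_printed` weight mode is faithful to its source but not fit for
  diagnostic use (see above); it exists for comparability.
* `embed_tsne` is exact ($O(n^2)$ per iteration) and intended for
  cohorts up to a few thousand samples.
* Real-array preprocessing upstream of beta values (IDAT parsing,
  normalisation, detection p-values) is out of scope; inputs are assumed
  to be normalised beta matrices.

# A minimal session

```{r example, eval = FALSE}
co <- generate_cohort(synthetic_spec(seed = 7))
cfg <- pipeline_config(seed = 7, n_probes = "auto", distance = "cosine")
res <- run_pipeline(co$beta, co$samples, config = cfg, out_dir = "run")

res$evaluation_filtered      # known-class micro/macro F1, held out
table(truth = res$predictions$truth == "unknown",
      called = res$predictions$predicted == "unknown")

# decision framework on the predictions (evidence comes from review)
dec <- categorize_decision(res$predictions$calibrated_score,
                           rep("concordant", nrow(res$predictions)),
                           sample_id = res$predictions$sample_id)
head(dec)
```
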
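---
title: "Hierarchical meta-classification for imbalanced disease staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical meta-classification for imbalanced disease staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Visit records of chronic kidney disease (CKD) patients at stage 3 or higher
are heavily skewed toward the mildest stage: in the cohort profile this
package emulates, stages 3, 4 and 5 occur in a ratio of about 23:2:1 at the
record level. A classifier that optimises overall accuracy on such data can
label nearly everything stage 3 and still look good — while missing
precisely the stage-4 and stage-5 patients for whom a missed label
(a false negative) has the most severe clinical consequences.

`hiermc` addresses this with a hierarchy of two subtasks:

1. **Coarse step.** Separate stage 3 from the combined class {4, 5} by
   meta-classification over balanced subsets.
2. **Refinement step.** Split the records assigned to the combined class
   into stage 4 versus stage 5 with a single classifier trained on the true
   stage-4/5 subset, under the original feature representation.

The combined class is a natural clinical grouping: stages 4 and 5 share a
critically reduced kidney function (eGFR below 30), whereas stage 3 is a
moderate decline. The hierarchy first recognises "advanced disease", then
resolves its grade.

## The coarse model

Let the training data contain $n_3$ majority records and $n_{45}$ combined
minority records. The ensemble size is

$$M = \lfloor n_3 / n_{45} \rfloor,$$

so the majority class can be partitioned into $M$ random, pairwise disjoint
blocks of exactly $n_{45}$ records. Each block, paired with the complete
minority set, forms one balanced training set; one base classifier is
trained per set. Records not covered by any block (when $n_3$ is not a
multiple of $M \cdot n_{45}$) are unused by base-classifier training but do
participate in meta-classifier training. At the emulated cohort's coarse
imbalance (73,425 vs 10,217 in the 2007–2014 window) this yields $M = 7$.

Every record $r$ is then **re-represented** as the $M$-vector of labels
$\langle C_1(r), \dots, C_M(r)\rangle$ assigned by the base classifiers.
A categorical naive Bayes is fitted on this representation from scratch:
with Laplace constant $\alpha$ and label alphabet $A$,

$$P(C_j = v \mid c) = \frac{n(C_j = v, c) + \alpha}{n(c) + \alpha |A|},
\qquad
\hat{c}(r) = \arg\max_c \Big[\log P(c) + \sum_{j=1}^M \log P(C_j = C_j(r) \mid c)\Big].$$

Unlike under-sampling, no majority record is thrown away globally — every
record informs one base classifier. Unlike over-sampling, no synthetic
record is fabricated.

### Numerical and design choices

* **Naive-Bayes variant.** The classifier family is fixed by the method;
  the variant is our choice: categorical features (the hard base labels),
  Laplace smoothing with $\alpha = 1$, and log-space scoring to avoid
  underflow at large $M$. Base classifiers contribute hard labels only —
  no probability calibration — since the meta-representation is defined on
  labels.
* **Tie-breaking.** Exact posterior ties go to the combined minority class
  (and, in the three-class variant, to the more severe stage). A false
  negative on advanced disease is costlier than a false alarm, so the
  conservative direction is toward severity.
* **Meta-training labels.** The meta-classifier is trained on label vectors
  of the full imbalanced training set, with base classifiers applied to
  records they may have seen during their own training; such labels can be
  optimistic. An `out_of_fold = TRUE` mode blanks each model's label on its
  own training records (naive Bayes simply skips the blanked term). The
  default keeps the simpler construction; the optimism risk is confined to
  the conditional tables, not the test-set evaluation.
* **Partition versus resampling.** Disjoint blocks are the default
  construction. An alternative reading — drawing each balanced subset
  independently without replacement — is available as
  `mode = "resample"`; it changes overlap between subsets but none of the
  count invariants.
* **Base family.** Random forest (100 trees, unlimited depth, per-model
  seeds `seed + j`) is the default; logistic regression (one-against-all
  for multiclass), Gaussian naive Bayes and CART trees are available. Base
  classifiers are delegated to established implementations (`ranger`,
  `stats::glm`, `e1071`, `rpart`); the partitioning, re-representation and
  the meta naive Bayes are implemented in this package.
* **Refinement.** No re-balancing between stages 4 and 5 by default: their
  ~2:1 ratio is mild, and a plain classifier on the true stage-4/5 subset
  suffices. `balance = TRUE` applies the same ensemble machinery inside
  the refinement step for more skewed second-level problems. Stage order
  is not exploited (no ordinal treatment).

## Comparator strategies

The harness implements four alternatives under one fit/predict contract:
a plain classifier with no imbalance handling (`baseline_oaa`), random
under-sampling of every stage to the smallest stage's count (a documented
flag restricts down-sampling to the majority only — the multiclass variant
of under-sampling is ambiguous and both readings are provided), SMOTE
over-sampling of the minorities to the majority size, and the
non-hierarchical meta-classifier (`simple_mc`, same balanced subsets but
three-valued label vectors). SMOTE follows the original definition — each
synthetic point is $x + u(x' - x)$ with $u \sim U(0,1)$ and $x'$ one of the
$k = 5$ nearest same-class neighbours under Euclidean distance — because no
SMOTE implementation exists in the package's R dependency stack and the
algorithm is small and exactly specified.

## Evaluation protocol

Records are split temporally: train on years $[y_0, 2014]$, test on the
fixed year 2015, emulating prospective prediction; cross-validation is
deliberately not used. Per class $i$, one-vs-rest counts give

$$\text{Specificity} = \frac{TN_i}{TN_i + FP_i},\quad
\text{Sensitivity} = \frac{TP_i}{TP_i + FN_i},\quad
\text{Precision} = \frac{TP_i}{TP_i + FP_i},$$

and the F-measure is their harmonic combination. A 0/0 denominator returns
0 with a warning — conservative, and it keeps aggregates defined when a
tiny test set leaves a class unpredicted. Summary tables report the
unweighted **macro** average over the three stages; the weighting of the
reported averages is genuinely open, and macro was chosen because single
sensitivity/specificity/F triples for three-class output most naturally
read as class means. `run_comparison()` refits each strategy across
repeats with seeds `base_seed + r` — re-drawing the balanced partitioning
and re-seeding the base classifiers each time, since the repeat protocol
("a different split each time") does not pin down whether classifiers were
also re-seeded — and aggregates mean ± sd against the fixed test set.
`run_truncation()` repeats the comparison over training windows that
progressively drop early years, reporting per-stage true-positive rates
per window.

## The synthetic cohort generator

No public data exists for this problem — the motivating cohort is private
EHR data — so the generator is a first-class module that emulates its
documented structure:

| property | default | basis |
|---|---|---|
| patients | 1,200 (test scale); 13,111 full scale | cohort size |
| visits/patient | 1 + Poisson(16) | mean 17 visits |
| years | 2007–2015, uniform over a patient's active span | nine-year span |
| stage mix (record level) | 23/26, 2/26, 1/26 | 23:2:1 imbalance |
| age | Normal(70, 12), truncated [18, 100] | reported mean (sd) |
| sex | 60% female | reported split |
| conditions | 447 Bernoulli, prevalence log-uniform [0.001, 0.2] | long tail of rare codes |
| vitals | 4 Gaussians (HR, SBP, DBP, BMI) | category sizes |
| missing records | 22.8% with 1–3 missing pertinent values | 27,521 of 120,739 incomplete |

Class signal is planted as odds multipliers on 30 condition indicators for
stages 4–5 (×4), a further 15 for stage 5 (×3), and vital-sign shifts of
0.8 SD (stages 4–5) plus 0.5 SD (stage 5). No feature-level effect sizes
are documented anywhere for the real data; these defaults were chosen once
to make the imbalance phenomenon realistic — a plain classifier misses
most minority records while the signal is strong enough that imbalance-aware
methods can recover them — and are not calibrated to CKD biology. The
default test scale (~20,000 records before filtering) keeps the 20-repeat
experiment protocols tractable on a single CPU while preserving the
imbalance ratio; `n_patients = 13111` reproduces the full scale.

Stage is sampled **per record**, not per patient, so record-level
proportions are directly controllable; disease progression over a
patient's visits is out of scope. Missingness is MCAR, matching the
complete-case analysis downstream (incomplete records are dropped, never
imputed). Race/ethnicity are integer codes, adequate for tree ensembles.

`generate_reference_cohort()` additionally **enforces** the emulated
cohort's exact per-year, per-stage complete-record counts (93,218 complete
records; 120,739 with the incomplete ones), with features still synthetic.
The per-year counts are obtained by differencing the cumulative
year-window totals of the documented distribution; the differences
reproduce both the overall total and the per-stage sums exactly. This
replica exists to validate counting, splitting and partition-size logic
against fixed numbers — its feature dimension is configurable and count
checks use a small one for speed.

### What passing tests do and do not show

The generator produces independent records with conditionally independent
features given stage. Real visit records violate this in ways the tests
therefore cannot probe: repeated visits of one patient are correlated,
comorbidities co-occur in networks, coding practices drift over calendar
years, and missingness is informative. Passing the directional property
(hierarchical meta-classification recovering minority-stage sensitivity
that the baseline misses) demonstrates the mechanism under controlled
imbalance — it does not certify performance levels on any real cohort.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run the comparison protocols
at the generator's default test scale (~20,000 records, ~15,800 after
complete-case filtering, 20 repeats) and the reference replica with a
12-condition feature space for count checks. These sizes are the package's
own choice of a desk-scale experiment; all protocols accept full-scale
inputs unchanged.

## Known limitations

* Refinement quality for stage 5 is bounded by the weak stage-4/5 contrast
  in the default synthetic signal; the hierarchical structure recovers the
  combined class well before grading it.
* The meta-classifier's conditional tables are estimated on potentially
  optimistic base labels unless `out_of_fold = TRUE`.
* No probability outputs, no ROC analysis, no significance testing between
  strategies, and no ordinal modelling of stage order.
* The generator makes no attempt at realistic diagnosis vocabularies or
  progression dynamics; it is an imbalance testbed, not a disease model.
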
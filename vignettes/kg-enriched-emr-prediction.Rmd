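---
title: "Knowledge-graph enrichment of EMR vectors: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph enrichment of EMR vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

General-practice electronic medical records (EMRs) mix structured entries
(ATC drug codes, ICPC-2 encounter codes) with short free-text notes full of
abbreviations and specialist vocabulary.  A classifier predicting whether a
patient will be hospitalized can read this material as a bag of words, but
the raw tokens fragment clinically coherent signals: the same condition
surfaces as half a dozen different expressions, each individually rare.
Knowledge graphs — drug and encounter terminologies, drug-interaction
ontologies, and cross-domain resources with category hierarchies — offer a
way to aggregate those fragments into concepts.  This package implements
that enrichment end to end, together with the statistical machinery needed
to decide whether it actually helps.

## The representation

Each patient $i$ is a vector $x^i = V^i \oplus C^i$:

* $V^i$ is a **bag of words**.  Tokens (Unicode letter/digit runs of length
  at least 2, after NFC normalization and lowercasing, hyphens split) are
  prefixed with the field they came from (`obs:`, `fh:`, ...), so the same
  word in the personal vs. family history yields two distinct features.
  Values are raw counts.
* $C^i$ is a **bag of concepts** extracted from five sources: ATC
  super-classes at chosen depth levels (level 1 = direct parent), the single
  ICPC-2 super-class per code, NDF-RT property–concept pairs
  (`may_treat`, `may_prevent`, `CI_with`) reached through the UMLS CUI
  annotated on the ATC code, Wikidata-like drug relations (subject-has-role,
  significant-drug-interaction, medical-condition-treated; drug nodes
  resolved by ATC code, then CUI, then RxNorm), and DBpedia-like *subjects*
  (categories) of entities mentioned in free text.  Concept features are
  named `SOURCE[:property]=label` and carry occurrence counts.

**The labelling rule.**  For hospitalized patients only consultations
*before* the hospitalization contribute (plus the static, lifelong fields);
for non-hospitalized patients everything contributes.  A hospitalized
patient whose hospitalization precedes every consultation carries no
usable evidence and is excluded with a warning.

**Text-based extraction** runs in two steps.  A pluggable annotator maps
text to entity mentions; the shipped dictionary annotator expands
abbreviation keys token-wise, then matches surface forms longest-first
without overlaps on the normalized text.  Mentioned entities then pass a
two-constraint medical-domain filter mirroring a federated category query:
(1) at least one `dcterms:subject` category of the entity must reach a seed
category (disease, health, medical genetics, medicine, urgency, treatment,
anatomy, addiction, bacteria) through the `skos:broader` closure, and
(2) the entity must be `owl:sameAs`-linked to a node typed with an allowed
medical class.  The qualifying subjects — not the entities — become the
concept features, which is what aggregates many rare surface forms into one
column.  The closure walk is cycle-safe and bounded (default depth 10;
live category graphs contain cycles).

## Feature-set variants

Twenty named variants control which sources enrich $C$, which fields are
read, and how concepts are selected.  The starred family (`+s*`, `+s*T`,
`+s*m`, ...) reads only fields about the patient's own record; the
unstarred DBpedia family adds family history, past problems and symptoms.
Word features always use the scope of the active family, so variants within
a family differ only in the concept block; across families the scope itself
differs, and comparisons confound the two (documented, deliberate).  The
machine-selected variants are `+s*m`/`+sm` (per-fold lasso selection) and
the derived `+sm∩` / `+sm∪` (concepts selected in *all* / in *at least one*
of the outer folds).  The intersection/union notation is read
set-theoretically everywhere: ∩ means *all* annotators or folds, ∪ means
*at least one*.

The Wikidata property IDs for "significant drug interaction" and "medical
condition treated" are easy to confound, so relations are keyed by *label*
(`role`, `interaction`, `condition`) and the property IRIs are remappable
per call.

## Concept selection

Inside each outer training fold, an L1-penalized logistic model is fit on
the full standardized matrix and concepts with nonzero coefficients
(|β| > 1e−8) are selected:

* Columns are scaled to unit variance **without centering**, preserving
  sparsity.
* The penalty applies uniformly to word and concept columns.  An earlier
  design kept word columns unpenalized so that concepts must add signal
  beyond the text, but the field-prefixed bag of words has more columns
  than patients; an unpenalized word block then saturates the binomial
  likelihood and no concept can ever enter.  Under the uniform penalty the
  words still compete with the concepts for the same signal, which is the
  intended denoising.
* The penalty strength is chosen by inner cross-validation (at least 3
  folds; 20 log-spaced values) at the minimum of the cross-validated
  deviance — the usual cross-validated-lasso behavior.  The
  one-standard-error rule is available (`lambda_choice = "lambda.1se"`)
  when a sparser set is preferred.
* Selection is read **only off concept columns**; word features are never
  reported as selected and never removed.  A consequence of the uniform
  penalty is that duplicating a word column can perturb the selected
  concept set slightly; the guaranteed invariant is the weaker one (word
  columns never selected, never dropped).

## Evaluation

The experiment is a stratified nested cross-validation (outer $K = 10$,
inner $L$) with random hyperparameter search: logistic regression
($C \sim$ Exp(1), penalty l1/l2, implemented as a single-lambda penalized
fit with $\lambda = 1/(Cn)$), random forests (trees 10–500, depth 5–30,
node size 1–30; a maximum-leaf-node cap has no equivalent in the ranger
backend and is not searched), and SVC (cost and gamma
$\sim$ Exp(1); linear, RBF or polynomial kernel; the margin is used for
ranking scores).  The inner-loop model-selection criterion is mean inner-fold
F1; ties break to the first-drawn candidate.  Two protocol presets are
recorded: `screen` ($K=10, L=2$, 7 iterations) and `strict` ($K=10, L=3$,
150 iterations).

Reported quantities:

* **Pooled F** $= 2\,TP_f / (2\,TP_f + FP_f + FN_f)$ with confusion counts
  summed over the $K$ folds (reduces to ordinary F1 at $K = 1$).
* Per-fold precision, recall, F1 and AUC, with means and sample standard
  deviations.
* The **variance-corrected dependent t-test** for per-fold metric
  differences $x_j$: $t = \bar{x} / \sqrt{(1/n + n_2/n_1)\,\hat\sigma^2}$
  with $n_1 = K - 1$ training folds and $n_2 = 1$ test fold, two-sided
  p-values on $n - 1$ degrees of freedom.  The statistic is undefined for
  constant differences; comparing a pipeline against itself is reported as
  `identical` rather than as evidence.
* **Krippendorff's α** (nominal) from the coincidence matrix, missing cells
  excluded, and the centered-cosine **correlation distance** (0 = perfect
  agreement, 1 = none, 2 = perfect disagreement) for comparing annotator
  vectors, including the per-fold machine "annotators" M_1..M_K and their
  union row U_1.
* The two **risk-communication figures**: absolute reduction in percentage
  points and the relative gain rounded to whole percent (61% → 44% gives
  17 points and 28%).

## The synthetic cohort

No clinical database ships with the package; a generator emulates the
statistical structure the analysis assumes, at a balanced design of 714
hospitalized / 732 non-hospitalized patients.

* **Label model.**  Each patient is exposed to each of the planted "signal"
  concepts independently (default probability 0.35).  Hospitalization is
  Bernoulli with log-odds = intercept + Σ (weight × exposure); default
  weights are 2 per concept and the intercept centers the linear predictor.
  Exact class counts are reached by accept–reject sampling, mirroring a
  balanced designed cohort rather than natural prevalence.
* **Why enrichment can win.**  Each signal concept is a DBpedia-like
  category with several entities, each with its own surface form; an
  exposed patient mentions a random subset of them.  The bag of words sees
  many rare tokens; the bag of concepts aggregates them into one column per
  category.  Noise categories (weight 0), entities failing the domain
  filter, and abbreviation substitution (default rate 0.2) are planted
  alongside.
* **What it does not emulate.**  Real French clinical language (filler text
  is Zipf-distributed ASCII tokens; only two French worked-example surface
  forms are included verbatim), label leakage through codes (ATC/ICPC-2
  codes are drawn independently of the outcome, so code-based variants are
  null enrichments here), negation and misspelling, and longitudinal
  dynamics beyond the truncation rule.  Passing tests therefore certify
  the machinery and its statistical behavior, not clinical performance.
* Field lengths and vocabulary sizes have no accessible reference
  distribution; the defaults (vocabulary 300, 3–10 consultations, 3–8
  tokens per consultation field) are stand-ins chosen once for plausible
  sparsity.

## Problem sizes used by the shipped checks

The packaged experiment (also what `scripts/acceptance.R` reruns) evaluates
baseline vs. `+sm` vs. `+sm∪` under logistic regression on the full
1,446-patient synthetic cohort with the `screen` protocol: all six planted
concepts are recovered in every outer fold and the enrichment improves
pooled F by several points with a strongly significant corrected t.  The
type-I calibration study uses 200 reduced cohorts (120 patients, 20 noise
concepts, zero planted effects, $K = 10$).

A finding worth stating plainly: under zero planted effects the lasso
usually selects nothing, the enriched pipeline then *coincides exactly*
with the baseline in most folds, and the corrected t-test — already
conservative by construction — almost never rejects.  Its empirical size in
the calibration study is far below the nominal 5%.  The test's type-I error
is controlled (it is not anti-conservative), but it is not *calibrated* at
desk scale; on real data, where selections are never empty, the per-fold
differences are continuous and the test operates closer to its nominal
behavior.

## Degenerate inputs and numerical conventions

Precision is 0 when nothing is predicted positive; F1 is 0 when its
denominator vanishes; the pooled F raises an error when no fold produces
any TP/FP/FN.  Zero-variance columns are excluded from the penalized fit
(they can never be selected).  Absent graph nodes yield empty extractions
with a warning, not an error — except an ICPC-2 code with two asserted
super-classes, which signals a corrupted hierarchy and raises.  All
randomness funnels through one master seed per run; per-stage seeds are
derived arithmetically so stages can be rerun independently.
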
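# kgemr — knowledge-graph enrichment of EMR vectors for hospitalization prediction

General-practice electronic medical records (EMRs) carry most of their
signal in short, abbreviation-heavy free text plus structured drug (ATC)
and encounter (ICPC-2) codes.  `kgemr` asks a concrete question: does
enriching a bag-of-words representation of such records with concepts from
knowledge graphs improve the prediction of a patient's hospitalization, and
which concepts are worth keeping?

For patient *i* the representation is the concatenation

x<sup>i</sup> = V<sup>i</sup> ⊕ C<sup>i</sup>

where V<sup>i</sup> is a field-prefixed word-count vector and C<sup>i</sup>
a concept-count vector extracted from five sources: ATC super-classes
(e.g. C01DA38 → C01DA → C01D → C01), the single ICPC-2 super-class per
code, NDF-RT drug relations (`may_treat`, `may_prevent`, `CI_with`,
e.g. atorvastatin —CI_with→ Pregnancy), Wikidata-like drug properties, and
DBpedia-like category subjects of entities found in free text by a
dictionary annotator with abbreviation expansion, filtered to the medical
domain by a two-constraint category/type query.  Concept features are
denoised by L1-penalized logistic selection run inside the inner loop of a
nested cross-validation; per-fold selections are combined into union
(`+sm∪`, selected in ≥1 fold) and intersection (`+sm∩`, selected in all
folds) sets.  Variants are compared with the pooled cross-validation F

F<sub>tp,fp</sub> = 2·TP<sub>f</sub> / (2·TP<sub>f</sub> + FP<sub>f</sub> + FN<sub>f</sub>)

(confusion counts summed over the K = 10 outer folds) and with the
variance-corrected dependent t-test
t = x̄ / √((1/n + n₂/n₁)·σ̂²) for per-fold metric differences.
Krippendorff's α (nominal) and the centered-cosine correlation distance
quantify agreement between annotators — human or the per-fold machine
"annotators" induced by feature selection.

Clinical EMR databases of this kind are access-restricted, so the package
ships a synthetic-cohort module: RDF fixtures (Turtle) for all five graphs
and a cohort generator that plants concept effects with known log-odds
weights into a balanced cohort of 714 hospitalized / 732 non-hospitalized
patients.  Every pipeline stage is testable offline, and parameter-recovery
of the planted concepts is part of the test suite.

## Worked example

```r
library(kgemr)

fixture <- generate_kg_fixture(fixture_spec(seed = 42))
cohort  <- generate_cohort(cohort_config(seed = 42), fixture)   # 714 / 732

d_base <- assemble_design_matrix(cohort, fixture, "baseline")
d_sm   <- assemble_design_matrix(cohort, fixture, "+sm")
proto  <- protocol_preset("screen", seed = 42)                  # K=10, L=2

r_base <- nested_cv(d_base, proto, "lr")
r_sm   <- nested_cv(d_sm,   proto, "lr", selection_mode = "lasso")
print(r_base)
#> <kgemr_cv_result 'baseline' (lr): pooled F = 0.7490, mean F1 = 0.7482>
print(r_sm)
#> <kgemr_cv_result '+sm' (lr): pooled F = 0.8293, mean F1 = 0.8292>

corrected_ttest(r_sm$metrics$F1, r_base$metrics$F1, n1 = 9, n2 = 1)[c("t", "p")]
#> $t
#> [1] 8.364241
#> $p
#> [1] 1.548252e-05
```

The enrichment lifts the pooled F from 0.749 to 0.829 because the planted
concept categories aggregate many individually rare surface forms into
single columns, and the corrected t-test (which inflates the variance to
account for overlapping training sets across folds) confirms the per-fold
F1 gain is systematic.  `fold_union(r_sm$selections)` lists the concepts
selected in at least one fold — on this cohort a set of 17 containing all
six planted categories (each selected in 10/10 folds), the rest being noise
categories picked up in isolated folds.

The same experiment runs end to end, with artifacts and a manifest, via

```r
report <- run_pipeline(run_config("run1", variants = c("baseline", "+sm", "+sm∪"),
                                  seed = 42))
```

or from a shell through the thin wrapper `inst/exec/kgemr`
(`kgemr run --config cfg.yaml --seed 42`).

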
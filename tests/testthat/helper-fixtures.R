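# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tiny_fixture <- function() cached("tiny_fixture", {
  generate_kg_fixture(fixture_spec(
    n_atc_chains = 3, n_icpc2 = 4, n_ndfrt_drugs = 2, n_wikidata_drugs = 3,
    n_signal_concepts = 3, n_entities_per_signal = 3, n_noise_concepts = 5,
    n_entities_per_noise = 2, n_excluded_entities = 4, seed = 101))
})

tiny_cohort <- function() cached("tiny_cohort", {
  generate_cohort(cohort_config(
    n_hospitalized = 20, n_not_hospitalized = 20, vocab_size_words = 40,
    n_signal_concepts = 3, n_noise_concepts = 5, effect_sizes = rep(2, 3),
    seed = 202), tiny_fixture())
})

# mid-size cohort for selection / CV behavior tests
mid_cohort <- function() cached("mid_cohort", {
  generate_cohort(cohort_config(
    n_hospitalized = 80, n_not_hospitalized = 80, vocab_size_words = 60,
    n_signal_concepts = 3, n_noise_concepts = 5, effect_sizes = rep(2.5, 3),
    consultations_range = c(3, 6), seed = 303), tiny_fixture())
})

mid_designs <- function() cached("mid_designs", {
  list(baseline = assemble_design_matrix(mid_cohort(), tiny_fixture(), "baseline"),
       sm = assemble_design_matrix(mid_cohort(), tiny_fixture(), "+sm"))
})
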
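# Feature-set variant registry.
#
# Each variant names which knowledge sources enrich the concept block, which
# EMR fields are read, and how concepts are selected.  The starred family
# ("+s*...") reads only fields related to the patient's own record; the
# unstarred DBpedia family adds family history, past health problems and
# symptoms.  Word features always use the field scope of the active variant
# family, so within a family the variants differ only in the concept block.

SSTAR_SCOPE <- c("personal_history", "allergies", "environmental_factors",
                 "current_problems", "reasons", "diagnoses", "drugs",
                 "care_procedures", "prescription_reasons", "observations")
FULL_SCOPE <- c(SSTAR_SCOPE, "family_history", "past_problems", "symptoms")

manual_concept_features <- function() paste0("DBPEDIA=", MANUAL_CONCEPT_LABELS)

# canonical variant names; ∩ / ∪ are the set intersection / union
# signs, − (minus sign) in "+c1-2" is accepted as an alias of "-"
variant_table <- function() {
  v <- function(name, sources, scope, mode, whitelist = NULL)
    list(name = name, sources = sources, field_scope = scope,
         selection_mode = mode, concept_whitelist = whitelist)
  list(
    v("baseline", list(), FULL_SCOPE, "none"),
    v("+t", list(icpc2 = TRUE), FULL_SCOPE, "none"),
    v("+c1", list(atc_levels = 1L), FULL_SCOPE, "none"),
    v("+c1-2", list(atc_levels = c(1L, 2L)), FULL_SCOPE, "none"),
    v("+c2", list(atc_levels = 2L), FULL_SCOPE, "none"),
    v("+d_prevent", list(ndfrt_props = "may_prevent"), FULL_SCOPE, "none"),
    v("+d_treat", list(ndfrt_props = "may_treat"), FULL_SCOPE, "none"),
    v("+d_CI", list(ndfrt_props = "CI_with"), FULL_SCOPE, "none"),
    v("+wa", list(wd_relations = "role"), FULL_SCOPE, "none"),
    v("+wi", list(wd_relations = "interaction"), FULL_SCOPE, "none"),
    v("+wm", list(wd_relations = "condition"), FULL_SCOPE, "none"),
    v("+s", list(dbpedia = TRUE), FULL_SCOPE, "manual_list",
      manual_concept_features()),
    v("+s*", list(dbpedia = TRUE), SSTAR_SCOPE, "manual_list",
      manual_concept_features()),
    v("+s*T", list(dbpedia = TRUE), SSTAR_SCOPE, "none"),
    v("+s*∩", list(dbpedia = TRUE), SSTAR_SCOPE, "manual_list"),
    v("+s*∪", list(dbpedia = TRUE), SSTAR_SCOPE, "manual_list"),
    v("+s*m", list(dbpedia = TRUE), SSTAR_SCOPE, "lasso"),
    v("+sm", list(dbpedia = TRUE), FULL_SCOPE, "lasso"),
    v("+sm∩", list(dbpedia = TRUE), FULL_SCOPE, "manual_list"),
    v("+sm∪", list(dbpedia = TRUE), FULL_SCOPE, "manual_list"))
}

#' Registered feature-set variant names
#' @return character vector of the 20 canonical variant names.
#' @export
feature_set_names <- function() {
  vapply(variant_table(), `[[`, "", "name")
}

#' Look up a feature-set variant
#'
#' @param name a registered variant name (see [feature_set_names()]); the
#'   Unicode minus sign is accepted in `"+c1-2"`.
#' @param concept_whitelist optional concept feature names restricting the
#'   concept block; required at matrix-assembly time for the derived
#'   intersection / union variants, whose whitelists come from annotators or
#'   from per-fold feature selection.
#' @return list of class `kgemr_feature_set` with fields `name`, `sources`,
#'   `field_scope`, `selection_mode`, `concept_whitelist`.
#' @export
feature_set_spec <- function(name, concept_whitelist = NULL) {
  if (inherits(name, "kgemr_feature_set")) return(name)
  name <- gsub("−", "-", name)
  tab <- variant_table()
  hit <- which(vapply(tab, `[[`, "", "name") == name)
  if (!length(hit)) stop("unknown feature-set variant: ", name)
  spec <- tab[[hit]]
  if (!is.null(concept_whitelist)) spec$concept_whitelist <- concept_whitelist
  class(spec) <- "kgemr_feature_set"
  spec
}
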
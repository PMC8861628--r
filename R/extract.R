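# Concept extraction from the knowledge graphs.
#
# Every operation returns "concept atoms": provenance-tagged feature units
# (source, optional property, concept IRI, preferred label, optional
# hierarchy depth, occurrence count).  Atom feature names follow the scheme
# "SOURCE=label" or "SOURCE:property=label".

concept_atoms <- function(source = character(), property = NA_character_,
                          concept = character(), label = character(),
                          depth = NA_integer_, count = 1L) {
  n <- length(concept)
  data.frame(source = rep_len(source, n), property = rep_len(property, n),
             concept = concept, label = rep_len(label, n),
             depth = rep_len(as.integer(depth), n),
             count = rep_len(as.integer(count), n), stringsAsFactors = FALSE)
}

empty_atoms <- function() concept_atoms()

# Sum counts of identical (source, property, concept) atoms.
aggregate_atoms <- function(atoms) {
  if (!nrow(atoms)) return(atoms)
  key <- paste(atoms$source, atoms$property, atoms$concept, sep = "\r")
  agg <- rowsum(atoms$count, key)
  first <- atoms[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(agg[match(paste(first$source, first$property,
                                            first$concept, sep = "\r"),
                                      rownames(agg)), 1])
  rownames(first) <- NULL
  first
}

#' Feature names of concept atoms
#' @param atoms a concept-atom data frame.
#' @return character vector, `"SOURCE=label"` or `"SOURCE:property=label"`.
#' @export
atom_feature_names <- function(atoms) {
  ifelse(is.na(atoms$property),
         paste0(atoms$source, "=", atoms$label),
         paste0(atoms$source, ":", atoms$property, "=", atoms$label))
}

#' Transitive ancestors via a relation
#'
#' Breadth-first walk over `relation` edges up to `max_depth`, excluding the
#' start node; cycle-safe via a visited set (live category graphs contain
#' cycles).
#'
#' @param graph an [rdf_graph()].
#' @param start node IRI.
#' @param relation predicate IRI (e.g., `rdfs:subClassOf`, `skos:broader`).
#' @param max_depth maximum number of hops (>= 1).
#' @return character vector of ancestor IRIs; empty (with a warning) when the
#'   start node has no outgoing `relation` edge and is absent from the graph.
#' @export
broader_closure <- function(graph, start, relation, max_depth = 10) {
  stopifnot(max_depth >= 1)
  if (!start %in% graph$s && !start %in% graph$o) {
    warning("node not present in graph: ", start)
    return(character())
  }
  visited <- character()
  frontier <- start
  for (d in seq_len(max_depth)) {
    nxt <- unique(rdf_match(graph, s = frontier, p = relation)$o)
    nxt <- setdiff(nxt, c(visited, start))
    if (!length(nxt)) break
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  visited
}

#' ATC super classes at selected depth levels
#'
#' Level 1 is the direct super class, level 2 its super class, and so on
#' (parent-first numbering, matching the tenitramine chain C01DA38 -> C01DA
#' -> C01D -> C01).
#'
#' @param fixture a `kgemr_fixture` (its `ATC` graph is used).
#' @param code an ATC code string.
#' @param levels set of depth levels (positive integers).
#' @return concept atoms with `depth` recorded; empty (with a warning) when
#'   the code is not in the graph.
#' @export
atc_ancestors <- function(fixture, code, levels = 1L) {
  stopifnot(all(levels >= 1))
  g <- fixture$graphs$ATC
  node <- paste0("urn:kg:atc:", code)
  if (!node %in% g$s && !node %in% g$o) {
    warning("ATC code not in graph: ", code)
    return(empty_atoms())
  }
  chain <- character()
  cur <- node
  repeat {
    parent <- rdf_objects(g, s = cur, p = kg_iri$subclassof)
    if (!length(parent)) break
    chain <- c(chain, parent[[1]])
    cur <- parent[[1]]
    if (length(chain) > 50) stop("ATC hierarchy deeper than 50: cycle?")
  }
  lv <- sort(unique(as.integer(levels)))
  lv <- lv[lv <= length(chain)]
  if (!length(lv)) return(empty_atoms())
  concept_atoms(source = "ATC", concept = chain[lv],
                label = vapply(chain[lv], function(i) node_label(g, i), ""),
                depth = lv)
}

#' The single ICPC-2 super class of a code
#'
#' The ICPC-2 hierarchy is shallow: each code has at most one direct super
#' class.  Two asserted super classes signal a corrupted graph and raise an
#' error.
#'
#' @param fixture a `kgemr_fixture`.
#' @param code an ICPC-2 code string.
#' @return concept atoms of length 0 or 1, source `ICPC2`.
#' @export
icpc2_ancestor <- function(fixture, code) {
  g <- fixture$graphs$ICPC2
  node <- paste0("urn:kg:icpc2:", code)
  if (!node %in% g$s && !node %in% g$o) {
    warning("ICPC-2 code not in graph: ", code)
    return(empty_atoms())
  }
  parent <- unique(rdf_objects(g, s = node, p = kg_iri$subclassof))
  if (length(parent) > 1)
    stop("ICPC-2 invariant violated: ", code, " has ", length(parent),
         " direct super classes")
  if (!length(parent)) return(empty_atoms())
  concept_atoms(source = "ICPC2", concept = parent,
                label = node_label(g, parent))
}

NDFRT_PROPS <- c(may_treat = "may_treat", may_prevent = "may_prevent",
                 CI_with = "ci_with")

#' NDF-RT property-concept pairs for a drug
#'
#' The drug is resolved through the UMLS CUI annotated on its ATC code
#' (`umls:cui` in the ATC graph); the feature identity is the
#' property-concept pair.
#'
#' @param fixture a `kgemr_fixture`.
#' @param atc_code ATC code of the prescribed drug.
#' @param properties subset of `c("may_treat", "may_prevent", "CI_with")`.
#' @return concept atoms, source `NDFRT`, `property` filled.
#' @export
ndfrt_pairs <- function(fixture, atc_code,
                        properties = c("may_treat", "may_prevent", "CI_with")) {
  properties <- match.arg(properties, names(NDFRT_PROPS), several.ok = TRUE)
  atc <- fixture$graphs$ATC
  ndf <- fixture$graphs$NDFRT
  cui <- rdf_objects(atc, s = paste0("urn:kg:atc:", atc_code), p = kg_iri$cui)
  if (!length(cui)) {
    warning("no UMLS CUI on ATC code: ", atc_code)
    return(empty_atoms())
  }
  drug <- unique(rdf_match(ndf, p = kg_iri$cui, o = cui)$s)
  if (!length(drug)) return(empty_atoms())
  out <- list()
  for (prop in properties) {
    objs <- unique(rdf_objects(ndf, s = drug, p = kg_iri[[NDFRT_PROPS[[prop]]]]))
    if (length(objs))
      out[[prop]] <- concept_atoms(source = "NDFRT", property = prop,
                                   concept = objs,
                                   label = vapply(objs, function(i)
                                     node_label(ndf, i), ""))
  }
  if (!length(out)) return(empty_atoms())
  do.call(rbind, out)
}

WD_RELATIONS <- c(role = "wd_role", interaction = "wd_interact",
                  condition = "wd_condition")

#' Wikidata-like property-concept pairs for a drug
#'
#' The drug node is resolved by trying its ATC code first, then the UMLS CUI,
#' then the RxNorm CUI.  Relations are keyed by label --- `role` ("subject
#' has role"), `interaction` ("significant drug interaction"), `condition`
#' ("medical condition treated") --- and the property IRIs can be remapped
#' via `prop_iris` for endpoints with different identifiers.
#'
#' @param fixture a `kgemr_fixture`.
#' @param atc,cui,rxnorm drug identifiers; at least one must be non-`NA`.
#' @param relations subset of `c("role", "interaction", "condition")`.
#' @param prop_iris named list overriding the relation property IRIs.
#' @return concept atoms, source `WIKIDATA`, `property` filled with the
#'   relation label.
#' @export
wikidata_pairs <- function(fixture, atc = NA, cui = NA, rxnorm = NA,
                           relations = c("role", "interaction", "condition"),
                           prop_iris = NULL) {
  relations <- match.arg(relations, names(WD_RELATIONS), several.ok = TRUE)
  if (all(is.na(c(atc, cui, rxnorm))))
    stop("at least one of atc / cui / rxnorm must be given")
  g <- fixture$graphs$WIKIDATA
  node <- character()
  for (id in list(c(kg_iri$wd_atc, atc), c(kg_iri$wd_cui, cui),
                  c(kg_iri$wd_rxnorm, rxnorm))) {
    if (!is.na(id[2])) node <- unique(rdf_match(g, p = id[1], o = id[2])$s)
    if (length(node)) break
  }
  if (!length(node)) {
    warning("no Wikidata drug resolvable from the given identifiers")
    return(empty_atoms())
  }
  out <- list()
  for (rel in relations) {
    iri <- (prop_iris[[rel]] %||% kg_iri[[WD_RELATIONS[[rel]]]])
    objs <- unique(rdf_objects(g, s = node, p = iri))
    if (length(objs))
      out[[rel]] <- concept_atoms(source = "WIKIDATA", property = rel,
                                  concept = objs,
                                  label = vapply(objs, function(i)
                                    node_label(g, i), ""))
  }
  if (!length(out)) return(empty_atoms())
  do.call(rbind, out)
}

#' Medical-domain subjects of mentioned entities
#'
#' Applies the two-constraint filter of the federated category query: an
#' entity contributes a subject when (1) that subject's `skos:broader`
#' closure (the subject included) meets a seed category, and (2) the entity
#' is `owl:sameAs`-linked to a node carrying at least one allowed
#' `rdf:type`.  Each mention of a passing entity contributes each of its
#' qualifying subjects once.
#'
#' @param mentions a mention data frame from [annotate_text()].
#' @param fixture a `kgemr_fixture`.
#' @param seed_categories category IRIs anchoring the medical domain;
#'   defaults to the fixture's.
#' @param allowed_classes class IRIs allowed on the sameAs counterpart;
#'   defaults to the fixture's.
#' @param max_depth closure depth bound for constraint 1.
#' @return concept atoms, source `DBPEDIA`, counts accumulated over mentions.
#' @export
dbpedia_candidate_subjects <- function(mentions, fixture,
                                       seed_categories = fixture$seed_categories,
                                       allowed_classes = fixture$allowed_classes,
                                       max_depth = 10) {
  g <- fixture$graphs$DBPEDIA
  if (!any(g$p == kg_iri$subject) || !any(g$p == kg_iri$broader))
    stop("DBPEDIA fixture lacks subject/broader edges; cannot apply the filter")
  if (!nrow(mentions)) return(empty_atoms())
  out <- list()
  for (ent in unique(mentions$iri)) {
    n_mention <- sum(mentions$iri == ent)
    subjects <- unique(rdf_objects(g, s = ent, p = kg_iri$subject))
    if (!length(subjects)) next
    qual <- subjects[vapply(subjects, function(su) {
      anc <- c(su, suppressWarnings(
        broader_closure(g, su, kg_iri$broader, max_depth)))
      any(anc %in% seed_categories)
    }, TRUE)]
    if (!length(qual)) next
    same <- rdf_objects(g, s = ent, p = kg_iri$sameas)
    typed <- length(same) > 0 &&
      any(rdf_match(g, s = same, p = kg_iri$rdftype)$o %in% allowed_classes)
    if (!typed) next
    out[[ent]] <- concept_atoms(source = "DBPEDIA", concept = qual,
                                label = vapply(qual, function(i)
                                  node_label(g, i), ""),
                                count = n_mention)
  }
  if (!length(out)) return(empty_atoms())
  aggregate_atoms(do.call(rbind, out))
}

#' Write per-patient extraction results as JSON lines
#'
#' One JSON object per patient, keyed by `patient_id`, with the concept
#' atoms and their counts.  Patients with no pre-hospitalization evidence
#' are skipped with a warning.
#'
#' @param cohort a `kgemr_cohort`.
#' @param fixture a `kgemr_fixture`.
#' @param variant a variant name or [feature_set_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_extractions <- function(cohort, fixture, variant, path) {
  variant <- feature_set_spec(variant)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (pid in cohort$patients$patient_id) {
    rec <- withCallingHandlers(aggregate_record(cohort, pid),
                               warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(rec)) {
      warning("skipping patient ", pid, ": no pre-hospitalization evidence")
      next
    }
    atoms <- extract_all(rec, fixture, variant)
    writeLines(jsonlite::toJSON(
      list(patient_id = pid,
           atoms = atoms[, c("source", "property", "concept", "label", "count")]),
      auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' Extract all concept atoms of a patient under a feature-set variant
#'
#' Dispatches to the code-based and text-based extraction operations that the
#' variant enables, on the fields inside the variant's scope, and accumulates
#' occurrence counts per atom.  The record must already be aggregated under
#' the labelling rule (see [aggregate_record()]).
#'
#' @param record an aggregated record from [aggregate_record()].
#' @param fixture a `kgemr_fixture`.
#' @param variant a [feature_set_spec()] (or a registered variant name).
#' @param annotator optional annotator function overriding the default
#'   [dictionary_annotator()].
#' @return concept atoms with accumulated counts (the patient's bag of
#'   concepts); zero rows for the baseline variant.
#' @export
extract_all <- function(record, fixture, variant, annotator = NULL) {
  if (is.character(variant)) variant <- feature_set_spec(variant)
  src <- variant$sources
  out <- list()
  if (isTRUE(src$icpc2) && length(record$icpc2_codes)) {
    for (code in record$icpc2_codes)
      out[[length(out) + 1]] <- icpc2_ancestor(fixture, code)
  }
  if (!is.null(src$atc_levels) && length(record$atc_codes)) {
    for (code in record$atc_codes)
      out[[length(out) + 1]] <- atc_ancestors(fixture, code, src$atc_levels)
  }
  if (!is.null(src$ndfrt_props) && length(record$atc_codes)) {
    for (code in record$atc_codes)
      out[[length(out) + 1]] <- suppressWarnings(
        ndfrt_pairs(fixture, code, src$ndfrt_props))
  }
  if (!is.null(src$wd_relations) && length(record$atc_codes)) {
    atc_tab <- fixture$atc_codes
    for (code in record$atc_codes) {
      row <- atc_tab[atc_tab$code == code, ]
      cui <- if (nrow(row)) row$cui[1] else NA
      rx <- if (nrow(row)) row$rxnorm[1] else NA
      out[[length(out) + 1]] <- suppressWarnings(
        wikidata_pairs(fixture, atc = code, cui = cui, rxnorm = rx,
                       relations = src$wd_relations))
    }
  }
  if (isTRUE(src$dbpedia)) {
    annotate <- annotator %||% dictionary_annotator(fixture)
    scope <- intersect(variant$field_scope, names(record$texts))
    for (f in scope) {
      mentions <- annotate(record$texts[[f]], f)
      out[[length(out) + 1]] <- dbpedia_candidate_subjects(mentions, fixture)
    }
  }
  atoms <- if (length(out)) aggregate_atoms(do.call(rbind, out)) else empty_atoms()
  if (!is.null(variant$concept_whitelist) && nrow(atoms))
    atoms <- atoms[atom_feature_names(atoms) %in% variant$concept_whitelist, ,
                   drop = FALSE]
  atoms
}
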
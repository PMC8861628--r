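# Synthetic knowledge-graph fixtures.
#
# Miniature stand-ins for the five graphs the extraction stage queries:
# an ATC drug hierarchy (rdfs:subClassOf chains with umls:cui annotations),
# an ICPC-2 hierarchy (one super class per code), NDF-RT drug relations
# (may_treat / may_prevent / CI_with), a Wikidata-like drug graph (identifier
# properties P267 / P2892 / P3345 and three drug relations) and a
# DBpedia-like graph (dcterms:subject, skos:broader category hierarchy,
# owl:sameAs links and rdf:type on the linked entities).

FIELD_CONSULT <- c("reasons", "observations", "symptoms", "diagnoses",
                   "drugs", "care_procedures", "prescription_reasons")
FIELD_STATIC  <- c("personal_history", "family_history", "past_problems",
                   "allergies", "environmental_factors", "current_problems")

#' EMR field names used across the package
#' @return character vector of the 13 field identifiers: 7 per-consultation
#'   free-text fields and 6 static patient-level fields.
#' @export
emr_field_names <- function() c(FIELD_CONSULT, FIELD_STATIC)

FIELD_PREFIX <- c(reasons = "rc", observations = "obs", symptoms = "sym",
                  diagnoses = "dx", drugs = "drg", care_procedures = "proc",
                  prescription_reasons = "rxr", personal_history = "ph",
                  family_history = "fh", past_problems = "pp",
                  allergies = "alg", environmental_factors = "env",
                  current_problems = "cp")

ALLOWED_CLASSES <- paste0("urn:kg:class:", c(
  "dbo-Disease", "dbo-Bacteria", "yago-WikicatViruses",
  "yago-WikicatRetroviruses", "yago-WikicatSurgicalProcedures",
  "yago-WikicatSurgicalRemovalProcedures"))

SEED_CATEGORY_LABELS <- c("disease", "health", "medical genetics", "medicine",
                          "urgency", "treatment", "anatomy", "addiction",
                          "bacteria")

# The 14 manually curated medical-domain categories (oncology through
# emergencies) used by the manual-whitelist feature sets.
MANUAL_CONCEPT_LABELS <- c(
  "Neoplasm stubs", "Oncology", "Radiation therapy",
  "Cardiovascular disease", "Cardiac arrhythmia",
  "Neurovascular disease",
  "Malignant hemopathy", "Autoimmune disease",
  "Medical condition related to obesity",
  "Genetic diseases and disorders",
  "Surgical removal procedures", "Organ failure",
  "Medical emergencies", "Cardiac emergencies")

cat_iri <- function(label) {
  paste0("urn:kg:cat:", gsub("[^A-Za-z0-9]+", "_", label))
}

#' Parameters for the knowledge-fixture generator
#'
#' @param n_atc_chains number of random ATC chains (each of depth 3 below a
#'   level-3 root) in addition to the two worked chains.
#' @param n_icpc2 number of ICPC-2 codes (each with exactly one super class).
#' @param n_ndfrt_drugs number of random NDF-RT drug entries (beyond
#'   atorvastatin).
#' @param n_wikidata_drugs number of Wikidata-like drug entries.
#' @param n_signal_concepts number of DBpedia-like categories that the cohort
#'   generator can plant outcome effects on.
#' @param n_entities_per_signal entities (distinct surface forms) per signal
#'   category; the bag-of-words sees each surface form as a separate rare
#'   token while the bag-of-concepts aggregates them into one category column.
#' @param n_noise_concepts number of medical-domain categories that pass both
#'   extraction constraints but carry no planted effect.
#' @param n_entities_per_noise entities per noise category.
#' @param n_excluded_entities entities that fail one of the two constraints
#'   (off-domain category, or no typed sameAs counterpart) and must never be
#'   returned as candidate subjects.
#' @param abbreviation_fraction fraction of signal/noise surface forms that
#'   also receive an abbreviated dictionary key.
#' @param seed integer seed; the fixture is fully reproducible from it.
#' @return a named list of class `kgemr_fixture_spec`.
#' @export
fixture_spec <- function(n_atc_chains = 12, n_icpc2 = 12, n_ndfrt_drugs = 6,
                         n_wikidata_drugs = 6, n_signal_concepts = 6,
                         n_entities_per_signal = 6, n_noise_concepts = 40,
                         n_entities_per_noise = 2, n_excluded_entities = 10,
                         abbreviation_fraction = 0.3, seed = 1L) {
  spec <- list(n_atc_chains = n_atc_chains, n_icpc2 = n_icpc2,
               n_ndfrt_drugs = n_ndfrt_drugs,
               n_wikidata_drugs = n_wikidata_drugs,
               n_signal_concepts = n_signal_concepts,
               n_entities_per_signal = n_entities_per_signal,
               n_noise_concepts = n_noise_concepts,
               n_entities_per_noise = n_entities_per_noise,
               n_excluded_entities = n_excluded_entities,
               abbreviation_fraction = abbreviation_fraction,
               seed = as.integer(seed))
  counts <- unlist(spec[startsWith(names(spec), "n_")])
  if (any(counts < 0)) stop("fixture spec counts must be >= 0")
  if (n_atc_chains < 1 || n_icpc2 < 1)
    stop("fixture spec below minimal sizes: need >= 1 ATC chain and >= 1 ICPC-2 code")
  if (n_signal_concepts < 1 || n_entities_per_signal < 1)
    stop("fixture spec below minimal sizes: need >= 1 signal concept with >= 1 entity")
  class(spec) <- "kgemr_fixture_spec"
  spec
}

#' Generate a synthetic knowledge-graph fixture
#'
#' Returns the five named RDF graphs plus the surface-form dictionary used by
#' the dictionary annotator.  The fixture always contains the worked examples
#' that anchor the extraction tests: the ATC chain C01DA38 -> C01DA -> C01D ->
#' C01 (tenitramine), the NDF-RT contraindication (atorvastatin, CI_with,
#' Pregnancy), a DBpedia-like entity for "insuffisance cardiaque" with
#' subjects Organ failure and Cardiovascular disease, and one for "kyste"
#' with subject Neoplasm stubs.
#'
#' @param spec a [fixture_spec()].
#' @return an object of class `kgemr_fixture`: list with elements `graphs`
#'   (named list of [rdf_graph()]s: ATC, ICPC2, NDFRT, WIKIDATA, DBPEDIA),
#'   `surface_forms` (data frame: surface, iri), `abbreviations` (data frame:
#'   key, expansion), `entities` (data frame: iri, surface, role,
#'   concept_index), `seed_categories`, `allowed_classes`,
#'   `signal_categories`, `noise_categories`, `manual_concepts`,
#'   `atc_codes`, `icpc2_codes` and the `spec` echo.
#' @export
generate_kg_fixture <- function(spec = fixture_spec()) {
  if (!inherits(spec, "kgemr_fixture_spec")) spec <- do.call(fixture_spec, spec)
  set.seed(spec$seed)

  ## ---- ATC graph -------------------------------------------------------
  atc_node <- function(code) paste0("urn:kg:atc:", code)
  atc <- rdf_graph()
  add_chain <- function(g, codes, labels, cui = NULL, rxnorm = NULL) {
    for (i in seq_along(codes)) {
      g <- rdf_add(g, atc_node(codes[i]), kg_iri$preflabel, labels[i], TRUE)
      if (i < length(codes))
        g <- rdf_add(g, atc_node(codes[i]), kg_iri$subclassof,
                     atc_node(codes[i + 1]))
    }
    leaf <- atc_node(codes[1])
    if (!is.null(cui)) g <- rdf_add(g, leaf, kg_iri$cui, cui, TRUE)
    if (!is.null(rxnorm)) g <- rdf_add(g, leaf, kg_iri$rxnorm, rxnorm, TRUE)
    g
  }
  atc <- add_chain(atc, c("C01DA38", "C01DA", "C01D", "C01"),
                   c("tenitramine", "Organic nitrates used in cardiac disease",
                     "VASODILATORS USED IN CARDIAC DISEASES",
                     "CARDIAC THERAPY DRUGS"),
                   cui = "CUI-TENI")
  atc <- add_chain(atc, c("C10AA05", "C10AA", "C10A", "C10"),
                   c("atorvastatin", "HMG CoA reductase inhibitors",
                     "LIPID MODIFYING AGENTS, PLAIN", "LIPID MODIFYING AGENTS"),
                   cui = "CUI-ATOR", rxnorm = "RX-ATOR")
  leaf_codes <- c("C01DA38", "C10AA05")
  leaf_cuis <- c("CUI-TENI", "CUI-ATOR")
  leaf_rx <- c(NA, "RX-ATOR")
  roots_used <- c("C01", "C10")
  for (i in seq_len(spec$n_atc_chains)) {
    repeat {
      root <- paste0(sample(LETTERS, 1), sprintf("%02d", sample(0:99, 1)))
      if (!root %in% roots_used) break
    }
    roots_used <- c(roots_used, root)
    l4 <- paste0(root, sample(LETTERS, 1))
    l5 <- paste0(l4, sample(LETTERS, 1))
    leaf <- paste0(l5, sprintf("%02d", sample(0:99, 1)))
    cui <- sprintf("CUI%04d", i)
    rx <- if (i %% 2 == 0) sprintf("RX%04d", i) else NA
    atc <- add_chain(atc, c(leaf, l5, l4, root),
                     paste0("atclabel_", c(leaf, l5, l4, root)),
                     cui = cui, rxnorm = if (is.na(rx)) NULL else rx)
    leaf_codes <- c(leaf_codes, leaf)
    leaf_cuis <- c(leaf_cuis, cui)
    leaf_rx <- c(leaf_rx, rx)
  }
  atc_codes <- data.frame(code = leaf_codes, cui = leaf_cuis, rxnorm = leaf_rx,
                          stringsAsFactors = FALSE)

  ## ---- ICPC-2 graph ----------------------------------------------------
  icpc <- rdf_graph()
  chapters <- c("A", "D", "K", "L", "N", "P", "R", "S", "T", "U", "X", "Y")
  icpc_codes <- character(spec$n_icpc2)
  icpc_parent <- character(spec$n_icpc2)
  used <- character()
  for (i in seq_len(spec$n_icpc2)) {
    repeat {
      ch <- sample(chapters, 1)
      code <- paste0(ch, sprintf("%02d", sample(1:99, 1)))
      if (!code %in% used) break
    }
    used <- c(used, code)
    icpc_codes[i] <- code
    icpc_parent[i] <- ch
    node <- paste0("urn:kg:icpc2:", code)
    parent <- paste0("urn:kg:icpc2:", ch)
    icpc <- rdf_add(icpc, node, kg_iri$preflabel, paste0("icpclabel_", code), TRUE)
    icpc <- rdf_add(icpc, node, kg_iri$subclassof, parent)
    if (!parent %in% icpc$s)
      icpc <- rdf_add(icpc, parent, kg_iri$preflabel,
                      paste0("icpcchapter_", ch), TRUE)
  }
  icpc2_codes <- data.frame(code = icpc_codes, parent = icpc_parent,
                            stringsAsFactors = FALSE)

  ## ---- NDF-RT graph ----------------------------------------------------
  ndfrt <- rdf_graph()
  ndf_cond <- function(label) paste0("urn:kg:ndfrt:", gsub("[^A-Za-z0-9]+", "_", label))
  add_ndf_drug <- function(g, name, cui, triples) {
    drug <- paste0("urn:kg:ndfrt:drug_", name)
    g <- rdf_add(g, drug, kg_iri$preflabel, name, TRUE)
    g <- rdf_add(g, drug, kg_iri$cui, cui, TRUE)
    for (tr in triples) {
      g <- rdf_add(g, drug, kg_iri[[tr$prop]], ndf_cond(tr$obj))
      if (!ndf_cond(tr$obj) %in% g$s)
        g <- rdf_add(g, ndf_cond(tr$obj), kg_iri$preflabel, tr$obj, TRUE)
    }
    g
  }
  ndfrt <- add_ndf_drug(ndfrt, "atorvastatin", "CUI-ATOR", list(
    list(prop = "ci_with", obj = "Pregnancy"),
    list(prop = "may_treat", obj = "Hypercholesterolemia")))
  cond_pool <- paste0("ndfcond", sprintf("%02d", 1:12))
  ndf_idx <- sample(seq_len(nrow(atc_codes))[-2], min(spec$n_ndfrt_drugs,
                                                      nrow(atc_codes) - 1))
  for (i in ndf_idx) {
    trs <- list()
    for (prop in c("may_treat", "may_prevent", "ci_with")) {
      n <- sample(0:2, 1)
      if (n > 0) for (obj in sample(cond_pool, n))
        trs <- c(trs, list(list(prop = prop, obj = obj)))
    }
    ndfrt <- add_ndf_drug(ndfrt, paste0("ndfdrug_", atc_codes$code[i]),
                          atc_codes$cui[i], trs)
  }

  ## ---- Wikidata-like graph --------------------------------------------
  wd <- rdf_graph()
  wd_cond <- function(label) paste0("urn:kg:wd:", gsub("[^A-Za-z0-9]+", "_", label))
  wd_pool <- paste0("wdcond", sprintf("%02d", 1:12))
  wd_idx <- sample(seq_len(nrow(atc_codes)),
                   min(spec$n_wikidata_drugs, nrow(atc_codes)))
  for (i in wd_idx) {
    q <- paste0("urn:kg:wd:Q", 1000 + i)
    wd <- rdf_add(wd, q, kg_iri$preflabel, paste0("wddrug_", atc_codes$code[i]), TRUE)
    # at least one identifier; each present independently
    ids <- c(atc = TRUE, cui = runif(1) < 0.7,
             rx = !is.na(atc_codes$rxnorm[i]) && runif(1) < 0.7)
    if (ids[["atc"]]) wd <- rdf_add(wd, q, kg_iri$wd_atc, atc_codes$code[i], TRUE)
    if (ids[["cui"]]) wd <- rdf_add(wd, q, kg_iri$wd_cui, atc_codes$cui[i], TRUE)
    if (ids[["rx"]])  wd <- rdf_add(wd, q, kg_iri$wd_rxnorm, atc_codes$rxnorm[i], TRUE)
    for (prop in c("wd_role", "wd_interact", "wd_condition")) {
      n <- sample(0:2, 1)
      if (n > 0) for (obj in sample(wd_pool, n)) {
        wd <- rdf_add(wd, q, kg_iri[[prop]], wd_cond(obj))
        if (!wd_cond(obj) %in% wd$s)
          wd <- rdf_add(wd, wd_cond(obj), kg_iri$preflabel, obj, TRUE)
      }
    }
  }

  ## ---- DBpedia-like graph ---------------------------------------------
  db <- rdf_graph()
  seed_cats <- cat_iri(paste0("seed_", gsub(" ", "_", SEED_CATEGORY_LABELS)))
  for (i in seq_along(seed_cats))
    db <- rdf_add(db, seed_cats[i], kg_iri$preflabel, SEED_CATEGORY_LABELS[i], TRUE)
  # a non-medical root for the excluded entities
  general_root <- cat_iri("general_topics")
  db <- rdf_add(db, general_root, kg_iri$preflabel, "general topics", TRUE)

  add_category <- function(g, iri, label, root) {
    mid <- cat_iri(paste0("mid_", sub("^urn:kg:cat:", "", root), "_",
                          substr(label, 1, 3)))
    if (!mid %in% g$s) {
      g <- rdf_add(g, mid, kg_iri$preflabel,
                   paste0("mid ", node_label(g, root)), TRUE)
      g <- rdf_add(g, mid, kg_iri$broader, root)
    }
    g <- rdf_add(g, iri, kg_iri$preflabel, label, TRUE)
    g <- rdf_add(g, iri, kg_iri$broader, mid)
    g
  }

  manual_iris <- cat_iri(MANUAL_CONCEPT_LABELS)
  for (i in seq_along(manual_iris))
    db <- add_category(db, manual_iris[i], MANUAL_CONCEPT_LABELS[i],
                       sample(seed_cats[c(1, 4, 6)], 1))

  sig_labels <- paste0("sigcat", sprintf("%02d", seq_len(spec$n_signal_concepts)))
  sig_iris <- cat_iri(sig_labels)
  for (i in seq_along(sig_iris))
    db <- add_category(db, sig_iris[i], sig_labels[i], sample(seed_cats, 1))

  noise_iris <- character(0)
  if (spec$n_noise_concepts > 0) {
    noise_labels <- paste0("noisecat", sprintf("%02d", seq_len(spec$n_noise_concepts)))
    noise_iris <- cat_iri(noise_labels)
    for (i in seq_along(noise_iris))
      db <- add_category(db, noise_iris[i], noise_labels[i], sample(seed_cats, 1))
  }

  # off-domain categories, broader chain outside every seed root
  off_iris <- cat_iri(paste0("offtopic", 1:3))
  for (i in seq_along(off_iris)) {
    db <- rdf_add(db, off_iris[i], kg_iri$preflabel, paste0("offtopic ", i), TRUE)
    db <- rdf_add(db, off_iris[i], kg_iri$broader, general_root)
  }

  ent_rows <- list()
  add_entity <- function(g, iri, surface, subjects, typed = TRUE,
                         type_class = ALLOWED_CLASSES[1], sameas = typed) {
    g <- rdf_add(g, iri, kg_iri$preflabel, surface, TRUE)
    for (su in subjects) g <- rdf_add(g, iri, kg_iri$subject, su)
    if (sameas) {
      en <- sub("^urn:kg:db:", "urn:kg:dben:", iri)
      g <- rdf_add(g, iri, kg_iri$sameas, en)
      if (typed) g <- rdf_add(g, en, kg_iri$rdftype, type_class)
    }
    g
  }

  # worked examples (French surface forms kept verbatim)
  db <- add_entity(db, "urn:kg:db:Insuffisance_cardiaque",
                   "insuffisance cardiaque",
                   cat_iri(c("Organ failure", "Cardiovascular disease")))
  db <- add_entity(db, "urn:kg:db:Kyste", "kyste", cat_iri("Neoplasm stubs"))
  ent_rows[[1]] <- data.frame(iri = "urn:kg:db:Insuffisance_cardiaque",
                              surface = "insuffisance cardiaque",
                              role = "worked", concept_index = NA_integer_)
  ent_rows[[2]] <- data.frame(iri = "urn:kg:db:Kyste", surface = "kyste",
                              role = "worked", concept_index = NA_integer_)

  mk_entities <- function(g, prefix, iris, n_per, role) {
    for (k in seq_along(iris)) {
      for (j in seq_len(n_per)) {
        surface <- sprintf("%s%02dx%02d", prefix, k, j)
        iri <- paste0("urn:kg:db:", surface)
        g <- add_entity(g, iri, surface, iris[k],
                        type_class = sample(ALLOWED_CLASSES, 1))
        ent_rows[[length(ent_rows) + 1]] <<- data.frame(
          iri = iri, surface = surface, role = role, concept_index = k)
      }
    }
    g
  }
  db <- mk_entities(db, "sigterm", sig_iris, spec$n_entities_per_signal, "signal")
  if (length(noise_iris))
    db <- mk_entities(db, "noiseterm", noise_iris, spec$n_entities_per_noise, "noise")

  if (spec$n_excluded_entities > 0) {
    for (j in seq_len(spec$n_excluded_entities)) {
      surface <- sprintf("exclterm%02d", j)
      iri <- paste0("urn:kg:db:", surface)
      if (j %% 2 == 0) {
        # fails constraint 1: off-domain subject
        db <- add_entity(db, iri, surface, sample(off_iris, 1))
      } else {
        # fails constraint 2: medical subject but no typed sameAs counterpart
        db <- add_entity(db, iri, surface,
                         sample(c(sig_iris, noise_iris, manual_iris), 1),
                         typed = FALSE, sameas = j %% 4 == 1)
      }
      ent_rows[[length(ent_rows) + 1]] <- data.frame(
        iri = iri, surface = surface, role = "excluded",
        concept_index = NA_integer_)
    }
  }
  entities <- do.call(rbind, ent_rows)

  ## ---- dictionary ------------------------------------------------------
  surface_forms <- data.frame(surface = entities$surface, iri = entities$iri,
                              stringsAsFactors = FALSE)
  abbrevable <- entities[entities$role %in% c("signal", "noise"), ]
  n_ab <- round(spec$abbreviation_fraction * nrow(abbrevable))
  ab_idx <- if (n_ab > 0) sample(seq_len(nrow(abbrevable)), n_ab) else integer()
  abbreviations <- data.frame(
    key = c("insuf", if (n_ab > 0) paste0("ab", abbrevable$surface[ab_idx])),
    expansion = c("insuffisance", abbrevable$surface[ab_idx]),
    stringsAsFactors = FALSE)

  fx <- list(graphs = list(ATC = atc, ICPC2 = icpc, NDFRT = ndfrt,
                           WIKIDATA = wd, DBPEDIA = db),
             surface_forms = surface_forms, abbreviations = abbreviations,
             entities = entities, seed_categories = seed_cats,
             allowed_classes = ALLOWED_CLASSES,
             signal_categories = sig_iris, noise_categories = noise_iris,
             manual_concepts = manual_iris,
             atc_codes = atc_codes, icpc2_codes = icpc2_codes, spec = spec)
  class(fx) <- "kgemr_fixture"
  fx
}

#' @export
print.kgemr_fixture <- function(x, ...) {
  sizes <- vapply(x$graphs, nrow, 1L)
  cat("<kgemr_fixture>\n  triples:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
      "\n  entities:", nrow(x$entities),
      " surface forms:", nrow(x$surface_forms), "\n")
  invisible(x)
}

#' Write a fixture to disk (Turtle + TSV dictionaries)
#' @param fixture a `kgemr_fixture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fixture$graphs))
    write_turtle(fixture$graphs[[nm]], file.path(dir, paste0(nm, ".ttl")))
  write_tsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(paste(names(df), collapse = "\t"),
                 do.call(paste, c(lapply(df, as.character), sep = "\t"))), con)
  }
  write_tsv(fixture$surface_forms, file.path(dir, "surface_forms.tsv"))
  write_tsv(fixture$abbreviations, file.path(dir, "abbreviations.tsv"))
  meta <- fixture[c("seed_categories", "allowed_classes", "signal_categories",
                    "noise_categories", "manual_concepts")]
  meta$spec <- unclass(fixture$spec)
  jsonlite::write_json(meta, file.path(dir, "fixture_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
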
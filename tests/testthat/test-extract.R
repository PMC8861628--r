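test_that("broader_closure handles leafless nodes, cycles, and depth bounds", {
  g <- rdf_graph(c("urn:a", "urn:b", "urn:c"), rep("urn:rel", 3),
                 c("urn:b", "urn:c", "urn:a"))   # 3-cycle
  expect_setequal(broader_closure(g, "urn:a", "urn:rel"),
                  c("urn:b", "urn:c"))
  expect_equal(broader_closure(g, "urn:a", "urn:rel", max_depth = 1), "urn:b")
  g2 <- rdf_graph("urn:x", "urn:rel", "urn:y")
  expect_length(broader_closure(g2, "urn:y", "urn:rel"), 0)  # leaf
  expect_warning(out <- broader_closure(g2, "urn:zzz", "urn:rel"), "not present")
  expect_length(out, 0)
})

test_that("broader_closure equals a breadth-first oracle on random DAGs", {
  for (seed in 1:20) {
    g <- random_dag(30, p_edge = 0.12, seed = seed)
    starts <- unique(g$s)[1:min(5, length(unique(g$s)))]
    for (st in starts)
      expect_setequal(broader_closure(g, st, "urn:rel", max_depth = 100),
                      oracle_reachable(g, st, "urn:rel"))
  }
})

test_that("broader_closure is monotone under triple addition", {
  g <- random_dag(20, p_edge = 0.1, seed = 3)
  st <- unique(g$s)[1]
  before <- broader_closure(g, st, "urn:rel", max_depth = 100)
  g2 <- rdf_add(g, "urn:n2", "urn:rel", "urn:extra")
  after <- broader_closure(g2, st, "urn:rel", max_depth = 100)
  expect_true(all(before %in% after))
})

test_that("ATC ancestors follow parent-first depth numbering on the worked chain", {
  fx <- tiny_fixture()
  expect_equal(atc_ancestors(fx, "C01DA38", 1)$label,
               "Organic nitrates used in cardiac disease")
  expect_equal(atc_ancestors(fx, "C01DA38", 2)$concept, "urn:kg:atc:C01D")
  a12 <- atc_ancestors(fx, "C01DA38", c(1, 2))
  expect_equal(a12$depth, c(1L, 2L))
  # unbounded: the full worked chain
  expect_setequal(atc_ancestors(fx, "C01DA38", 1:10)$concept,
                  paste0("urn:kg:atc:", c("C01DA", "C01D", "C01")))
  # root-level code has no parent
  expect_equal(nrow(atc_ancestors(fx, "C01", 1)), 0)
  expect_warning(out <- atc_ancestors(fx, "ZZZ99", 1), "not in graph")
  expect_equal(nrow(out), 0)
})

test_that("ICPC-2 extraction returns the single super class and enforces the invariant", {
  fx <- tiny_fixture()
  code <- fx$icpc2_codes$code[1]
  atom <- icpc2_ancestor(fx, code)
  expect_equal(nrow(atom), 1)
  expect_equal(atom$source, "ICPC2")
  # oracle: direct lookup in the raw triples
  g <- fx$graphs$ICPC2
  expect_equal(atom$concept,
               g$o[g$s == paste0("urn:kg:icpc2:", code) &
                     g$p == kgemr:::kg_iri$subclassof])
  expect_warning(out <- icpc2_ancestor(fx, "Q99"), "not in graph")
  expect_equal(nrow(out), 0)
  # corrupted graph with two parents errors
  fx2 <- fx
  fx2$graphs$ICPC2 <- rdf_add(g, paste0("urn:kg:icpc2:", code),
                              kgemr:::kg_iri$subclassof, "urn:kg:icpc2:ZZ")
  expect_error(icpc2_ancestor(fx2, code), "invariant")
})

test_that("NDF-RT pairs resolve through the CUI and match a triple-scan oracle", {
  fx <- tiny_fixture()
  ci <- ndfrt_pairs(fx, "C10AA05", "CI_with")
  expect_equal(ci$property, "CI_with")
  expect_equal(ci$label, "Pregnancy")
  # drug without NDF-RT triples
  no_ndf <- setdiff(fx$atc_codes$code,
                    fx$atc_codes$code[fx$atc_codes$cui %in%
                                        fx$graphs$NDFRT$o])
  if (length(no_ndf))
    expect_equal(nrow(ndfrt_pairs(fx, no_ndf[1])), 0)
  expect_warning(ndfrt_pairs(fx, "ZZZ99"), "CUI")
  # oracle over every linkable code and property
  g <- fx$graphs$NDFRT
  for (i in seq_len(nrow(fx$atc_codes))) {
    code <- fx$atc_codes$code[i]; cui <- fx$atc_codes$cui[i]
    drug <- unique(g$s[g$p == kgemr:::kg_iri$cui & g$o == cui])
    for (prop in c("may_treat", "may_prevent", "CI_with")) {
      expected <- if (length(drug))
        sort(unique(g$o[g$s == drug &
                          g$p == kgemr:::kg_iri[[kgemr:::NDFRT_PROPS[[prop]]]]]))
      else character()
      got <- suppressWarnings(ndfrt_pairs(fx, code, prop))
      expect_setequal(got$concept, expected)
    }
  }
})

test_that("Wikidata drugs resolve by ATC, then CUI, then RxNorm, idempotently", {
  fx <- tiny_fixture()
  g <- fx$graphs$WIKIDATA
  linked <- fx$atc_codes[fx$atc_codes$code %in%
                           g$o[g$p == kgemr:::kg_iri$wd_atc], ]
  row <- linked[1, ]
  full <- wikidata_pairs(fx, atc = row$code, cui = row$cui, rxnorm = row$rxnorm)
  by_atc <- wikidata_pairs(fx, atc = row$code)
  expect_equal(full, by_atc)   # multi-identifier resolution is idempotent
  # oracle: raw triple scan of the resolved node
  node <- g$s[g$p == kgemr:::kg_iri$wd_atc & g$o == row$code]
  expected <- sort(unique(g$o[g$s == node &
                                g$p %in% unlist(kgemr:::kg_iri[
                                  c("wd_role", "wd_interact", "wd_condition")])]))
  expect_setequal(full$concept, expected)
  expect_warning(out <- wikidata_pairs(fx, atc = "ZZZ99"), "resolvable")
  expect_equal(nrow(out), 0)
  expect_error(wikidata_pairs(fx), "at least one")
})

test_that("relation property IRIs are remappable by label", {
  fx <- tiny_fixture()
  g <- fx$graphs$WIKIDATA
  linked <- fx$atc_codes$code[fx$atc_codes$code %in%
                                g$o[g$p == kgemr:::kg_iri$wd_atc]]
  code <- linked[1]
  # swapping the interaction/condition IRIs swaps the returned pairs
  swapped <- wikidata_pairs(fx, atc = code, relations = "interaction",
                            prop_iris = list(
                              interaction = kgemr:::kg_iri$wd_condition))
  straight <- wikidata_pairs(fx, atc = code, relations = "condition")
  expect_setequal(swapped$concept, straight$concept)
})

test_that("the two-constraint subject filter matches the heart-failure and cyst worked examples", {
  fx <- tiny_fixture()
  m <- annotate_text("insuffisance cardiaque", fx$surface_forms)
  atoms <- dbpedia_candidate_subjects(m, fx)
  expect_setequal(atoms$label, c("Organ failure", "Cardiovascular disease"))
  # excluded entities contribute nothing
  excl <- fx$entities$surface[fx$entities$role == "excluded"]
  for (s in excl[1:2]) {
    m2 <- annotate_text(s, fx$surface_forms)
    expect_equal(nrow(dbpedia_candidate_subjects(m2, fx)), 0)
  }
  # a fixture without subject edges is a configuration error
  fx3 <- fx
  fx3$graphs$DBPEDIA <- rdf_match(fx$graphs$DBPEDIA, p = kgemr:::kg_iri$broader)
  expect_error(dbpedia_candidate_subjects(m, fx3), "subject/broader")
})

test_that("the two-constraint filter equals an exhaustive oracle on random fixtures", {
  for (seed in 1:25) {
    rf <- random_db_fixture(n_entities = 30, n_cats = 15, seed = seed)
    fx <- list(graphs = list(DBPEDIA = rf$graph),
               seed_categories = rf$seeds, allowed_classes = rf$allowed)
    expected <- oracle_two_constraint(rf$graph, rf$entities, rf$seeds, rf$allowed)
    mentions <- data.frame(surface = rf$entities, iri = rf$entities,
                           field = NA, start = 1, stringsAsFactors = FALSE)
    got <- dbpedia_candidate_subjects(mentions, fx, rf$seeds, rf$allowed,
                                      max_depth = 100)
    expect_setequal(got$concept, as.character(unique(unlist(expected))))
    # subset property: constraint 2 never enlarges the constraint-1 result
    c1_only <- unlist(lapply(rf$entities, function(e) {
      subs <- rf$graph$o[rf$graph$s == e & rf$graph$p == kgemr:::kg_iri$subject]
      Filter(function(su) length(intersect(
        c(su, oracle_reachable(rf$graph, su, kgemr:::kg_iri$broader)),
        rf$seeds)) > 0, subs)
    }))
    expect_true(all(got$concept %in% c1_only))
  }
})

test_that("extract_all respects variant scopes and accumulates counts", {
  fx <- tiny_fixture()
  rec <- list(texts = list(observations = "kyste et insuffisance cardiaque",
                           symptoms = "kyste"),
              atc_codes = c("C10AA05", "C10AA05", "C01DA38"),
              icpc2_codes = fx$icpc2_codes$code[1],
              hospitalized = FALSE)
  # baseline: no enrichment
  expect_equal(nrow(extract_all(rec, fx, feature_set_spec("baseline"))), 0)
  # +d_CI on a record prescribing atorvastatin twice: count 2
  ci <- extract_all(rec, fx, feature_set_spec("+d_CI"))
  expect_equal(ci$count[ci$label == "Pregnancy"], 2L)
  # +t touches only ICPC-2 codes, never free text
  t_atoms <- extract_all(rec, fx, feature_set_spec("+t"))
  expect_true(all(t_atoms$source == "ICPC2"))
  expect_false(any(grepl("Neoplasm", t_atoms$label)))
  # full scope sees the symptoms field, starred scope does not
  starred <- extract_all(rec, fx, feature_set_spec("+s*T"))
  fullscope <- extract_all(rec, fx, feature_set_spec("+sm"))
  expect_equal(starred$count[starred$label == "Neoplasm stubs"], 1L)
  expect_equal(fullscope$count[fullscope$label == "Neoplasm stubs"], 2L)
  # determinism
  expect_identical(extract_all(rec, fx, feature_set_spec("+sm")), fullscope)
  expect_error(extract_all(rec, fx, "no-such-variant"), "unknown")
})

test_that("extraction results serialize as JSON lines keyed by patient", {
  co <- tiny_cohort()
  fx <- tiny_fixture()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_extractions(co, fx, "+sm", path)
  lines <- readLines(path)
  expect_length(lines, nrow(co$patients))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$patient_id, co$patients$patient_id[1])
  expect_true(all(c("source", "concept", "count") %in% names(first$atoms)))
})
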
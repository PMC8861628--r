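test_that("bag-of-words features carry field prefixes", {
  rec <- list(texts = list(observations = "pas signe de phlébite",
                           personal_history = "phlébite ancienne",
                           family_history = "phlébite"),
              atc_codes = character(), icpc2_codes = character(),
              hospitalized = FALSE)
  v <- build_bow(rec)
  expect_equal(unname(v["obs:phlébite"]), 1L)
  expect_false("phlébite" %in% names(v))
  # same word in two fields gives two distinct features
  expect_equal(unname(v["ph:phlébite"]), 1L)
  expect_equal(unname(v["fh:phlébite"]), 1L)
  # empty record
  empty <- list(texts = list(observations = ""), atc_codes = character(),
                icpc2_codes = character())
  expect_length(build_bow(empty), 0)
  expect_error(build_bow(rec, field_scope = "bogus_field"), "unknown field")
})

test_that("token conservation: V-block column sums equal tokenizer output", {
  co <- tiny_cohort()
  fx <- tiny_fixture()
  d <- assemble_design_matrix(co, fx, "baseline")
  total_tokens <- 0L
  for (pid in d$patient_ids) {
    rec <- aggregate_record(co, pid)
    for (f in kgemr:::FULL_SCOPE)
      total_tokens <- total_tokens +
        length(tokenize_text(rec$texts[[f]])[[1]])
  }
  expect_equal(sum(d$matrix[, seq_len(d$boundary)]), total_tokens)
})

test_that("bag-of-concepts accumulates counts per property-concept pair", {
  atoms <- rbind(
    kgemr:::concept_atoms("DBPEDIA", NA, "urn:c1", "Organ failure"),
    kgemr:::concept_atoms("DBPEDIA", NA, "urn:c2", "Medical emergencies"),
    kgemr:::concept_atoms("NDFRT", "CI_with", "urn:p", "Pregnancy", count = 2L))
  v <- build_boc(atoms)
  expect_equal(unname(v["DBPEDIA=Organ failure"]), 1L)
  expect_equal(unname(v["DBPEDIA=Medical emergencies"]), 1L)
  expect_equal(unname(v["NDFRT:CI_with=Pregnancy"]), 2L)
  expect_length(build_boc(kgemr:::empty_atoms()), 0)
  # duplicated atoms merge
  v2 <- build_boc(rbind(atoms, atoms))
  expect_equal(unname(v2["NDFRT:CI_with=Pregnancy"]), 4L)
})

test_that("concatenation preserves widths and values and rejects collisions", {
  v <- c("obs:a" = 1L, "obs:b" = 2L, "rc:a" = 1L, "dx:x" = 4L, "ph:z" = 1L)
  c_ <- c("DBPEDIA=X" = 2L, "ATC=Y" = 1L, "ICPC2=Z" = 3L)
  x <- concat_vectors(v, c_)
  expect_length(x, 8)
  expect_equal(attr(x, "boundary"), 5)
  expect_equal(sort(as.integer(x)), sort(c(as.integer(v), as.integer(c_))))
  id <- concat_vectors(v, stats::setNames(integer(), character()))
  expect_equal(names(id), names(v))
  expect_equal(unname(id), unname(v), ignore_attr = TRUE)
  expect_error(concat_vectors(v, c("obs:a" = 1L)), "collide")
})

test_that("the design matrix separates blocks and the baseline has no concepts", {
  d <- mid_designs()
  expect_equal(ncol(d$baseline$matrix) - d$baseline$boundary, 0)
  expect_gt(ncol(d$sm$matrix) - d$sm$boundary, 0)
  expect_true(all(grepl("^[a-z]+:", colnames(d$baseline$matrix))))
  cc <- concept_columns(d$sm)
  expect_true(all(grepl("^(ATC|ICPC2|NDFRT|WIKIDATA|DBPEDIA)[:=]", cc)))
  expect_true(all(d$sm$matrix@x >= 0))
  expect_false(anyDuplicated(colnames(d$sm$matrix)) > 0)
})

test_that("enrichment never perturbs the word block (same family scope)", {
  d <- mid_designs()
  vb <- d$baseline$matrix[, seq_len(d$baseline$boundary)]
  vs <- d$sm$matrix[, seq_len(d$sm$boundary)]
  expect_equal(dim(vb), dim(vs))
  expect_equal(colnames(vb), colnames(vs))
  expect_equal(as.matrix(vb), as.matrix(vs))
})

test_that("hospitalized rows exclude post-hospitalization tokens by construction", {
  co <- tiny_cohort()
  fx <- tiny_fixture()
  d <- assemble_design_matrix(co, fx, "baseline")
  hosp <- co$patients[co$patients$hospitalized, ]
  p <- hosp[which(hosp$hospitalization_index >= 2)[1], ]
  cons <- co$consultations[co$consultations$patient_id == p$patient_id, ]
  post <- cons[cons$order_index >= p$hospitalization_index, ]
  pre <- cons[cons$order_index < p$hospitalization_index, ]
  post_only <- setdiff(unlist(tokenize_text(unlist(post[kgemr:::FIELD_CONSULT]))),
                       unlist(tokenize_text(unlist(pre[kgemr:::FIELD_CONSULT]))))
  # also not present in statics
  stat <- unlist(tokenize_text(unlist(p[intersect(names(p), kgemr:::FIELD_STATIC)])))
  post_only <- setdiff(post_only, stat)
  if (length(post_only)) {
    row <- d$matrix[p$patient_id, , drop = TRUE]
    nz <- sub("^[a-z]+:", "", names(row)[row > 0])
    expect_length(intersect(post_only, nz), 0)
  }
})

test_that("matrix assembly is invariant to patient order up to row permutation", {
  co <- tiny_cohort()
  fx <- tiny_fixture()
  co2 <- co
  perm <- rev(seq_len(nrow(co$patients)))
  co2$patients <- co$patients[perm, ]
  d1 <- assemble_design_matrix(co, fx, "baseline")
  d2 <- assemble_design_matrix(co2, fx, "baseline")
  expect_equal(colnames(d1$matrix), colnames(d2$matrix))
  expect_equal(as.matrix(d2$matrix[d1$patient_ids, ]), as.matrix(d1$matrix))
})

test_that("design matrices persist as MatrixMarket with sidecars", {
  d <- mid_designs()$sm
  dir <- withr::local_tempdir()
  write_design(d, dir)
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  expect_equal(dim(m), dim(d$matrix))
  expect_equal(sum(m), sum(d$matrix))
  cols <- utils::read.delim(file.path(dir, "columns.tsv"))
  expect_equal(nrow(cols), ncol(d$matrix))
  expect_equal(sum(cols$block == "V"), d$boundary)
})

test_that("the variant registry matches the notation list", {
  expect_length(feature_set_names(), 20)
  s <- feature_set_spec("+s*T")
  expect_true(isTRUE(s$sources$dbpedia))
  expect_equal(s$selection_mode, "none")
  expect_false("symptoms" %in% s$field_scope)
  expect_false("family_history" %in% s$field_scope)
  sm <- feature_set_spec("+sm")
  expect_equal(sm$selection_mode, "lasso")
  expect_true(all(c("symptoms", "family_history", "past_problems")
                  %in% sm$field_scope))
  expect_length(feature_set_spec("baseline")$sources, 0)
  expect_equal(feature_set_spec("+c1−2")$sources$atc_levels, c(1L, 2L))
  expect_error(feature_set_spec("+zz"), "unknown")
  # manual-list variants need a whitelist at assembly time
  expect_error(assemble_design_matrix(tiny_cohort(), tiny_fixture(), "+sm∪"),
               "whitelist")
})
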
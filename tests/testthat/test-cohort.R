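test_that("degenerate class counts produce the requested records", {
  co <- generate_cohort(cohort_config(n_hospitalized = 0,
                                      n_not_hospitalized = 1,
                                      n_signal_concepts = 3,
                                      n_noise_concepts = 5,
                                      effect_sizes = rep(2, 3), seed = 1),
                        tiny_fixture())
  expect_equal(nrow(co$patients), 1)
  expect_false(co$patients$hospitalized)
  expect_true(is.na(co$patients$hospitalization_index))
})

test_that("cohort hits the exact configured class counts", {
  co <- tiny_cohort()
  expect_equal(sum(co$patients$hospitalized), 20)
  expect_equal(sum(!co$patients$hospitalized), 20)
})

test_that("hospitalization_index present iff hospitalized, within consultation range", {
  co <- tiny_cohort()
  for (i in seq_len(nrow(co$patients))) {
    p <- co$patients[i, ]
    n_cons <- sum(co$consultations$patient_id == p$patient_id)
    if (p$hospitalized) {
      expect_false(is.na(p$hospitalization_index))
      expect_gte(p$hospitalization_index, 1)
      expect_lte(p$hospitalization_index, n_cons)
    } else {
      expect_true(is.na(p$hospitalization_index))
    }
  }
  # order_index unique per patient
  dup <- tapply(co$consultations$order_index, co$consultations$patient_id,
                function(x) anyDuplicated(x) > 0)
  expect_false(any(dup))
})

test_that("generated ATC and ICPC-2 codes are syntactically valid", {
  co <- tiny_cohort()
  atc <- unlist(strsplit(co$consultations$atc_codes, ","))
  atc <- atc[nzchar(atc)]
  expect_true(all(grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", atc)))
  icpc <- unlist(strsplit(co$consultations$icpc2_codes, ","))
  icpc <- icpc[nzchar(icpc)]
  expect_true(all(grepl("^[A-Z][0-9]{2}$", icpc)))
})

test_that("same config and seed serialize byte-identically", {
  cfg <- cohort_config(n_hospitalized = 5, n_not_hospitalized = 5,
                       vocab_size_words = 30, n_signal_concepts = 2,
                       n_noise_concepts = 3, effect_sizes = c(2, 2), seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg, tiny_fixture()), d1)
  write_cohort(generate_cohort(cfg, tiny_fixture()), d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("cohorts round-trip through TSV/JSON", {
  co <- tiny_cohort()
  d <- withr::local_tempdir()
  write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_equal(co2$patients$hospitalized, co$patients$hospitalized)
  expect_equal(co2$patients$hospitalization_index,
               co$patients$hospitalization_index)
  expect_equal(co2$consultations$observations, co$consultations$observations)
  expect_equal(co2$config$effect_sizes, co$config$effect_sizes)
})

test_that("signal surface forms are more prevalent among hospitalized patients", {
  co <- mid_cohort()
  fx <- tiny_fixture()
  sig <- fx$entities$surface[fx$entities$role == "signal" &
                               fx$entities$concept_index <= 3]
  text_of <- function(pid) {
    cons <- co$consultations[co$consultations$patient_id == pid, ]
    pat <- co$patients[co$patients$patient_id == pid, ]
    paste(c(unlist(cons[intersect(names(cons), emr_field_names())]),
            unlist(pat[intersect(names(pat), emr_field_names())])),
          collapse = " ")
  }
  has_sig <- vapply(co$patients$patient_id, function(pid)
    any(vapply(sig, function(s) grepl(s, text_of(pid), fixed = TRUE), TRUE)), TRUE)
  prev_h <- mean(has_sig[co$patients$hospitalized])
  prev_n <- mean(has_sig[!co$patients$hospitalized])
  expect_gt(prev_h, prev_n)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(effect_sizes = c(1, 2), n_signal_concepts = 3),
               "length")
  expect_error(cohort_config(abbreviation_rate = 1.5), "\\[0, 1\\]")
  fx <- tiny_fixture()
  expect_error(generate_cohort(cohort_config(
    n_signal_concepts = 99, effect_sizes = rep(1, 99)), fx), "exceeds")
})

test_that("aggregation truncates hospitalized records at the hospitalization index", {
  co <- tiny_cohort()
  hosp <- co$patients[co$patients$hospitalized &
                        co$patients$hospitalization_index >= 2, ][1, ]
  rec <- aggregate_record(co, hosp$patient_id)
  cons <- co$consultations[co$consultations$patient_id == hosp$patient_id, ]
  post <- cons[cons$order_index >= hosp$hospitalization_index, ]
  pre <- cons[cons$order_index < hosp$hospitalization_index, ]
  # tokens unique to post-hospitalization consultations never appear
  post_tokens <- setdiff(unlist(tokenize_text(unlist(post[kgemr:::FIELD_CONSULT]))),
                         unlist(tokenize_text(unlist(pre[kgemr:::FIELD_CONSULT]))))
  agg_tokens <- unlist(tokenize_text(unlist(
    rec$texts[intersect(names(rec$texts), kgemr:::FIELD_CONSULT)])))
  expect_length(intersect(post_tokens, agg_tokens), 0)
  # non-hospitalized: everything aggregates
  nh <- co$patients[!co$patients$hospitalized, ][1, ]
  rec_nh <- aggregate_record(co, nh$patient_id)
  cons_nh <- co$consultations[co$consultations$patient_id == nh$patient_id, ]
  expect_equal(sort(unlist(tokenize_text(rec_nh$texts$observations))),
               sort(unlist(tokenize_text(paste(cons_nh$observations,
                                               collapse = " ")))))
})
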
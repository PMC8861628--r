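# Synthetic EMR cohort generator.
#
# Emulates a balanced primary-care cohort labelled hospitalized / not
# hospitalized.  Hospitalization is drawn from a Bernoulli-logistic model
# whose linear predictor sums planted log-odds weights over "signal"
# knowledge-graph concepts; a concept contributes when surface forms of its
# entities were injected into the patient's texts.  The cohort is then built
# to the exact configured class counts by accept-reject sampling, mirroring a
# balanced designed dataset rather than natural prevalence.

#' Configuration of the synthetic cohort
#'
#' @param n_hospitalized,n_not_hospitalized exact class counts (defaults give
#'   the 714 / 732 balanced design).
#' @param consultations_range integer range (min, max) of consultations per
#'   patient.
#' @param field_names EMR field identifiers; defaults to [emr_field_names()].
#' @param vocab_size_words size of the filler-word vocabulary.
#' @param n_signal_concepts,n_noise_concepts numbers of planted-effect and
#'   zero-effect concept categories used from the fixture.
#' @param effect_sizes per-signal-concept log-odds weights
#'   (length `n_signal_concepts`).
#' @param exposure_prob probability that a patient is exposed to (i.e.,
#'   mentions entities of) each signal concept.
#' @param abbreviation_rate probability that an injected surface form is
#'   written as its dictionary abbreviation.
#' @param intercept log-odds intercept; default centers the linear predictor
#'   at zero so the accept-reject step discards few candidates.
#' @param seed integer seed.
#' @return list of class `kgemr_cohort_config`.
#' @export
cohort_config <- function(n_hospitalized = 714, n_not_hospitalized = 732,
                          consultations_range = c(3L, 10L),
                          field_names = emr_field_names(),
                          vocab_size_words = 300,
                          n_signal_concepts = 6, n_noise_concepts = 40,
                          effect_sizes = rep(2, n_signal_concepts),
                          exposure_prob = 0.35, abbreviation_rate = 0.2,
                          intercept = NULL, seed = 1L) {
  stopifnot(n_hospitalized >= 0, n_not_hospitalized >= 0,
            vocab_size_words >= 1, n_signal_concepts >= 0,
            n_noise_concepts >= 0,
            length(consultations_range) == 2,
            consultations_range[1] >= 1,
            consultations_range[2] >= consultations_range[1])
  if (abbreviation_rate < 0 || abbreviation_rate > 1)
    stop("abbreviation_rate must be in [0, 1]")
  if (exposure_prob < 0 || exposure_prob > 1)
    stop("exposure_prob must be in [0, 1]")
  if (length(effect_sizes) != n_signal_concepts)
    stop("effect_sizes must have length n_signal_concepts")
  if (is.null(intercept))
    intercept <- -sum(effect_sizes * exposure_prob)
  cfg <- list(n_hospitalized = as.integer(n_hospitalized),
              n_not_hospitalized = as.integer(n_not_hospitalized),
              consultations_range = as.integer(consultations_range),
              field_names = field_names,
              vocab_size_words = as.integer(vocab_size_words),
              n_signal_concepts = as.integer(n_signal_concepts),
              n_noise_concepts = as.integer(n_noise_concepts),
              effect_sizes = as.numeric(effect_sizes),
              exposure_prob = exposure_prob,
              abbreviation_rate = abbreviation_rate,
              intercept = intercept, seed = as.integer(seed))
  class(cfg) <- "kgemr_cohort_config"
  cfg
}

#' Generate a synthetic EMR cohort
#'
#' @param config a [cohort_config()].
#' @param fixture a [generate_kg_fixture()] result; signal and noise entities
#'   (and their abbreviations) are drawn from it.
#' @return list of class `kgemr_cohort` with elements `patients` (one row per
#'   patient: `patient_id`, `hospitalized`, `hospitalization_index`, one
#'   column per static field), `consultations` (one row per consultation:
#'   `patient_id`, `order_index`, one column per consultation field,
#'   `atc_codes` and `icpc2_codes` as comma-separated strings),
#'   `ground_truth` (planted categories, weights and the model intercept) and
#'   the `config` echo.
#' @export
generate_cohort <- function(config = cohort_config(),
                            fixture = generate_kg_fixture()) {
  if (!inherits(config, "kgemr_cohort_config"))
    config <- do.call(cohort_config, config)
  if (config$n_signal_concepts > length(fixture$signal_categories))
    stop("n_signal_concepts exceeds the signal concepts available in the fixture")
  if (config$n_noise_concepts > length(fixture$noise_categories))
    stop("n_noise_concepts exceeds the noise concepts available in the fixture")
  set.seed(derive_seed(config$seed, "cohort"))

  ent <- fixture$entities
  sig_ent <- ent[ent$role == "signal" & ent$concept_index <= config$n_signal_concepts, ]
  noise_ent <- ent[ent$role == "noise" & ent$concept_index <= config$n_noise_concepts, ]
  worked_ent <- ent[ent$role == "worked", ]
  excl_ent <- ent[ent$role == "excluded", ]
  abbrev_of <- stats::setNames(fixture$abbreviations$key,
                               fixture$abbreviations$expansion)

  vocab <- sprintf("w%04d", seq_len(config$vocab_size_words))
  zipf <- (1 / seq_along(vocab)); zipf <- zipf / sum(zipf)
  draw_filler <- function(n) paste(sample(vocab, n, replace = TRUE, prob = zipf),
                                   collapse = " ")
  mention_token <- function(surface) {
    if (stats::runif(1) < config$abbreviation_rate && surface %in% names(abbrev_of))
      abbrev_of[[surface]] else surface
  }
  # fields that free-text entity mentions land in, weighted towards the
  # observation and reason notes
  mention_fields <- c("observations", "reasons", "symptoms", "diagnoses",
                      "personal_history", "family_history", "past_problems",
                      "current_problems")
  mention_w <- c(0.35, 0.2, 0.1, 0.1, 0.08, 0.06, 0.06, 0.05)
  keep_mf <- mention_fields %in% config$field_names
  if (!any(keep_mf)) stop("field_names must include at least one free-text mention field")
  mention_fields <- mention_fields[keep_mf]
  mention_w <- mention_w[keep_mf] / sum(mention_w[keep_mf])

  consult_fields <- intersect(FIELD_CONSULT, config$field_names)
  static_fields <- intersect(FIELD_STATIC, config$field_names)

  quota <- c(`TRUE` = config$n_hospitalized, `FALSE` = config$n_not_hospitalized)
  total <- sum(quota)
  pat_rows <- vector("list", total)
  cons_rows <- vector("list", total)
  filled <- 0L
  attempts <- 0L
  max_attempts <- 200L * total + 1000L

  while (filled < total) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not reach the configured class counts; check effect sizes / intercept")
    exposed <- stats::rbinom(config$n_signal_concepts, 1, config$exposure_prob)
    lp <- config$intercept + sum(config$effect_sizes * exposed)
    y <- stats::runif(1) < stats::plogis(lp)
    if (quota[[as.character(y)]] == 0L) next
    quota[[as.character(y)]] <- quota[[as.character(y)]] - 1L
    filled <- filled + 1L
    pid <- sprintf("P%05d", filled)

    rint <- function(a, b) a + floor(stats::runif(1) * (b - a + 1L))
    n_cons <- rint(config$consultations_range[1], config$consultations_range[2])
    if (y && n_cons < 2L) n_cons <- 2L
    h_index <- if (y) as.integer(rint(2L, n_cons)) else NA_integer_

    cons <- data.frame(patient_id = pid, order_index = seq_len(n_cons),
                       stringsAsFactors = FALSE)
    for (f in consult_fields)
      cons[[f]] <- vapply(seq_len(n_cons), function(i) draw_filler(sample(3:8, 1)), "")
    n_codes <- nrow(fixture$atc_codes)
    cons$atc_codes <- vapply(seq_len(n_cons), function(i)
      paste(fixture$atc_codes$code[sample.int(n_codes, sample(0:2, 1))],
            collapse = ","), "")
    n_icpc <- nrow(fixture$icpc2_codes)
    cons$icpc2_codes <- vapply(seq_len(n_cons), function(i)
      paste(fixture$icpc2_codes$code[sample.int(n_icpc, sample(0:1, 1))],
            collapse = ","), "")

    statics <- stats::setNames(
      vapply(static_fields, function(f) draw_filler(sample(2:6, 1)), ""),
      static_fields)

    # visible window: what the aggregation rule will keep
    visible_cons <- if (y) seq_len(h_index - 1L) else seq_len(n_cons)

    inject <- function(surface, pre_hosp_only) {
      tok <- mention_token(surface)
      f <- sample(mention_fields, 1, prob = mention_w)
      if (f %in% static_fields) {
        statics[[f]] <<- paste(statics[[f]], tok)
      } else {
        pool <- if (pre_hosp_only) visible_cons else seq_len(n_cons)
        if (!length(pool)) pool <- seq_len(n_cons)
        i <- if (length(pool) == 1) pool else sample(pool, 1)
        cons[[f]][i] <<- paste(cons[[f]][i], tok)
      }
    }

    for (k in which(exposed == 1L)) {
      pool <- sig_ent$surface[sig_ent$concept_index == k]
      n_m <- 1L + stats::rpois(1, 1)
      for (s in sample(pool, n_m, replace = TRUE)) inject(s, pre_hosp_only = y)
    }
    if (nrow(noise_ent)) {
      n_m <- stats::rpois(1, 2)
      if (n_m > 0)
        for (s in sample(noise_ent$surface, n_m, replace = TRUE))
          inject(s, pre_hosp_only = FALSE)
    }
    if (stats::runif(1) < 0.05 && nrow(worked_ent))
      inject(sample(worked_ent$surface, 1), pre_hosp_only = y)
    if (stats::runif(1) < 0.1 && nrow(excl_ent))
      inject(sample(excl_ent$surface, 1), pre_hosp_only = FALSE)

    pat_rows[[filled]] <- cbind(
      data.frame(patient_id = pid, hospitalized = y,
                 hospitalization_index = h_index, stringsAsFactors = FALSE),
      as.data.frame(as.list(statics), stringsAsFactors = FALSE))
    cons_rows[[filled]] <- cons
  }

  patients <- do.call(rbind, pat_rows)
  consultations <- do.call(rbind, cons_rows)
  rownames(patients) <- rownames(consultations) <- NULL
  gt <- list(
    signal_concepts = data.frame(
      iri = fixture$signal_categories[seq_len(config$n_signal_concepts)],
      label = vapply(fixture$signal_categories[seq_len(config$n_signal_concepts)],
                     function(i) node_label(fixture$graphs$DBPEDIA, i), ""),
      weight = config$effect_sizes, stringsAsFactors = FALSE),
    intercept = config$intercept)
  out <- list(patients = patients, consultations = consultations,
              ground_truth = gt, config = config)
  class(out) <- "kgemr_cohort"
  out
}

#' @export
print.kgemr_cohort <- function(x, ...) {
  cat(sprintf("<kgemr_cohort: %d patients (%d hospitalized), %d consultations>\n",
              nrow(x$patients), sum(x$patients$hospitalized),
              nrow(x$consultations)))
  invisible(x)
}

#' Aggregate a patient record under the labelling rule
#'
#' Hospitalized patients contribute only consultations occurring before the
#' hospitalization (order_index < hospitalization_index) plus static texts;
#' non-hospitalized patients contribute all consultations plus static texts.
#'
#' @param cohort a `kgemr_cohort`.
#' @param patient_id patient identifier.
#' @return list with `texts` (named list field -> single aggregated string),
#'   `atc_codes` and `icpc2_codes` (character vectors with repetitions),
#'   `hospitalized` flag; or `NULL` (with a warning) when a hospitalized
#'   patient has hospitalization_index 0, i.e., no pre-hospitalization
#'   evidence.
#' @export
aggregate_record <- function(cohort, patient_id) {
  p <- cohort$patients[cohort$patients$patient_id == patient_id, ]
  if (nrow(p) != 1) stop("unknown patient_id: ", patient_id)
  cons <- cohort$consultations[cohort$consultations$patient_id == patient_id, ]
  cons <- cons[order(cons$order_index), ]
  if (isTRUE(p$hospitalized)) {
    if (is.na(p$hospitalization_index) || p$hospitalization_index < 1) {
      warning("patient ", patient_id,
              " has no pre-hospitalization evidence; excluded")
      return(NULL)
    }
    cons <- cons[cons$order_index < p$hospitalization_index, ]
  }
  texts <- list()
  for (f in intersect(FIELD_CONSULT, names(cons)))
    texts[[f]] <- paste(cons[[f]], collapse = " ")
  for (f in intersect(FIELD_STATIC, names(p)))
    texts[[f]] <- as.character(p[[f]])
  split_codes <- function(x) {
    x <- unlist(strsplit(x[nzchar(x)], ",", fixed = TRUE))
    x[nzchar(x)]
  }
  list(patient_id = patient_id, texts = texts,
       atc_codes = split_codes(cons$atc_codes %||% character()),
       icpc2_codes = split_codes(cons$icpc2_codes %||% character()),
       hospitalized = isTRUE(p$hospitalized))
}

write_tsv_raw <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  body <- do.call(paste, c(lapply(df, function(col) {
    x <- as.character(col)
    x[is.na(col)] <- "NA"
    x
  }), sep = "\t"))
  writeLines(c(paste(names(df), collapse = "\t"), body), con)
  invisible(path)
}

#' Write a cohort as TSV + JSON
#' @param cohort a `kgemr_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_raw(cohort$patients, file.path(dir, "patients.tsv"))
  write_tsv_raw(cohort$consultations, file.path(dir, "consultations.tsv"))
  jsonlite::write_json(
    list(signal_concepts = cohort$ground_truth$signal_concepts,
         intercept = cohort$ground_truth$intercept,
         config = unclass(cohort$config)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `patients.tsv`, `consultations.tsv` and
#'   `ground_truth.json`.
#' @return a `kgemr_cohort`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), sep = "\t",
                                      colClasses = "character",
                                      na.strings = character(),
                                      check.names = FALSE,
                                      fileEncoding = "UTF-8")
  patients <- rd("patients.tsv")
  patients$hospitalized <- patients$hospitalized == "TRUE"
  patients$hospitalization_index <- suppressWarnings(
    as.integer(patients$hospitalization_index))
  consultations <- rd("consultations.tsv")
  consultations$order_index <- as.integer(consultations$order_index)
  meta <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  cfg <- cohort_config(cfg$n_hospitalized, cfg$n_not_hospitalized,
                       cfg$consultations_range, cfg$field_names,
                       cfg$vocab_size_words, cfg$n_signal_concepts,
                       cfg$n_noise_concepts, cfg$effect_sizes,
                       cfg$exposure_prob, cfg$abbreviation_rate,
                       cfg$intercept, cfg$seed)
  out <- list(patients = patients, consultations = consultations,
              ground_truth = list(signal_concepts = meta$signal_concepts,
                                  intercept = meta$intercept),
              config = cfg)
  class(out) <- "kgemr_cohort"
  out
}
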
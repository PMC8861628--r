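# End-to-end pipeline: generate -> extract/vectorize -> select -> evaluate.
#
# All randomness funnels through one master seed from which per-stage seeds
# are derived, so stages are independently rerunnable and a manifest makes
# the run reproducible.

#' Configuration of a pipeline run
#'
#' @param out_dir run directory for all stage outputs.
#' @param cohort a [cohort_config()] (or argument list).
#' @param fixture a [fixture_spec()] (or argument list).
#' @param variants feature-set variant names to evaluate; the machine
#'   variants `+sm` intersection / union are derived automatically when
#'   `"+sm"` is included with lasso selection.
#' @param estimators subset of `c("lr", "rf", "svc")`.
#' @param protocol a [cv_protocol()] or preset name.
#' @param seed master seed; overrides the cohort / fixture / protocol seeds.
#' @return list of class `kgemr_run_config`.
#' @export
run_config <- function(out_dir, cohort = cohort_config(),
                       fixture = fixture_spec(),
                       variants = c("baseline", "+sm"),
                       estimators = "lr",
                       protocol = protocol_preset("screen"),
                       seed = 1L) {
  if (is.character(protocol)) protocol <- protocol_preset(protocol)
  known <- c(feature_set_names(), "+sm∪", "+sm∩")
  bad <- setdiff(variants, known)
  if (length(bad)) stop("unregistered variant(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(seed)
  cohort$seed <- seed
  fixture$seed <- derive_seed(seed, "fixture")
  protocol$seed <- seed
  cfg <- list(out_dir = out_dir, cohort = cohort, fixture = fixture,
              variants = variants, estimators = estimators,
              protocol = protocol, seed = seed)
  class(cfg) <- "kgemr_run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys mirroring the [run_config()] arguments.
#' @return a `kgemr_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(out_dir = y$out_dir %||% "kgemr_run",
             cohort = do.call(cohort_config, y$cohort %||% list()),
             fixture = do.call(fixture_spec, y$fixture %||% list()),
             variants = unlist(y$variants) %||% c("baseline", "+sm"),
             estimators = unlist(y$estimators) %||% "lr",
             protocol = if (is.character(y$protocol %||% "screen"))
               y$protocol %||% "screen"
             else do.call(cv_protocol, y$protocol),
             seed = y$seed %||% 1L)
}

#' Run the full pipeline
#'
#' Generates the fixture and cohort, assembles the design matrix of each
#' requested variant, runs nested cross-validation per estimator, derives
#' the per-fold union / intersection concept variants when `+sm` (or `+s*m`)
#' ran with lasso selection, and writes every stage output plus a manifest
#' under the run directory.
#'
#' @param config a [run_config()].
#' @return list of class `kgemr_report`: `results` (variant x estimator
#'   `kgemr_cv_result`s), `summary` (data frame: variant, estimator, pooled
#'   F, metric means/sds), `ttests` (corrected-t table vs. the first
#'   variant), `selections`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kgemr_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  fixture <- stage("fixture", generate_kg_fixture(config$fixture))
  stage("fixture-io", write_fixture(fixture, file.path(config$out_dir, "fixtures")))
  cohort <- stage("cohort", generate_cohort(config$cohort, fixture))
  stage("cohort-io", write_cohort(cohort, file.path(config$out_dir, "cohort")))

  union_variants <- intersect(config$variants, c("+sm∪", "+sm∩"))
  base_variants <- setdiff(config$variants, union_variants)
  if (length(union_variants) && !"+sm" %in% base_variants)
    base_variants <- c(base_variants, "+sm")

  results <- list()
  selections_sm <- NULL
  for (v in base_variants) {
    design <- stage(paste0("vectorize ", v),
                    assemble_design_matrix(cohort, fixture, v))
    stage("design-io", write_design(design, file.path(
      config$out_dir, "designs", gsub("[^A-Za-z0-9]+", "_", v))))
    mode <- feature_set_spec(v)$selection_mode
    for (est in config$estimators) {
      r <- stage(paste(v, est), nested_cv(
        design, config$protocol, est,
        selection_mode = if (mode == "lasso") "lasso" else "none"))
      results[[paste(v, est, sep = "|")]] <- r
      if (mode == "lasso" && est == config$estimators[[1]])
        selections_sm <- r$selections
    }
  }
  for (v in union_variants) {
    if (is.null(selections_sm))
      stop("pipeline stage '", v, "' failed: no lasso selections to derive from")
    wl <- if (v == "+sm∪") fold_union(selections_sm)
          else fold_intersection(selections_sm)
    spec <- feature_set_spec(v, concept_whitelist = wl)
    design <- stage(paste0("vectorize ", v),
                    assemble_design_matrix(cohort, fixture, spec))
    for (est in config$estimators)
      results[[paste(v, est, sep = "|")]] <-
        stage(paste(v, est), nested_cv(design, config$protocol, est, "none"))
  }

  summary <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    am <- avg_metrics(r$metrics)
    data.frame(variant = r$variant, estimator = r$estimator,
               pooled_f = r$pooled_f,
               t(stats::setNames(am$mean, paste0(am$metric, "_avg"))),
               t(stats::setNames(am$sd, paste0(am$metric, "_sd"))),
               stringsAsFactors = FALSE)
  }))
  first_est <- config$estimators[[1]]
  per_variant <- results[grepl(paste0("\\|", first_est, "$"), names(results))]
  names(per_variant) <- sub("\\|.*$", "", names(per_variant))
  ttests <- if (length(per_variant) > 1)
    compare_variants(per_variant, baseline = names(per_variant)[1])
  else NULL

  if (!is.null(selections_sm)) {
    jsonlite::write_json(
      lapply(selections_sm, function(s)
        list(fold = s$fold, lambda = s$lambda, selected = s$selected)),
      file.path(config$out_dir, "fold_selections.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("kgemr")),
    seed = config$seed, variants = config$variants,
    estimators = config$estimators,
    protocol = unclass(config$protocol),
    file_md5 = as.list(tools::md5sum(
      list.files(config$out_dir, recursive = TRUE, full.names = TRUE,
                 pattern = "\\.(tsv|ttl|json|mtx)$"))))
  names(manifest$file_md5) <- basename(names(manifest$file_md5))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  report <- list(results = results, summary = summary, ttests = ttests,
                 selections = selections_sm, manifest = manifest)
  class(report) <- "kgemr_report"
  render_report(report, config$out_dir)
  report
}

#' Render a report as TSV tables
#'
#' Writes (and returns) two tables: per-variant pooled F and average metrics,
#' and the corrected-t comparison against the first variant.  Row order
#' follows the variant registry order and is stable across runs.
#'
#' @param report a `kgemr_report`.
#' @param dir optional directory to write `summary.tsv` / `ttests.tsv` into.
#' @return list of data frames `summary` and `ttests`, invisibly.
#' @export
render_report <- function(report, dir = NULL) {
  ord <- c(feature_set_names(), "+sm∩", "+sm∪")
  s <- report$summary
  if (!is.null(s) && nrow(s))
    s <- s[order(match(s$variant, ord), s$estimator), , drop = FALSE]
  tt <- report$ttests
  if (!is.null(tt) && nrow(tt))
    tt <- tt[order(match(tt$variant, ord)), , drop = FALSE]
  if (!is.null(dir)) {
    if (!is.null(s)) write_tsv_raw(
      within(s, {
        pooled_f <- sprintf("%.4f", pooled_f)
      }), file.path(dir, "summary.tsv"))
    if (!is.null(tt) && nrow(tt)) write_tsv_raw(tt, file.path(dir, "ttests.tsv"))
  }
  invisible(list(summary = s, ttests = tt))
}

#' @export
print.kgemr_report <- function(x, ...) {
  cat("<kgemr_report>\n")
  if (!is.null(x$summary)) {
    df <- x$summary
    df$pooled_f <- sprintf("%.4f", df$pooled_f)
    print(df[, c("variant", "estimator", "pooled_f", "F1_avg", "F1_sd")],
          row.names = FALSE)
  }
  if (!is.null(x$ttests)) {
    cat("corrected t-tests against the reference variant:\n")
    print(x$ttests, row.names = FALSE)
  }
  invisible(x)
}
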
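# Bag-of-words / bag-of-concepts vectorization.
#
# The design matrix of a cohort is x = V (+) C: a field-prefixed word-count
# block concatenated with a concept-count block.  Values are raw occurrence
# counts for both blocks; no tf-idf, no binarization.

#' Bag-of-words of an aggregated record
#'
#' Each token contributes to the feature `"<field-prefix>:<token>"`, so the
#' same word in two fields (e.g., personal vs. family history) yields two
#' distinct features.
#'
#' @param record an aggregated record from [aggregate_record()].
#' @param field_scope fields whose text is tokenized.
#' @return named integer vector of token counts (possibly empty).
#' @export
build_bow <- function(record, field_scope = FULL_SCOPE) {
  unknown <- setdiff(field_scope, names(FIELD_PREFIX))
  if (length(unknown)) stop("unknown field(s) in scope: ",
                            paste(unknown, collapse = ", "))
  counts <- integer()
  for (f in intersect(field_scope, names(record$texts))) {
    toks <- tokenize_text(record$texts[[f]])[[1]]
    if (!length(toks)) next
    tab <- table(paste0(FIELD_PREFIX[[f]], ":", toks))
    counts <- c(counts, stats::setNames(as.integer(tab), names(tab)))
  }
  if (!length(counts)) return(stats::setNames(integer(), character()))
  tapply_sum <- tapply(counts, names(counts), sum)
  stats::setNames(as.integer(tapply_sum), names(tapply_sum))
}

#' Bag-of-concepts of an extraction result
#'
#' One feature per distinct (source, property, concept); the value is the
#' accumulated occurrence count.
#'
#' @param atoms concept atoms from [extract_all()].
#' @return named integer vector of concept counts.
#' @export
build_boc <- function(atoms) {
  if (!nrow(atoms)) return(stats::setNames(integer(), character()))
  atoms <- aggregate_atoms(atoms)
  stats::setNames(as.integer(atoms$count), atom_feature_names(atoms))
}

#' Concatenate a word vector and a concept vector
#'
#' @param v,c named count vectors from [build_bow()] / [build_boc()].
#' @return named vector of length `|v| + |c|` with an attribute `boundary`
#'   (the V-block width); the namespaces must not collide.
#' @export
concat_vectors <- function(v, c) {
  if (length(intersect(names(v), names(c))))
    stop("word / concept feature namespaces collide")
  out <- c(v, c)
  attr(out, "boundary") <- length(v)
  out
}

#' Assemble the patient x feature design matrix of a cohort
#'
#' One row per patient.  Hospitalized patients contribute only consultations
#' before the hospitalization plus static texts; non-hospitalized patients
#' contribute everything.  The vocabulary is the union over the cohort; word
#' columns come first (sorted), concept columns after (sorted).
#'
#' @param cohort a `kgemr_cohort`.
#' @param fixture a `kgemr_fixture`.
#' @param variant a variant name or [feature_set_spec()].
#' @param annotator optional annotator override for [extract_all()].
#' @return an object of class `kgemr_design`: list with `matrix` (a sparse
#'   [Matrix::dgCMatrix-class] of counts), `boundary` (number of word
#'   columns), `patient_ids`, `labels` (1 = hospitalized) and `variant`.
#' @export
assemble_design_matrix <- function(cohort, fixture, variant,
                                   annotator = NULL) {
  variant <- feature_set_spec(variant)
  if (variant$selection_mode == "manual_list" &&
      is.null(variant$concept_whitelist))
    stop("variant ", variant$name,
         " needs a concept_whitelist (derived from annotators or fold selections)")
  ids <- cohort$patients$patient_id
  rows <- list()
  keep_ids <- character()
  labels <- integer()
  for (pid in ids) {
    rec <- withCallingHandlers(
      aggregate_record(cohort, pid),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(rec)) {
      warning("excluding patient ", pid, ": no pre-hospitalization evidence")
      next
    }
    v <- build_bow(rec, variant$field_scope)
    atoms <- extract_all(rec, fixture, variant, annotator)
    rows[[pid]] <- concat_vectors(v, build_boc(atoms))
    keep_ids <- c(keep_ids, pid)
    labels <- c(labels, as.integer(rec$hospitalized))
  }
  v_cols <- sort(unique(unlist(lapply(rows, function(r)
    names(r)[seq_len(attr(r, "boundary"))]))))
  c_cols <- sort(unique(unlist(lapply(rows, function(r) {
    b <- attr(r, "boundary")
    if (length(r) > b) names(r)[(b + 1):length(r)] else character()
  }))))
  all_cols <- c(v_cols, c_cols)
  col_index <- stats::setNames(seq_along(all_cols), all_cols)
  trip <- lapply(seq_along(rows), function(r) {
    vec <- rows[[r]]
    if (!length(vec)) return(NULL)
    list(i = rep.int(r, length(vec)), j = unname(col_index[names(vec)]),
         x = as.integer(vec))
  })
  trip <- trip[!vapply(trip, is.null, TRUE)]
  m <- Matrix::sparseMatrix(i = unlist(lapply(trip, `[[`, "i")),
                            j = unlist(lapply(trip, `[[`, "j")),
                            x = unlist(lapply(trip, `[[`, "x")),
                            dims = c(length(rows), length(all_cols)),
                            dimnames = list(keep_ids, all_cols))
  out <- list(matrix = m, boundary = length(v_cols), patient_ids = keep_ids,
              labels = labels, variant = variant$name)
  class(out) <- "kgemr_design"
  out
}

#' @export
print.kgemr_design <- function(x, ...) {
  cat(sprintf(
    "<kgemr_design '%s': %d patients x (%d word + %d concept) features>\n",
    x$variant, nrow(x$matrix), x$boundary, ncol(x$matrix) - x$boundary))
  invisible(x)
}

#' Concept-block column names of a design
#' @param design a `kgemr_design`.
#' @return character vector (possibly empty).
#' @export
concept_columns <- function(design) {
  cols <- colnames(design$matrix)
  if (design$boundary >= length(cols)) character()
  else cols[(design$boundary + 1):length(cols)]
}

#' Persist a design matrix as MatrixMarket + sidecars
#' @param design a `kgemr_design`.
#' @param dir output directory; writes `matrix.mtx`, `rows.tsv`,
#'   `columns.tsv`, `meta.json`.
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(design$matrix, file.path(dir, "matrix.mtx"))
  write_tsv_raw(data.frame(patient_id = design$patient_ids,
                           label = design$labels),
                file.path(dir, "rows.tsv"))
  write_tsv_raw(data.frame(column = colnames(design$matrix),
                           block = c(rep("V", design$boundary),
                                     rep("C", ncol(design$matrix) - design$boundary))),
                file.path(dir, "columns.tsv"))
  jsonlite::write_json(list(variant = design$variant,
                            boundary = design$boundary),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}
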
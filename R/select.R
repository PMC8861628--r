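# L1-penalized concept selection inside the inner cross-validation loop.
#
# The penalized logistic model sees the full design matrix under a uniform
# L1 penalty: word features compete with concept features for signal, so a
# concept survives only when it predicts at least as well as the raw tokens
# it aggregates.  The selection is read exclusively off the concept columns;
# word features are never removed from the design, whatever their
# coefficients.  Columns are scaled to unit variance without centering to
# preserve sparsity.  (The field-prefixed bag-of-words has more columns than
# patients, so leaving the word block unpenalized would saturate the fit and
# make concept selection vacuous.)

#' Select concept features with an L1-penalized logistic model
#'
#' The L1-penalized logistic model is fit on the full standardized matrix
#' (word and concept columns under the same penalty); the penalty strength
#' is chosen by `L`-fold inner cross-validation over a log-spaced path (20
#' values), at the minimum of the cross-validated deviance.
#' Concepts with |coefficient| > 1e-8 at the chosen penalty are selected.
#' Word features are read out of the selection: they are never reported as
#' selected and never removed from the design.
#'
#' @param design a `kgemr_design`.
#' @param rows integer or logical index of training rows (default all).
#' @param inner_folds number of inner CV folds `L` (>= 2).
#' @param seed integer seed controlling the inner fold assignment.
#' @param lambda_choice `"lambda.min"` (default; the penalty minimizing the
#'   inner CV error, matching the usual cross-validated-lasso behavior) or
#'   `"lambda.1se"` for a sparser one-standard-error rule.
#' @param fold_index outer-fold index recorded on the result.
#' @return list of class `kgemr_fold_selection`: `fold` (index),
#'   `selected` (concept feature names), `lambda` (chosen penalty).
#' @export
lasso_select <- function(design, rows = seq_along(design$labels),
                         inner_folds = 3, seed = 1L,
                         lambda_choice = c("lambda.min", "lambda.1se"),
                         fold_index = NA_integer_) {
  lambda_choice <- match.arg(lambda_choice)
  # the penalty-path CV needs at least 3 folds
  inner_folds <- max(as.integer(inner_folds), 3L)
  x <- design$matrix[rows, , drop = FALSE]
  y <- design$labels[rows]
  if (length(unique(y)) < 2) stop("labels are constant on the training rows")
  c_cols <- concept_columns(design)
  res <- list(fold = fold_index, selected = character(), lambda = NA_real_)
  class(res) <- "kgemr_fold_selection"
  if (!length(c_cols)) return(res)

  # unit-variance scaling (no centering, to preserve sparsity)
  n <- nrow(x)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  sdv <- sqrt(pmax(ex2 - mu^2, 0) * n / max(n - 1, 1))
  keep <- sdv > 0
  if (!any(keep[colnames(x) %in% c_cols])) return(res)
  xs <- x[, keep, drop = FALSE] %*% Matrix::Diagonal(x = 1 / sdv[keep])
  colnames(xs) <- colnames(x)[keep]

  foldid <- stratified_folds(y, inner_folds, derive_seed(seed, "select"))
  fit <- glmnet::cv.glmnet(xs, y, family = "binomial", foldid = foldid,
                           standardize = FALSE, nlambda = 20)
  beta <- as.matrix(stats::coef(fit, s = lambda_choice))[-1, 1]
  sel <- names(beta)[abs(beta) > 1e-8]
  res$selected <- intersect(sel, c_cols)
  res$lambda <- fit[[lambda_choice]]
  res
}

#' Union of per-fold concept selections
#' @param selections list of `kgemr_fold_selection` (>= 1).
#' @return character vector: concepts selected in at least one fold.
#' @export
fold_union <- function(selections) {
  stopifnot(length(selections) >= 1)
  sort(unique(unlist(lapply(selections, `[[`, "selected"))))
}

#' Intersection of per-fold concept selections
#' @param selections list of `kgemr_fold_selection` (>= 1).
#' @return character vector: concepts selected in every fold.
#' @export
fold_intersection <- function(selections) {
  stopifnot(length(selections) >= 1)
  sets <- lapply(selections, `[[`, "selected")
  sort(Reduce(intersect, sets))
}

#' Binary machine-annotation matrix from fold selections
#'
#' Each outer fold acts as one machine annotator M_k over the concept
#' universe; the extra row U_1 is the union indicator (element-wise OR).
#'
#' @param selections list of `kgemr_fold_selection`.
#' @param universe concept feature names covering every selection.
#' @return 0/1 matrix with rows `M_1..M_K, U_1` and one column per concept;
#'   machine rows contain no missing cells.
#' @export
machine_annotation_vectors <- function(selections, universe) {
  sel_all <- unique(unlist(lapply(selections, `[[`, "selected")))
  if (!all(sel_all %in% universe))
    stop("selection contains concepts outside the universe")
  k <- length(selections)
  m <- matrix(0L, nrow = k + 1, ncol = length(universe),
              dimnames = list(c(paste0("M_", seq_len(k)), "U_1"), universe))
  for (i in seq_len(k)) m[i, selections[[i]]$selected] <- 1L
  m[k + 1, ] <- as.integer(colSums(m[seq_len(k), , drop = FALSE]) > 0)
  m
}
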
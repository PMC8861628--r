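# Nested cross-validation of hospitalization classifiers.
#
# Outer loop: stratified K-fold; inner loop: stratified L-fold scoring of
# hyperparameter draws from a random search.  When a variant uses lasso
# concept selection, selection runs on the training portion of each outer
# fold, before the estimator fit, so the test fold never influences it.

#' Nested cross-validation protocol
#'
#' @param K outer folds (>= 2).
#' @param L inner folds (>= 2).
#' @param n_iter random-search iterations (>= 1).
#' @param seed integer seed; drives fold assignment and the search draws.
#' @return list of class `kgemr_protocol`.
#' @export
cv_protocol <- function(K = 10, L = 3, n_iter = 150, seed = 1L) {
  stopifnot(K >= 2, L >= 2, n_iter >= 1)
  out <- list(K = as.integer(K), L = as.integer(L),
              n_iter = as.integer(n_iter), seed = as.integer(seed))
  class(out) <- "kgemr_protocol"
  out
}

#' Protocol presets
#'
#' `"screen"` is the light protocol (K=10, L=2, 7 iterations) used for
#' representation screening; `"strict"` the full protocol (K=10, L=3, 150
#' iterations) used for the enrichment comparison.
#'
#' @param name `"screen"` or `"strict"`.
#' @param seed integer seed.
#' @return a [cv_protocol()].
#' @export
protocol_preset <- function(name = c("screen", "strict"), seed = 1L) {
  switch(match.arg(name),
         screen = cv_protocol(10, 2, 7, seed),
         strict = cv_protocol(10, 3, 150, seed))
}

# One random hyperparameter draw per estimator.  Continuous parameters use
# exponential draws with scale 1; integer ranges are sampled uniformly.
draw_params <- function(estimator) {
  switch(estimator,
         lr = list(C = stats::rexp(1),
                   penalty = sample(c("l1", "l2"), 1)),
         rf = list(num_trees = sample(10:500, 1),
                   max_depth = sample(5:30, 1),
                   min_node = sample(1:30, 1)),
         svc = list(C = stats::rexp(1), gamma = stats::rexp(1),
                    kernel = sample(c("linear", "radial", "polynomial"), 1)),
         stop("unknown estimator: ", estimator))
}

# Fit on (x, y) and return a scoring closure over new rows:
# list(score = continuous score for class 1, class = 0/1 prediction).
fit_estimator <- function(estimator, params, x, y) {
  if (estimator == "lr") {
    lam <- 1 / (params$C * nrow(x))
    fit <- glmnet::glmnet(x, y, family = "binomial",
                          alpha = as.numeric(params$penalty == "l1"),
                          lambda = lam, standardize = FALSE)
    function(newx) {
      s <- as.numeric(stats::predict(fit, newx, type = "link"))
      list(score = s, class = as.integer(s > 0))
    }
  } else if (estimator == "rf") {
    df <- as.data.frame(as.matrix(x))
    names(df) <- paste0("f", seq_along(df))
    df$.y <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                          num.trees = params$num_trees,
                          max.depth = params$max_depth,
                          min.node.size = params$min_node,
                          num.threads = 1, seed = 1)
    function(newx) {
      nd <- as.data.frame(as.matrix(newx))
      names(nd) <- paste0("f", seq_along(nd))
      p1 <- stats::predict(fit, nd, num.threads = 1)$predictions[, "1"]
      list(score = p1, class = as.integer(p1 > 0.5))
    }
  } else if (estimator == "svc") {
    xm <- as.matrix(x)
    yf <- factor(y, levels = c(0, 1))
    fit <- e1071::svm(xm, yf, kernel = params$kernel, cost = params$C,
                      gamma = params$gamma, scale = FALSE)
    function(newx) {
      nm <- as.matrix(newx)
      pr <- stats::predict(fit, nm, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- dv[, 1]
      # orient the margin so larger = class "1"
      if (grepl("^0/1$", colnames(dv)[1])) s <- -s
      list(score = s, class = as.integer(as.character(pr)))
    }
  } else stop("unknown estimator: ", estimator)
}

confusion <- function(truth, pred) {
  c(TP = sum(truth == 1 & pred == 1), FP = sum(truth == 0 & pred == 1),
    FN = sum(truth == 1 & pred == 0), TN = sum(truth == 0 & pred == 0))
}

fold_metrics <- function(truth, pred, score) {
  cf <- confusion(truth, pred)
  pr <- if (cf["TP"] + cf["FP"] == 0) 0 else cf[["TP"]] / (cf[["TP"]] + cf[["FP"]])
  re <- if (cf["TP"] + cf["FN"] == 0) 0 else cf[["TP"]] / (cf[["TP"]] + cf[["FN"]])
  f1 <- if (2 * cf["TP"] + cf["FP"] + cf["FN"] == 0) 0 else
    2 * cf[["TP"]] / (2 * cf[["TP"]] + cf[["FP"]] + cf[["FN"]])
  auc <- if (length(unique(truth)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(truth, as.numeric(score),
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  list(counts = cf, PR = pr, RE = re, F1 = f1, AUC = auc)
}

#' Run the nested cross-validation experiment on one design
#'
#' @param design a `kgemr_design`.
#' @param protocol a [cv_protocol()].
#' @param estimator `"lr"`, `"rf"` or `"svc"`.
#' @param selection_mode `"none"` or `"lasso"`; with `"lasso"`, concept
#'   columns are filtered per outer fold by [lasso_select()] before the
#'   estimator fit.
#' @return list of class `kgemr_cv_result`: `fold_counts` (data frame of
#'   TP/FP/FN/TN per outer fold), `metrics` (per-fold PR/RE/F1/AUC),
#'   `params` (chosen hyperparameters per fold), `selections` (per-fold
#'   `kgemr_fold_selection`, lasso mode only), `pooled_f` and the protocol.
#' @export
nested_cv <- function(design, protocol = cv_protocol(), estimator = "lr",
                      selection_mode = c("none", "lasso")) {
  selection_mode <- match.arg(selection_mode)
  y <- design$labels
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < protocol$K)
    stop("fewer observations in the minority class than outer folds")
  outer <- stratified_folds(y, protocol$K, derive_seed(protocol$seed, "cv"))
  counts <- list(); mets <- list(); params <- list(); selections <- list()
  for (k in seq_len(protocol$K)) {
    train <- which(outer != k)
    test <- which(outer == k)
    cols <- colnames(design$matrix)
    if (selection_mode == "lasso") {
      sel <- lasso_select(design, rows = train, inner_folds = protocol$L,
                          seed = protocol$seed + k, fold_index = k)
      selections[[k]] <- sel
      cols <- c(cols[seq_len(design$boundary)], sel$selected)
    }
    x <- design$matrix[, cols, drop = FALSE]
    ytr <- y[train]
    # seeded random search, inner-CV scored by mean F1
    set.seed(derive_seed(protocol$seed * 1000 + k, "search"))
    cand <- replicate(protocol$n_iter, draw_params(estimator),
                      simplify = FALSE)
    inner <- stratified_folds(ytr, protocol$L,
                              derive_seed(protocol$seed * 1000 + k, "cv"))
    best <- NULL; best_score <- -Inf
    for (p in cand) {
      f1s <- vapply(seq_len(protocol$L), function(l) {
        tr <- train[inner != l]; va <- train[inner == l]
        sc <- fit_estimator(estimator, p, x[tr, , drop = FALSE], y[tr])
        pred <- sc(x[va, , drop = FALSE])
        fold_metrics(y[va], pred$class, pred$score)$F1
      }, 0)
      m <- mean(f1s)
      if (m > best_score) { best_score <- m; best <- p }   # first-best ties
    }
    params[[k]] <- best
    sc <- fit_estimator(estimator, best, x[train, , drop = FALSE], ytr)
    pred <- sc(x[test, , drop = FALSE])
    fm <- fold_metrics(y[test], pred$class, pred$score)
    counts[[k]] <- fm$counts
    mets[[k]] <- data.frame(fold = k, PR = fm$PR, RE = fm$RE, F1 = fm$F1,
                            AUC = fm$AUC)
  }
  fold_counts <- as.data.frame(do.call(rbind, counts))
  fold_counts <- cbind(fold = seq_len(protocol$K), fold_counts)
  out <- list(fold_counts = fold_counts, metrics = do.call(rbind, mets),
              params = params, selections = selections,
              pooled_f = f_tp_fp(fold_counts), protocol = protocol,
              estimator = estimator, variant = design$variant)
  class(out) <- "kgemr_cv_result"
  out
}

#' @export
print.kgemr_cv_result <- function(x, ...) {
  cat(sprintf("<kgemr_cv_result '%s' (%s): pooled F = %.4f, mean F1 = %.4f>\n",
              x$variant, x$estimator, x$pooled_f, mean(x$metrics$F1)))
  invisible(x)
}

#' Corrected t-test table of variants against a baseline
#'
#' All results must come from the same outer split (same protocol seed) so
#' the per-fold metric differences are paired.
#'
#' @param results named list of `kgemr_cv_result` (names = variant labels).
#' @param baseline name of the reference entry in `results`.
#' @param metric per-fold metric column to compare (default `"F1"`).
#' @return data frame: `variant`, `t`, `p`; `NA`s (flagged `identical`)
#'   where the per-fold differences are constant.
#' @export
compare_variants <- function(results, baseline = "baseline", metric = "F1") {
  stopifnot(baseline %in% names(results))
  base <- results[[baseline]]
  k <- base$protocol$K
  rows <- lapply(setdiff(names(results), baseline), function(nm) {
    r <- results[[nm]]
    if (nrow(r$metrics) != nrow(base$metrics))
      stop("mismatched fold counts for variant ", nm)
    tt <- tryCatch(
      corrected_ttest(r$metrics[[metric]], base$metrics[[metric]],
                      n1 = k - 1, n2 = 1),
      error = function(e) list(t = NA_real_, p = NA_real_))
    data.frame(variant = nm, t = tt$t, p = tt$p,
               identical = is.na(tt$t) &&
                 all(r$metrics[[metric]] == base$metrics[[metric]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus concept sets from an annotation matrix
#'
#' Derives the whitelist for the intersection / union feature-set variants:
#' concepts judged relevant by all annotators (`"all"`) or by at least one
#' (`"any"`).  Missing cells count as not-relevant for that annotator.
#'
#' @param m annotation matrix (rows = annotators, columns = concepts) with
#'   values `"relevant"` / `"irrelevant"` or 1 / 0; `NA` allowed.
#' @param mode `"all"` (intersection) or `"any"` (union).
#' @return character vector of concept column names.
#' @export
annotation_consensus <- function(m, mode = c("all", "any")) {
  mode <- match.arg(mode)
  rel <- if (is.character(m)) m == "relevant" else m == 1
  rel[is.na(rel)] <- FALSE
  keep <- if (mode == "all") colSums(rel) == nrow(rel) else colSums(rel) > 0
  colnames(m)[keep]
}

#' Simulate annotators copying a hidden truth
#'
#' Each annotator labels every concept of the universe: with probability
#' `agreement` the hidden truth label is copied, otherwise it is flipped.
#' `agreement = 1` gives identical annotators; `agreement = 0.5` gives
#' chance-level agreement (alpha near 0 in expectation).
#'
#' @param universe concept names (columns of the matrix).
#' @param n_annotators number of annotators (>= 2).
#' @param agreement copy probability in `[0, 1]`.
#' @param seed integer seed.
#' @return character matrix (`"relevant"` / `"irrelevant"`), rows
#'   `A_1..A_n`, no missing cells.
#' @export
simulate_annotators <- function(universe, n_annotators = 3, agreement = 0.8,
                                seed = 1L) {
  if (n_annotators < 2) stop("need at least 2 annotators")
  if (agreement < 0 || agreement > 1) stop("agreement must be in [0, 1]")
  if (!length(universe)) stop("universe must be non-empty")
  set.seed(derive_seed(seed, "annotate"))
  truth <- stats::rbinom(length(universe), 1, 0.5)
  m <- matrix(NA_character_, n_annotators, length(universe),
              dimnames = list(paste0("A_", seq_len(n_annotators)), universe))
  for (i in seq_len(n_annotators)) {
    copy <- stats::rbinom(length(universe), 1, agreement) == 1
    lab <- ifelse(copy, truth, 1 - truth)
    m[i, ] <- ifelse(lab == 1, "relevant", "irrelevant")
  }
  m
}
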
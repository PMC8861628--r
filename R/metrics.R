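# Evaluation metrics and statistical tests.

#' Pooled F1 across cross-validation folds
#'
#' Confusion counts are summed over all folds before the F1 formula is
#' applied: F = 2 TP_f / (2 TP_f + FP_f + FN_f).  With a single fold this is
#' the ordinary F1.
#'
#' @param counts data frame with columns `TP`, `FP`, `FN` (one row per fold;
#'   a `TN` column may be present and is ignored by the formula).
#' @return pooled score in `[0, 1]`.
#' @export
f_tp_fp <- function(counts) {
  tp <- sum(counts$TP); fp <- sum(counts$FP); fn <- sum(counts$FN)
  denom <- 2 * tp + fp + fn
  if (denom == 0) stop("pooled F undefined: TP + FP + FN = 0")
  2 * tp / denom
}

#' Per-fold metric averages and standard deviations
#' @param metrics data frame of per-fold metrics (numeric columns, e.g.
#'   `PR`, `RE`, `F1`, `AUC`).
#' @return data frame with one row per metric: `metric`, `mean`, `sd`
#'   (sample standard deviation).
#' @export
avg_metrics <- function(metrics) {
  num <- metrics[vapply(metrics, is.numeric, TRUE)]
  num <- num[setdiff(names(num), "fold")]
  data.frame(metric = names(num),
             mean = vapply(num, mean, 0),
             sd = vapply(num, stats::sd, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variance-corrected dependent t-test for cross-validated metrics
#'
#' Per-fold differences x_j = A_j - B_j violate the independence assumption
#' of the ordinary paired t-test because the training sets overlap; the
#' corrected statistic inflates the variance by (1/n + n2/n1), with n1 / n2
#' the training / testing fold counts of the resampling:
#' t = mean(x) / sqrt((1/n + n2/n1) * var(x)).
#'
#' @param a,b equal-length per-fold metric vectors of the two methods.
#' @param n1,n2 training and testing fold counts (defaults 9 and 1, the K=10
#'   cross-validation split).
#' @return list with `t`, `p` (two-sided, n-1 degrees of freedom), `df`,
#'   `mean_diff`.  Errors when the differences are constant (zero variance).
#' @export
corrected_ttest <- function(a, b, n1 = 9, n2 = 1) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  x <- a - b
  n <- length(x)
  s2 <- stats::var(x)
  if (s2 == 0) stop("zero variance of per-fold differences; corrected t undefined")
  t <- mean(x) / sqrt((1 / n + n2 / n1) * s2)
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       mean_diff = mean(x))
}

#' Krippendorff's alpha (nominal level)
#'
#' Computed from the coincidence matrix; cells marked missing (NA) are
#' excluded, and units with fewer than two non-missing labels do not
#' contribute.
#'
#' @param m annotation matrix: rows = annotators, columns = units, values =
#'   labels (any atomic type), `NA` = missing.
#' @return alpha in `[-1, 1]` (1 = perfect agreement, 0 = chance level).
#' @export
krippendorff_alpha <- function(m) {
  stopifnot(nrow(m) >= 2)
  vals <- sort(unique(stats::na.omit(as.vector(m))))
  if (length(vals) < 2) return(1)
  nv <- length(vals)
  coin <- matrix(0, nv, nv, dimnames = list(vals, vals))
  for (u in seq_len(ncol(m))) {
    col <- m[, u]
    col <- col[!is.na(col)]
    mu <- length(col)
    if (mu < 2) next
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i == j) next
      coin[as.character(col[i]), as.character(col[j])] <-
        coin[as.character(col[i]), as.character(col[j])] + 1 / (mu - 1)
    }
  }
  n_tot <- sum(coin)
  if (n_tot == 0) stop("no pairable values: every unit has < 2 labels")
  nc <- rowSums(coin)
  d_o <- sum(coin) - sum(diag(coin))
  d_e <- (sum(outer(nc, nc)) - sum(nc^2)) / (n_tot - 1)
  if (d_e == 0) return(1)
  1 - d_o / d_e
}

#' Correlation distance between annotation vectors
#'
#' 1 - centered cosine: 0 = perfect correlation, 1 = no correlation,
#' 2 = perfect negative correlation.
#'
#' @param u,v equal-length numeric vectors; both must be non-constant.
#' @return value in `[0, 2]`.
#' @export
correlation_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  uc <- u - mean(u); vc <- v - mean(v)
  nu <- sqrt(sum(uc^2)); nv <- sqrt(sum(vc^2))
  if (nu == 0 || nv == 0) stop("correlation distance undefined for a constant vector")
  1 - sum(uc * vc) / (nu * nv)
}

#' Absolute risk reduction in percentage points
#' @param p0 risk without intervention, in percent.
#' @param p1 risk with intervention, in percent (`0 <= p1 <= p0 <= 100`).
#' @return `p0 - p1`, in percentage points.
#' @export
absolute_risk_reduction <- function(p0, p1) {
  if (p1 > p0) stop("treated risk exceeds untreated risk")
  stopifnot(p0 <= 100, p1 >= 0)
  p0 - p1
}

#' Relative risk reduction in percent (rounded)
#' @inheritParams absolute_risk_reduction
#' @return `round(100 * (p0 - p1) / p0)`.
#' @export
relative_risk_gain <- function(p0, p1) {
  if (p0 <= 0) stop("untreated risk must be positive")
  if (p1 > p0) stop("treated risk exceeds untreated risk")
  round(100 * (p0 - p1) / p0)
}
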
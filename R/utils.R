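# Shared helpers: text normalization, tokenization, seeding, folds.

#' Normalize clinical text for matching
#'
#' Unicode NFC normalization followed by lowercasing.  Accents are preserved:
#' the source labels are French and transliteration would merge distinct
#' surface forms.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfc(as.character(x)))
}

#' Tokenize free text
#'
#' Tokens are runs of Unicode letters/digits of length >= 2, taken after
#' [normalize_text()]; hyphenated compounds are split.  The tokenizer is
#' deliberately simple and is the single place where word features are defined.
#'
#' @param x character vector of texts.
#' @return list of character vectors of tokens (one element per input text).
#' @export
tokenize_text <- function(x) {
  x <- normalize_text(x)
  x <- gsub("-", " ", x, fixed = TRUE)
  stringi::stri_extract_all_regex(x, "[\\p{L}\\p{N}]{2,}", omit_no_match = TRUE)
}

# Derive a stage seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, fixture = 23L, cv = 37L, select = 53L,
               annotate = 71L, search = 89L, null = 101L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 7919 + off * 104729) %% 2147483647)
}

# Stratified K-fold assignment: returns an integer fold id per observation.
# Both classes are spread as evenly as possible across folds.
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  y <- as.integer(y)
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) stop("fewer observations of class ", cls,
                              " than folds (k = ", k, ")")
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
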
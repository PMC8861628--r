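# Entity annotation.
#
# Annotation is a pluggable contract: any function text -> mention data frame
# can stand in (e.g., a client for a statistical semantic annotator).  The
# default, used throughout the tests, is a dictionary annotator: abbreviation
# keys are expanded token-wise, then surface forms are matched
# longest-match-first without overlaps on the normalized text.

#' Annotate free text with dictionary entities
#'
#' Matching happens after [normalize_text()] (NFC + lowercase); abbreviation
#' keys are expanded to their dictionary form first, so an abbreviated
#' mention links to the same entity as the full surface form.  Character
#' offsets refer to the normalized, abbreviation-expanded text.
#'
#' @param text a single character string.
#' @param surface_forms data frame with columns `surface`, `iri`.
#' @param abbreviations optional data frame with columns `key`, `expansion`;
#'   keys are replaced as whole tokens before matching.
#' @param field field name recorded on the mentions (provenance only).
#' @return data frame with columns `surface`, `iri`, `field`, `start`
#'   (1-based offset); zero rows for empty text or no match.
#' @export
annotate_text <- function(text, surface_forms, abbreviations = NULL,
                          field = NA_character_) {
  empty <- data.frame(surface = character(), iri = character(),
                      field = character(), start = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(trimws(text))) return(empty)
  txt <- normalize_text(text)
  if (!is.null(abbreviations) && nrow(abbreviations)) {
    keys <- normalize_text(abbreviations$key)
    exps <- normalize_text(abbreviations$expansion)
    # cheap fixed-string pre-filter before the word-boundary replacement
    present <- which(stringi::stri_detect_fixed(txt, keys))
    for (i in present[order(-nchar(keys[present]))]) {
      txt <- stringi::stri_replace_all_regex(
        txt, paste0("\\b", stringi::stri_replace_all_regex(
          keys[i], "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"), "\\b"),
        stringi::stri_replace_all_fixed(exps[i], "$", "\\$"))
    }
  }
  surfaces <- normalize_text(surface_forms$surface)
  cand <- list()
  for (i in which(stringi::stri_detect_fixed(txt, surfaces))) {
    pat <- paste0("\\b", stringi::stri_replace_all_regex(
      surfaces[i], "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"), "\\b")
    m <- stringi::stri_locate_all_regex(txt, pat)[[1]]
    if (!is.na(m[1, 1])) {
      cand[[length(cand) + 1]] <- data.frame(
        surface = surfaces[i], iri = surface_forms$iri[i],
        start = m[, 1], end = m[, 2], stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # longest match wins; ties broken by position then dictionary order
  cand <- cand[order(-(cand$end - cand$start), cand$start), ]
  taken <- logical(nchar(txt))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), ]
  data.frame(surface = out$surface, iri = out$iri, field = field,
             start = out$start, stringsAsFactors = FALSE)
}

#' Build the default dictionary annotator for a fixture
#'
#' @param fixture a `kgemr_fixture`.
#' @return a function `(text, field)` returning mentions, satisfying the
#'   annotator contract used by [extract_all()].
#' @export
dictionary_annotator <- function(fixture) {
  force(fixture)
  function(text, field = NA_character_) {
    annotate_text(text, fixture$surface_forms, fixture$abbreviations, field)
  }
}
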
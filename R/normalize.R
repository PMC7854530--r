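#' Normalize a registered-organization owner name into a match key
#'
#' Ownership networks are keyed on the exact legal name of each
#' registered-organization owner. Public filings of the same entity differ
#' only in punctuation and spacing, so the match key is the raw name with
#' all commas and periods removed, runs of whitespace collapsed to a single
#' space, ends trimmed, and case folded to upper case. No other
#' canonicalization is applied: "LLC" and "L L C" remain distinct keys,
#' because the legal-name convention makes aggressive suffix folding unsafe.
#'
#' The transformation is deterministic and idempotent: normalizing a key
#' returns the key itself.
#'
#' @param raw Character vector of raw owner names.
#' @return Character vector of match keys, same length as `raw`. Empty or
#'   `NA` input yields an empty key (`""`); callers are expected to flag
#'   such records upstream.
#' @examples
#' normalize_owner_name("SUNRISE  CARE, L.L.C.")  # "SUNRISE CARE LLC"
#' @export
normalize_owner_name <- function(raw) {
  key <- ifelse(is.na(raw), "", as.character(raw))
  key <- stringr::str_remove_all(key, "[,.]")
  key <- stringr::str_squish(key)
  stringr::str_to_upper(key)
}

#' Restrict owner records to registered organizations
#'
#' Network construction excludes facilities owned solely by individuals:
#' only organization-kind owner ties participate in the bipartite graph.
#' Records whose `owner_kind` is not `"organization"` are dropped and the
#' dropped count is reported via a message.
#'
#' @param records A data frame of owner records with at least an
#'   `owner_kind` column (values `"organization"` or `"individual"`).
#' @param quiet Suppress the dropped-record message.
#' @return A tibble containing only organization-kind rows.
#' @export
filter_registered_organizations <- function(records, quiet = FALSE) {
  stopifnot("owner_kind" %in% names(records))
  out <- dplyr::filter(records, .data$owner_kind == "organization")
  n_dropped <- nrow(records) - nrow(out)
  if (n_dropped > 0 && !quiet) {
    message(n_dropped, " individual-owner record(s) excluded from network construction")
  }
  tibble::as_tibble(out)
}
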
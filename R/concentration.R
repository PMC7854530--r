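#' Herfindahl-Hirschman Index of bed-share concentration
#'
#' For facilities with certified-bed counts \eqn{b_i} in one focal area
#' (HRR), \deqn{HHI = \sum_i (b_i / \sum_j b_j)^2.} Reported on the 0-1
#' scale. Facilities with zero beds carry no market share and are excluded
#' with a warning; a market with zero total beds is undefined.
#'
#' @param beds Numeric vector of per-facility certified-bed counts.
#' @return HHI in (0, 1]; `1/n <= HHI <= 1` for `n` facilities.
#' @examples
#' hhi(c(50, 50))         # 0.5
#' hhi(c(30, 30, 30, 30)) # 0.25
#' @export
hhi <- function(beds) {
  beds <- check_beds(beds)
  shares <- beds / sum(beds)
  sum(shares^2)
}

check_beds <- function(beds) {
  stopifnot(is.numeric(beds), length(beds) >= 1)
  if (any(is.na(beds) | beds < 0)) stop("bed counts must be non-negative and non-missing", call. = FALSE)
  if (any(beds == 0)) {
    warning(sum(beds == 0), " facilit(ies) with zero certified beds excluded from concentration index",
            call. = FALSE)
    beds <- beds[beds > 0]
  }
  if (!length(beds) || sum(beds) == 0) stop("undefined market: total certified beds is zero", call. = FALSE)
  beds
}

#' Affiliation-accounted Herfindahl-Hirschman Index
#'
#' HHI computed after pooling the beds of facilities belonging to the same
#' ownership group: each group contributes one squared share of its pooled
#' beds, each ungrouped (single-affiliation) facility contributes its own.
#' Pooling squared shares is superadditive, so `AHHI >= HHI` always; the
#' excess is the concentration attributable purely to super-organization.
#'
#' @param facilities Tibble with columns `provider_id` and `beds` for one
#'   HRR and date.
#' @param groups Tibble with columns `provider_id` and `group_id` (e.g.
#'   from [detect_ownership_groups()]); facilities absent from it are
#'   treated as standalone. A facility in two groups is a partition error.
#' @return AHHI in (0, 1].
#' @export
ahhi <- function(facilities, groups = NULL) {
  stopifnot(all(c("provider_id", "beds") %in% names(facilities)))
  if (anyDuplicated(facilities$provider_id)) stop("duplicate provider_id in facilities", call. = FALSE)
  unit <- facilities$provider_id
  if (!is.null(groups) && nrow(groups)) {
    if (anyDuplicated(groups$provider_id)) {
      stop("partition error: facility assigned to more than one ownership group", call. = FALSE)
    }
    idx <- match(facilities$provider_id, groups$provider_id)
    unit[!is.na(idx)] <- paste0("group:", groups$group_id[idx[!is.na(idx)]])
  }
  pooled <- tapply(facilities$beds, unit, sum)
  hhi(as.numeric(pooled))
}

#' Concentration gain attributable to super-organization
#'
#' `delta = AHHI - HHI` on the same beds and partition; non-negative by
#' superadditivity of squared shares.
#'
#' @inheritParams ahhi
#' @return Non-negative real.
#' @export
delta_hhi <- function(facilities, groups = NULL) {
  ahhi(facilities, groups) - hhi(facilities$beds)
}

#' Concentration record for one HRR and date
#'
#' @inheritParams ahhi
#' @param hrr,date Identifiers carried into the output row.
#' @return One-row tibble: `hrr`, `date`, `n_facilities`, `total_beds`,
#'   `hhi`, `ahhi`, `delta`.
#' @export
concentration_record <- function(facilities, groups = NULL, hrr = NA, date = NA) {
  h <- hhi(facilities$beds)
  a <- ahhi(facilities, groups)
  tibble::tibble(hrr = hrr, date = date,
                 n_facilities = nrow(facilities),
                 total_beds = sum(facilities$beds),
                 hhi = h, ahhi = a, delta = a - h)
}
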
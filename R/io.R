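#' Default column mapping for the Nursing Home Compare CSV dialect
#'
#' CMS renamed columns across releases, so every reader takes a mapping
#' from internal field names to CSV header names. The defaults match the
#' 2016-2018 Nursing Home Compare headers.
#'
#' @param ... Named overrides, e.g. `provider_id = "PROVNUM"`.
#' @return Named list mapping internal field names to CSV column names.
#' @export
nhc_columns <- function(...) {
  defaults <- list(
    provider_id       = "Federal Provider Number",
    zip               = "Provider Zip Code",
    state             = "Provider State",
    beds              = "Number of Certified Beds",
    residents         = "Number of Residents in Certified Beds",
    occupancy_pct     = "Occupancy Percentage",
    years_in_business = "Years in Business",
    ownership_type    = "Ownership Type",
    hospital_based    = "Provider Resides in Hospital",
    sff               = "Special Focus Facility",
    ccrc              = "Continuing Care Retirement Community",
    council           = "With a Resident and Family Council",
    ownership_changed = "Provider Changed Ownership in Last 12 Months",
    staffing_cna_hrd  = "Adjusted CNA Staffing Hours per Resident per Day",
    staffing_lpn_hrd  = "Adjusted LPN Staffing Hours per Resident per Day",
    staffing_rn_hrd   = "Adjusted RN Staffing Hours per Resident per Day",
    five_star         = "Overall Rating",
    twhss             = "Total Weighted Health Survey Score",
    owner_name        = "Owner Name",
    owner_type        = "Owner Type",
    cw_zip            = "zip",
    cw_hrr_id         = "hrr_id",
    cw_hrr_name       = "hrr_name"
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown column mapping field(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, overrides)
}

# Round half away from zero; the deficiency score is discretized to the
# nearest integer before Poisson modelling and base round() is half-to-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

require_columns <- function(df, cols, path) {
  missing <- setdiff(unname(unlist(cols)), names(df))
  if (length(missing)) {
    stop("format error in '", path, "': missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a provider-characteristics table for one processing date
#'
#' Parses one NHC-dialect CSV of facility characteristics into a snapshot
#' tibble (one row per facility). Numeric fields are parsed, the weighted
#' health-survey score is discretized to the nearest integer
#' (half away from zero), and invariant violations are recorded in a
#' `flags` column rather than imputed or dropped.
#'
#' Flagged invariants: occupancy outside \[0, 100\]; residents exceeding
#' certified beds; a five-star rating outside 1..5; negative staffing
#' hours. Missing covariates are left `NA` and flagged.
#'
#' @param path CSV file path.
#' @param date Processing-date index (1-based position in the study window).
#' @param columns Column mapping from [nhc_columns()].
#' @return Tibble with one row per facility: identifiers, covariates,
#'   `twhss`, `twhss_int`, and a `flags` character column ("" when clean).
#' @export
read_provider_table <- function(path, date, columns = nhc_columns()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  fields <- c("provider_id", "zip", "state", "beds", "residents", "occupancy_pct",
              "years_in_business", "ownership_type", "hospital_based", "sff",
              "ccrc", "council", "ownership_changed", "staffing_cna_hrd",
              "staffing_lpn_hrd", "staffing_rn_hrd", "five_star", "twhss")
  require_columns(raw, columns[fields], path)

  out <- tibble::tibble(
    provider_id = raw[[columns$provider_id]],
    date = as.integer(date),
    zip = raw[[columns$zip]],
    state = raw[[columns$state]],
    beds = suppressWarnings(as.numeric(raw[[columns$beds]])),
    residents = suppressWarnings(as.numeric(raw[[columns$residents]])),
    occupancy_pct = suppressWarnings(as.numeric(raw[[columns$occupancy_pct]])),
    years_in_business = suppressWarnings(as.numeric(raw[[columns$years_in_business]])),
    ownership_type = raw[[columns$ownership_type]],
    hospital_based = parse_yes_no(raw[[columns$hospital_based]]),
    sff = parse_yes_no(raw[[columns$sff]]),
    ccrc = parse_yes_no(raw[[columns$ccrc]]),
    council = parse_yes_no(raw[[columns$council]]),
    ownership_changed = parse_yes_no(raw[[columns$ownership_changed]]),
    staffing_cna_hrd = suppressWarnings(as.numeric(raw[[columns$staffing_cna_hrd]])),
    staffing_lpn_hrd = suppressWarnings(as.numeric(raw[[columns$staffing_lpn_hrd]])),
    staffing_rn_hrd = suppressWarnings(as.numeric(raw[[columns$staffing_rn_hrd]])),
    five_star = suppressWarnings(as.integer(raw[[columns$five_star]])),
    twhss = suppressWarnings(as.numeric(raw[[columns$twhss]]))
  )
  if (anyDuplicated(out$provider_id)) {
    dup <- unique(out$provider_id[duplicated(out$provider_id)])
    stop("linkage error in '", path, "': duplicate provider id(s) within one date: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  out$twhss_int <- round_half_away(out$twhss)
  out$flags <- snapshot_flags(out)
  out
}

parse_yes_no <- function(x) {
  up <- toupper(trimws(as.character(x)))
  dplyr::case_when(
    up %in% c("YES", "Y", "TRUE", "1") ~ TRUE,
    up %in% c("NO", "N", "FALSE", "0") ~ FALSE,
    .default = NA
  )
}

snapshot_flags <- function(df) {
  flag_of <- function(cond, label) ifelse(!is.na(cond) & cond, label, NA_character_)
  covars <- c("beds", "residents", "occupancy_pct", "years_in_business",
              "ownership_type", "hospital_based", "sff", "ccrc", "council",
              "ownership_changed", "staffing_cna_hrd", "staffing_lpn_hrd",
              "staffing_rn_hrd", "twhss")
  miss <- rowSums(is.na(df[covars])) > 0
  mat <- cbind(
    flag_of(df$occupancy_pct < 0 | df$occupancy_pct > 100, "occupancy_out_of_range"),
    flag_of(df$residents > df$beds, "residents_exceed_beds"),
    flag_of(df$beds < 0 | df$residents < 0, "negative_count"),
    flag_of(!is.na(df$five_star) & !(df$five_star %in% 1:5), "five_star_out_of_range"),
    flag_of(df$staffing_cna_hrd < 0 | df$staffing_lpn_hrd < 0 | df$staffing_rn_hrd < 0,
            "negative_staffing"),
    flag_of(miss, "missing_covariate")
  )
  apply(mat, 1, function(r) paste(stats::na.omit(r), collapse = ";"))
}

#' Read an ownership table for one processing date
#'
#' Parses one NHC-dialect ownership CSV into owner-facility tie records.
#' The raw owner name is normalized into a match key with
#' [normalize_owner_name()]; the owner-type column is mapped to
#' `owner_kind` (`"individual"` when the type mentions an individual,
#' `"organization"` otherwise). Rows with an empty owner name are skipped
#' with a warning.
#'
#' @inheritParams read_provider_table
#' @return Tibble with columns `provider_id`, `owner_name_raw`,
#'   `owner_key`, `owner_kind`, `date`.
#' @export
read_ownership_table <- function(path, date, columns = nhc_columns()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(raw, columns[c("provider_id", "owner_name", "owner_type")], path)
  out <- tibble::tibble(
    provider_id = raw[[columns$provider_id]],
    owner_name_raw = raw[[columns$owner_name]],
    owner_key = normalize_owner_name(raw[[columns$owner_name]]),
    owner_kind = ifelse(grepl("individual", raw[[columns$owner_type]], ignore.case = TRUE),
                        "individual", "organization"),
    date = as.integer(date)
  )
  empty <- is.na(out$owner_name_raw) | out$owner_key == ""
  if (any(empty)) {
    warning(sum(empty), " ownership record(s) with empty owner name skipped in '",
            path, "'", call. = FALSE)
    out <- out[!empty, ]
  }
  out
}

#' Read an MDS quality-measure prevalence table for one processing date
#'
#' Long-format CSV of facility-level resident quality-measure prevalences
#' ("Measure Code", "Measure Value" percentages), pivoted wide to one
#' `mds_<code>` column per measure code.
#'
#' @inheritParams read_provider_table
#' @return Tibble with `provider_id`, `date`, and one `mds_<code>` column
#'   per measure code present in the file.
#' @export
read_mds_table <- function(path, date, columns = nhc_columns()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(raw, columns["provider_id"], path)
  if (!all(c("Measure Code", "Measure Value") %in% names(raw))) {
    stop("format error in '", path,
         "': missing required column(s): Measure Code, Measure Value", call. = FALSE)
  }
  tibble::tibble(
    provider_id = raw[[columns$provider_id]],
    code = paste0("mds_", raw[["Measure Code"]]),
    value = suppressWarnings(as.numeric(raw[["Measure Value"]]))
  ) |>
    tidyr::pivot_wider(names_from = "code", values_from = "value") |>
    dplyr::mutate(date = as.integer(date), .after = "provider_id")
}

#' Read a ZIP-to-HRR crosswalk
#'
#' Facilities are placed into hospital referral regions (HRRs) by ZIP code.
#' The crosswalk must map each ZIP to exactly one HRR; duplicate ZIP rows
#' with conflicting HRRs are a format error, identical duplicates are
#' dropped.
#'
#' @inheritParams read_provider_table
#' @return Tibble with columns `zip`, `hrr_id`, `hrr_name`.
#' @export
read_crosswalk <- function(path, columns = nhc_columns()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  require_columns(raw, columns[c("cw_zip", "cw_hrr_id", "cw_hrr_name")], path)
  out <- tibble::tibble(
    zip = raw[[columns$cw_zip]],
    hrr_id = raw[[columns$cw_hrr_id]],
    hrr_name = raw[[columns$cw_hrr_name]]
  ) |> dplyr::distinct()
  if (anyDuplicated(out$zip)) {
    dup <- unique(out$zip[duplicated(out$zip)])
    stop("format error in '", path, "': ZIP(s) mapped to conflicting HRRs: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Resolve ZIP codes to HRR identifiers
#'
#' Total lookup over the supplied ZIPs: any ZIP absent from the crosswalk
#' is an error naming the ZIP, never a silent `NA`.
#'
#' @param crosswalk Tibble from [read_crosswalk()].
#' @param zip Character vector of 5-digit ZIP codes.
#' @return Character vector of HRR ids, same length as `zip`.
#' @export
lookup_hrr <- function(crosswalk, zip) {
  idx <- match(zip, crosswalk$zip)
  if (anyNA(idx)) {
    missing <- unique(zip[is.na(idx)])
    stop("ZIP code(s) absent from crosswalk: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  crosswalk$hrr_id[idx]
}

#' Assemble the longitudinal facility panel
#'
#' Links per-date provider snapshots, owner records and (optionally) MDS
#' prevalences by Federal Provider Number, resolves each facility's HRR
#' from its ZIP, and computes the complete-case provider set: facilities
#' present at every processing date, with at least one
#' registered-organization owner at every date and all required covariates
#' non-missing at every date. Incomplete facilities are retained in the
#' panel but flagged; an empty complete set is a valid (empty-panel)
#' result, not an error.
#'
#' @param providers List of snapshot tibbles (one per date, from
#'   [read_provider_table()]) or one stacked tibble with a `date` column.
#' @param owners List of owner tibbles or one stacked tibble.
#' @param crosswalk Tibble from [read_crosswalk()].
#' @param mds Optional list of MDS tibbles or one stacked tibble; joined on
#'   (`provider_id`, `date`).
#' @param required_covariates Character vector of snapshot column names
#'   that must be non-missing at every date for a provider to be complete.
#' @return An object of class `nh_panel`: a list with `snapshots` (tibble,
#'   incl. `hrr` and `complete`), `owners` (tibble), `dates` (integer
#'   vector), and `complete_providers` (character vector).
#' @export
assemble_panel <- function(providers, owners, crosswalk,
                           mds = NULL,
                           required_covariates = panel_covariates("model1")) {
  snapshots <- if (is.data.frame(providers)) tibble::as_tibble(providers) else dplyr::bind_rows(providers)
  owner_tbl <- if (is.data.frame(owners)) tibble::as_tibble(owners) else dplyr::bind_rows(owners)
  stopifnot(nrow(snapshots) > 0, "date" %in% names(snapshots))
  if (!is.null(mds)) {
    mds_tbl <- if (is.data.frame(mds)) tibble::as_tibble(mds) else dplyr::bind_rows(mds)
    snapshots <- dplyr::left_join(snapshots, mds_tbl, by = c("provider_id", "date"))
  }
  snapshots$hrr <- lookup_hrr(crosswalk, snapshots$zip)
  dates <- sort(unique(snapshots$date))

  missing_cov <- setdiff(required_covariates, names(snapshots))
  if (length(missing_cov)) {
    stop("required covariate(s) absent from panel: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }

  # (a) snapshot at every date with all required covariates non-missing
  cov_ok <- snapshots |>
    dplyr::mutate(ok = rowSums(is.na(dplyr::pick(dplyr::all_of(required_covariates)))) == 0) |>
    dplyr::summarise(n_ok = sum(.data$ok), .by = "provider_id") |>
    dplyr::filter(.data$n_ok == length(dates))

  # (b) >=1 organization-kind owner at every date
  org_ok <- owner_tbl |>
    dplyr::filter(.data$owner_kind == "organization") |>
    dplyr::distinct(.data$provider_id, .data$date) |>
    dplyr::summarise(n_dates = dplyr::n(), .by = "provider_id") |>
    dplyr::filter(.data$n_dates == length(dates))

  complete_providers <- intersect(cov_ok$provider_id, org_ok$provider_id)
  snapshots$complete <- snapshots$provider_id %in% complete_providers

  structure(
    list(snapshots = snapshots, owners = owner_tbl, dates = as.integer(dates),
         complete_providers = complete_providers),
    class = "nh_panel"
  )
}

#' Required covariate sets for the two model variants
#'
#' Model 1 uses the five-star quality rating; Model 2 replaces it with the
#' individual MDS measure-code prevalences (the rating is derived from
#' them, so the two never enter one model together).
#'
#' @param variant `"model1"` or `"model2"`.
#' @param mds_codes Measure codes for model 2 (defaults to the 21 study
#'   codes).
#' @return Character vector of snapshot column names.
#' @export
panel_covariates <- function(variant = c("model1", "model2"),
                             mds_codes = nhc_mds_codes()) {
  variant <- match.arg(variant)
  base <- c("beds", "residents", "occupancy_pct", "years_in_business",
            "ownership_type", "hospital_based", "sff", "ccrc", "council",
            "ownership_changed", "staffing_cna_hrd", "staffing_lpn_hrd",
            "staffing_rn_hrd", "twhss")
  if (variant == "model1") c(base, "five_star") else c(base, paste0("mds_", mds_codes))
}

#' The 21 MDS quality-measure codes used as model 2 covariates
#'
#' Fifteen long-stay and six short-stay four-quarter-average prevalence
#' measures.
#'
#' @return Character vector of measure codes.
#' @export
nhc_mds_codes <- function() {
  c("401", "402", "403", "404", "405", "406", "407", "408", "409", "410",
    "411", "415", "419", "451", "452",          # long-stay
    "424", "425", "426", "430", "434", "471")   # short-stay
}

#' @export
print.nh_panel <- function(x, ...) {
  cat("<nh_panel> ", length(unique(x$snapshots$provider_id)), " facilities x ",
      length(x$dates), " dates (", length(x$complete_providers),
      " complete-case)\n", sep = "")
  cat("  HRRs: ", length(unique(x$snapshots$hrr)),
      "; states: ", length(unique(x$snapshots$state)), "\n", sep = "")
  invisible(x)
}

#' Write a panel's snapshot and owner tables to CSV
#'
#' One record per facility-date; the normalized-panel output consumed by
#' the network and regression stages can be re-read with
#' [read_panel_csv()] for a lossless round trip.
#'
#' @param panel An `nh_panel`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_panel_csv <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(snapshots = file.path(dir, "panel_snapshots.csv"),
             owners = file.path(dir, "panel_owners.csv"))
  readr::write_csv(panel$snapshots, paths["snapshots"])
  readr::write_csv(panel$owners, paths["owners"])
  invisible(paths)
}

#' Re-read a panel written by [write_panel_csv()]
#'
#' @param dir Directory containing the panel CSVs.
#' @param crosswalk Crosswalk tibble used to re-derive HRR membership.
#' @param required_covariates As in [assemble_panel()].
#' @return An `nh_panel`.
#' @export
read_panel_csv <- function(dir, crosswalk,
                           required_covariates = panel_covariates("model1")) {
  snapshots <- readr::read_csv(
    file.path(dir, "panel_snapshots.csv"),
    col_types = readr::cols(
      provider_id = readr::col_character(), zip = readr::col_character(),
      state = readr::col_character(), ownership_type = readr::col_character(),
      hrr = readr::col_character(), flags = readr::col_character(),
      date = readr::col_integer(), five_star = readr::col_integer(),
      complete = readr::col_logical(), hospital_based = readr::col_logical(),
      sff = readr::col_logical(), ccrc = readr::col_logical(),
      council = readr::col_logical(), ownership_changed = readr::col_logical(),
      .default = readr::col_double()
    ), progress = FALSE)
  snapshots$flags[is.na(snapshots$flags)] <- ""
  snapshots$hrr <- NULL
  snapshots$complete <- NULL
  owners <- readr::read_csv(
    file.path(dir, "panel_owners.csv"),
    col_types = readr::cols(date = readr::col_integer(),
                            .default = readr::col_character()),
    progress = FALSE)
  assemble_panel(snapshots, owners, crosswalk,
                 required_covariates = required_covariates)
}
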
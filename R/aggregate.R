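#' Run the network stage over every HRR and processing date
#'
#' For each HRR x date cell of the panel: build the bipartite
#' facility-owner graph from the organization-kind owner ties, project it
#' onto facilities, classify affiliation, detect ownership groups, and
#' compute the concentration record. This is step one of the two-step
#' procedure (networks first, regression second).
#'
#' @param panel An `nh_panel` from [assemble_panel()].
#' @param complete_only Restrict to the complete-case providers (the
#'   analysis sample); default `TRUE`.
#' @param resolution,seed Passed to [detect_ownership_groups()].
#' @param keep_graphs Also return the igraph objects (memory-heavy on
#'   large panels).
#' @return List of tibbles: `affiliation` (per facility x date),
#'   `groups` (per grouped facility x date), `concentration` (per HRR x
#'   date, incl. `n_coowners`), and optionally `graphs`.
#' @export
derive_networks <- function(panel, complete_only = TRUE,
                            resolution = 1, seed = 20160301,
                            keep_graphs = FALSE) {
  snaps <- panel$snapshots
  if (complete_only) snaps <- snaps[snaps$complete, ]
  owners <- filter_registered_organizations(panel$owners, quiet = TRUE)

  cells <- dplyr::distinct(snaps, .data$hrr, .data$date)
  res <- purrr::pmap(cells, function(hrr, date) {
    fac <- snaps[snaps$hrr == hrr & snaps$date == date, ]
    own <- owners[owners$date == date & owners$provider_id %in% fac$provider_id, ]
    g <- build_bipartite(own, fac, hrr = hrr, date = date)
    p <- project_facilities(g)
    aff <- classify_affiliation(p)
    grp <- detect_ownership_groups(p, resolution = resolution, seed = seed)
    conc <- concentration_record(fac[, c("provider_id", "beds")], grp,
                                 hrr = hrr, date = date)
    conc$n_coowners <- count_coowning_organizations(g, grp)
    conc$n_owners <- sum(igraph::V(g)$type)
    list(affiliation = aff, groups = grp, concentration = conc,
         graphs = if (keep_graphs) list(bipartite = g, projection = p))
  })
  out <- list(
    affiliation = dplyr::bind_rows(purrr::map(res, "affiliation")),
    groups = dplyr::bind_rows(purrr::map(res, "groups")),
    concentration = dplyr::bind_rows(purrr::map(res, "concentration"))
  )
  if (keep_graphs) {
    out$graphs <- purrr::map(res, "graphs")
    names(out$graphs) <- paste(cells$hrr, cells$date, sep = "/")
  }
  out
}

#' HRR-level super-organization metrics
#'
#' Joins the network-stage outputs into one record per HRR x date with the
#' five explanatory variables used at the focal-area level: prevalence of
#' multiple-affiliation facilities (%), mean ownership-group size, HHI,
#' AHHI and delta-HHI, plus bookkeeping counts. An HRR x date with no
#' ownership groups gets `mean_group_size = 1` (every facility standalone)
#' and `no_groups = TRUE`, so the regression covariate is defined
#' everywhere.
#'
#' @param networks Output of [derive_networks()].
#' @return Tibble, one row per HRR x date: `hrr`, `date`, `n_facilities`,
#'   `n_multiple`, `prevalence_multiple_pct`, `n_groups`,
#'   `mean_group_size`, `no_groups`, `hhi`, `ahhi`, `delta`,
#'   `n_coowners`, `n_owners`, `total_beds`.
#' @export
compute_hrr_metrics <- function(networks) {
  aff <- networks$affiliation |>
    dplyr::summarise(
      n_facilities = dplyr::n(),
      n_multiple = sum(.data$class == "multiple"),
      .by = c("hrr", "date")
    ) |>
    dplyr::mutate(prevalence_multiple_pct = 100 * .data$n_multiple / .data$n_facilities)

  grp <- networks$groups |>
    dplyr::distinct(.data$hrr, .data$date, .data$group_id, .data$group_size) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      mean_group_size = sum(.data$group_size) / dplyr::n(),
      .by = c("hrr", "date")
    )

  aff |>
    dplyr::left_join(grp, by = c("hrr", "date")) |>
    dplyr::mutate(
      no_groups = is.na(.data$n_groups),
      n_groups = dplyr::coalesce(.data$n_groups, 0L),
      mean_group_size = dplyr::coalesce(.data$mean_group_size, 1)
    ) |>
    dplyr::left_join(
      networks$concentration[, c("hrr", "date", "hhi", "ahhi", "delta",
                                 "n_coowners", "n_owners", "total_beds")],
      by = c("hrr", "date")
    ) |>
    dplyr::arrange(.data$date, .data$hrr)
}

#' National summary of HRR-level metrics for one processing date
#'
#' Unweighted mean and sample standard deviation (n-1 denominator) across
#' HRRs of the five super-organization variables, plus national totals.
#' A single-HRR summary reports SD 0 with `degenerate = TRUE`.
#'
#' @param metrics Tibble from [compute_hrr_metrics()].
#' @param date Processing-date index to summarise (default: all, one row
#'   each).
#' @return Tibble, one row per date: means/SDs of prevalence, group size
#'   and the three concentration indices; totals of facilities,
#'   multiple-affiliation facilities, organization owners, co-owning
#'   organizations and ownership groups.
#' @export
national_summary <- function(metrics, date = NULL) {
  if (!is.null(date)) metrics <- metrics[metrics$date %in% date, ]
  stopifnot(nrow(metrics) >= 1)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  metrics |>
    dplyr::summarise(
      n_hrrs = dplyr::n(),
      degenerate = dplyr::n() < 2,
      dplyr::across(
        c("prevalence_multiple_pct", "mean_group_size", "hhi", "ahhi", "delta"),
        list(mean = mean, sd = sd0)
      ),
      total_facilities = sum(.data$n_facilities),
      total_multiple = sum(.data$n_multiple),
      total_owners = sum(.data$n_owners),
      total_coowners = sum(.data$n_coowners),
      total_groups = sum(.data$n_groups),
      .by = "date"
    ) |>
    dplyr::arrange(.data$date)
}
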
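# Independent oracles and fixture builders used across the suite.

# O(n^2 * m) pairwise shared-owner count, independent of igraph.
brute_force_projection <- function(ties, facility_ids) {
  fac <- sort(facility_ids)
  out <- list()
  for (i in seq_along(fac)) {
    for (j in seq_len(i - 1)) {
      oi <- ties$owner_key[ties$provider_id == fac[i]]
      oj <- ties$owner_key[ties$provider_id == fac[j]]
      w <- length(intersect(unique(oi), unique(oj)))
      if (w > 0) out[[length(out) + 1]] <- tibble::tibble(a = fac[j], b = fac[i], weight = w)
    }
  }
  if (!length(out)) return(tibble::tibble(a = character(), b = character(), weight = integer()))
  dplyr::arrange(dplyr::bind_rows(out), a, b)
}

projection_edges <- function(p) {
  if (igraph::ecount(p) == 0) {
    return(tibble::tibble(a = character(), b = character(), weight = integer()))
  }
  e <- igraph::as_data_frame(p, what = "edges")
  tibble::tibble(a = pmin(e$from, e$to), b = pmax(e$from, e$to),
                 weight = as.integer(e$weight)) |>
    dplyr::arrange(a, b)
}

# all set partitions of 1..n as membership vectors (Bell-number enumeration)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    k <- max(p)
    for (g in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, g)
  }
  out
}

# exhaustive maximum weighted modularity over all partitions
max_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  best <- -Inf
  for (p in all_partitions(n)) {
    m <- igraph::modularity(g, p, weights = igraph::E(g)$weight)
    if (m > best) best <- m
  }
  best
}

# random bipartite owner-tie table (uses the current RNG state)
random_bipartite_ties <- function(n_fac, n_own, p = 0.25) {
  fac <- sprintf("F%02d", seq_len(n_fac))
  own <- sprintf("OWNER %d LLC", seq_len(n_own))
  pick <- which(matrix(runif(n_fac * n_own) < p, n_fac, n_own), arr.ind = TRUE)
  ties <- tibble::tibble(provider_id = fac[pick[, 1]], owner_key = own[pick[, 2]],
                         owner_kind = "organization")
  list(ties = ties, facilities = tibble::tibble(provider_id = fac))
}

# 14-facility single-HRR topology matching the exemplar referral region:
# two planted ownership groups (sizes 5 and 3) and six isolated facilities.
fig2_fixture <- function() {
  fac <- sprintf("F%02d", 1:14)
  ties <- dplyr::bind_rows(
    tibble::tibble(provider_id = fac[1:5], owner_key = "BIG GROUP HOLDINGS LLC"),
    tibble::tibble(provider_id = fac[6:8], owner_key = "SMALL GROUP PARTNERS INC"),
    tibble::tibble(provider_id = fac, owner_key = paste("SOLE OWNER", fac, "LLC"))
  )
  ties$owner_kind <- "organization"
  list(ties = ties, facilities = tibble::tibble(provider_id = fac),
       n_multiple = 8L, n_single = 6L, n_groups = 2L)
}

# tiny provider CSV written to a temp file in the default NHC dialect
write_provider_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  cols <- nhc_columns()
  defaults <- list(provider_id = "000001", zip = "00101", state = "AL",
                   beds = 100, residents = 80, occupancy_pct = 80,
                   years_in_business = 10, ownership_type = "for-profit",
                   hospital_based = "NO", sff = "NO", ccrc = "NO",
                   council = "YES", ownership_changed = "NO",
                   staffing_cna_hrd = 2.3, staffing_lpn_hrd = 0.8,
                   staffing_rn_hrd = 0.6, five_star = 3, twhss = 50)
  df <- purrr::map_dfr(rows, function(r) {
    vals <- utils::modifyList(defaults, r)
    tibble::as_tibble(lapply(vals, as.character))
  })
  names(df) <- unname(unlist(cols[names(defaults)]))
  readr::write_csv(df, path, na = "")
  path
}

write_ownership_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  cols <- nhc_columns()
  df <- purrr::map_dfr(rows, tibble::as_tibble)
  names(df) <- unname(unlist(cols[c("provider_id", "owner_name", "owner_type")]))
  readr::write_csv(df, path, na = "")
  path
}

tiny_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_facilities = 120, n_hrrs = 4, n_states = 2, n_dates = 5,
         covariate_missing_rate = 0, mds_missing_rate = 0,
         individual_only_rate = 0),
    list(...))
  do.call(nhc_sim_config, args)
}
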
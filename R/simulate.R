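#' Configuration for the synthetic Nursing Home Compare generator
#'
#' Defaults emulate the study conditions of the real 2016-2018 panel:
#' five semi-annual processing dates, ownership-type shares 74.3/6.5/19.2
#' (for-profit/government/non-profit), a target multiple-affiliation
#' prevalence of 56.8% of facilities per HRR, ownership-group sizes from a
#' truncated geometric with mean ~3.15 (echoing the observed 3.11-3.23
#' mean group size), a marginal deficiency-score mean of ~58 (observed
#' range 54.5-63.6), and true variance components whose implied state/HRR
#' intraclass correlations sit near 0.18/0.075. A fraction of HRRs span
#' two states so that state and HRR membership is genuinely
#' cross-classified.
#'
#' @param n_facilities,n_hrrs,n_states,n_dates Panel dimensions.
#' @param hrr_state_overlap Fraction of HRRs whose facilities are split
#'   between two states (drives cross-classification).
#' @param target_prevalence_multiple_pct Percent of facilities per HRR
#'   planted into ownership groups.
#' @param group_size_mean,group_size_max Truncated-geometric group-size
#'   distribution (minimum size 2).
#' @param second_owner_rate Probability a facility has a second sole
#'   organization owner (noise owners; they create no shared ties).
#' @param pct_individual_owners Percent of facilities that additionally
#'   carry an individual-kind owner record.
#' @param individual_only_rate Fraction of facilities owned solely by
#'   individuals (excluded from the analysis sample by the panel filter).
#' @param covariate_missing_rate Fraction of facilities with one missing
#'   base covariate at one random date.
#' @param mds_missing_rate Fraction of facilities with one missing MDS
#'   measure at one random date (drives the smaller model-2 sample).
#' @param ownership_type_shares Named probabilities for
#'   for-profit/government/non-profit.
#' @param beds_meanlog,beds_sdlog Log-normal certified-bed distribution.
#' @param twhss_mean Target marginal mean of the deficiency score.
#' @param true_beta Named coefficient vector on the centered design scale
#'   (see [nhc_true_beta()]); the intercept is solved internally so the
#'   marginal outcome mean hits `twhss_mean`.
#' @param true_variances Named variances of the state, HRR, facility and
#'   observation-level random effects on the log scale.
#' @return A list of class `nhc_sim_config`.
#' @export
nhc_sim_config <- function(n_facilities = 1000, n_hrrs = 20, n_states = 8,
                           n_dates = 5,
                           hrr_state_overlap = 0.3,
                           target_prevalence_multiple_pct = 56.8,
                           group_size_mean = 3.15, group_size_max = 12,
                           second_owner_rate = 0.3,
                           pct_individual_owners = 20,
                           individual_only_rate = 0.02,
                           covariate_missing_rate = 0.01,
                           mds_missing_rate = 0.08,
                           ownership_type_shares = c(`for-profit` = 0.743,
                                                     government = 0.065,
                                                     `non-profit` = 0.192),
                           beds_meanlog = log(100), beds_sdlog = 0.4,
                           twhss_mean = 58,
                           true_beta = nhc_true_beta(),
                           true_variances = c(state = 0.12, hrr = 0.05,
                                              facility = 0.25, observation = 0.25)) {
  stopifnot(n_facilities >= n_hrrs, n_hrrs >= n_states, n_dates >= 1,
            hrr_state_overlap >= 0, hrr_state_overlap <= 1,
            target_prevalence_multiple_pct >= 0,
            target_prevalence_multiple_pct <= 100,
            group_size_mean >= 2, group_size_max >= group_size_mean,
            all(true_variances >= 0),
            abs(sum(ownership_type_shares) - 1) < 1e-8)
  structure(as.list(environment()), class = "nhc_sim_config")
}

#' Default true coefficients for the synthetic outcome model
#'
#' Magnitudes echo the scale of the fitted prevalence ratios in the real
#' panel (log scale; e.g. RN staffing ~ exp(-0.2) ~ 0.82). Names match the
#' design-matrix columns produced by [build_design()] for model 1; MDS
#' columns carry zero effect by default.
#'
#' @return Named numeric vector (no intercept; solved by the generator).
#' @export
nhc_true_beta <- function() {
  c(staffing_cna_hrd = -0.03, staffing_lpn_hrd = 0.01, staffing_rn_hrd = -0.2,
    residents = 0.003, occupancy_pct = -0.005, years_in_business = 0.006,
    `ownership_type:government` = -0.05, `ownership_type:non-profit` = -0.13,
    hospital_based = -0.09, sff = 0.6, ccrc = -0.09, council = 0.07,
    ownership_changed = -0.008,
    `five_star:2` = -0.04, `five_star:3` = -0.065,
    `five_star:4` = -0.105, `five_star:5` = -0.175,
    prevalence_multiple_pct = -0.001, mean_group_size = -0.017,
    delta = 0.03, `affiliation:single` = 0.022,
    `government:single` = -0.12, `non-profit:single` = -0.035)
}

# truncated geometric on {2, ..., max} with the requested mean
rtrunc_geom <- function(n, mean, max) {
  if (mean <= 2) return(rep(2L, n))
  q <- (mean - 2) / (mean - 1)
  s <- 2L + stats::rgeom(n, prob = 1 - q)
  pmin(s, as.integer(max))
}

# decorate a normalized owner key with punctuation/spacing noise that the
# name-cleaning rule removes, so fixtures exercise normalization
decorate_owner_name <- function(key) {
  vapply(key, function(k) {
    words <- strsplit(k, " ", fixed = TRUE)[[1]]
    if (stats::runif(1) < 0.5 && length(words) > 1) {
      words[length(words) - 1] <- paste0(words[length(words) - 1], ",")
    }
    if (stats::runif(1) < 0.5 && words[length(words)] %in% c("LLC", "INC")) {
      words[length(words)] <- paste0(paste(strsplit(words[length(words)], "")[[1]],
                                           collapse = "."), ".")
    }
    sep <- ifelse(stats::runif(length(words) - 1) < 0.2, "  ", " ")
    out <- paste0(words[1], paste0(sep, words[-1], collapse = ""))
    if (stats::runif(1) < 0.3) out <- stringr::str_to_title(out)
    out
  }, character(1), USE.NAMES = FALSE)
}

sim_geography <- function(cfg) {
  hrr_id <- sprintf("HRR%03d", seq_len(cfg$n_hrrs))
  states <- if (cfg$n_states <= 50) datasets::state.abb[seq_len(cfg$n_states)] else
    sprintf("Z%02d", seq_len(cfg$n_states))
  primary <- states[1 + (seq_len(cfg$n_hrrs) - 1) %% cfg$n_states]
  n_overlap <- round(cfg$hrr_state_overlap * cfg$n_hrrs)
  overlap_idx <- if (n_overlap > 0) sample(cfg$n_hrrs, n_overlap) else integer()
  secondary <- rep(NA_character_, cfg$n_hrrs)
  for (i in overlap_idx) secondary[i] <- sample(setdiff(states, primary[i]), 1)
  zips_per_hrr <- 30
  crosswalk <- tibble::tibble(
    zip = sprintf("%05d", rep(seq_len(cfg$n_hrrs) * 100, each = zips_per_hrr) +
                    seq_len(zips_per_hrr)),
    hrr_id = rep(hrr_id, each = zips_per_hrr),
    hrr_name = rep(paste("Region", seq_len(cfg$n_hrrs)), each = zips_per_hrr)
  )
  list(hrr_id = hrr_id, primary = primary, secondary = secondary,
       crosswalk = crosswalk, zips_per_hrr = zips_per_hrr)
}

sim_facility_base <- function(cfg, geo) {
  n <- cfg$n_facilities
  # near-even allocation so no HRR is empty
  hrr_idx <- sample(rep(seq_len(cfg$n_hrrs), length.out = n))
  state <- geo$primary[hrr_idx]
  has2 <- !is.na(geo$secondary[hrr_idx])
  use2 <- has2 & stats::runif(n) < 0.4
  state[use2] <- geo$secondary[hrr_idx][use2]
  zip <- sprintf("%05d", hrr_idx * 100 + sample.int(geo$zips_per_hrr, n, replace = TRUE))
  beds <- pmax(10, round(stats::rlnorm(n, cfg$beds_meanlog, cfg$beds_sdlog)))
  tibble::tibble(
    provider_id = sprintf("%06d", seq_len(n)),
    hrr = geo$hrr_id[hrr_idx], state = state, zip = zip, beds = beds,
    occupancy_base = pmin(100, pmax(20, stats::rnorm(n, 82, 12))),
    years_base = stats::rgamma(n, shape = 4, scale = 6),
    ownership_type = sample(names(cfg$ownership_type_shares), n, replace = TRUE,
                            prob = cfg$ownership_type_shares),
    hospital_based = stats::runif(n) < 0.05,
    sff = stats::runif(n) < 0.02,
    ccrc = stats::runif(n) < 0.10,
    council = stats::runif(n) < 0.90,
    ownership_changed = stats::runif(n) < 0.08,
    cna_base = pmax(0.2, stats::rnorm(n, 2.3, 0.4)),
    lpn_base = pmax(0.1, stats::rnorm(n, 0.85, 0.25)),
    rn_base = pmax(0.05, stats::rnorm(n, 0.65, 0.3)),
    five_star = sample(1:5, n, replace = TRUE, prob = c(.15, .2, .25, .2, .2))
  )
}

sim_ownership <- function(cfg, base) {
  n <- nrow(base)
  individual_only <- stats::runif(n) < cfg$individual_only_rate
  group_rows <- vector("list", cfg$n_hrrs)
  next_group <- 1L
  for (h in unique(base$hrr)) {
    idx <- which(base$hrr == h & !individual_only)
    m <- round(cfg$target_prevalence_multiple_pct / 100 * length(idx))
    if (m < 2) next
    sizes <- integer()
    while (sum(sizes) < m) {
      s <- rtrunc_geom(1, cfg$group_size_mean, cfg$group_size_max)
      if (sum(sizes) + s > m) s <- m - sum(sizes)
      if (s == 1) { sizes[length(sizes)] <- sizes[length(sizes)] + 1L; break }
      if (s < 2) break
      sizes <- c(sizes, s)
    }
    members <- sample(idx, sum(sizes))
    gid <- rep(seq_along(sizes), sizes) + next_group - 1L
    next_group <- next_group + length(sizes)
    group_rows[[match(h, unique(base$hrr))]] <-
      tibble::tibble(row = members, group_id = gid)
  }
  planted <- dplyr::bind_rows(group_rows)

  owner_of <- function(provider_id, key, kind) {
    tibble::tibble(provider_id = provider_id,
                   owner_name_raw = decorate_owner_name(key),
                   owner_key = key, owner_kind = kind)
  }
  recs <- list()
  if (!is.null(planted) && nrow(planted)) {
    recs$shared <- owner_of(base$provider_id[planted$row],
                            sprintf("GROUP %d HOLDINGS LLC", planted$group_id),
                            "organization")
  }
  solo <- which(!individual_only)
  recs$sole <- owner_of(base$provider_id[solo],
                        sprintf("OPERATOR %s INC", base$provider_id[solo]),
                        "organization")
  second <- solo[stats::runif(length(solo)) < cfg$second_owner_rate]
  if (length(second)) {
    recs$second <- owner_of(base$provider_id[second],
                            sprintf("PARTNERS %s LLC", base$provider_id[second]),
                            "organization")
  }
  indiv <- union(which(individual_only),
                 which(stats::runif(n) < cfg$pct_individual_owners / 100))
  if (length(indiv)) {
    recs$individual <- owner_of(base$provider_id[indiv],
                                sprintf("OWNER %s PERSON", base$provider_id[indiv]),
                                "individual")
  }
  owners <- dplyr::bind_rows(recs)
  list(owners = owners, planted = tibble::tibble(
    provider_id = if (is.null(planted) || !nrow(planted)) character() else base$provider_id[planted$row],
    group_id = if (is.null(planted) || !nrow(planted)) integer() else planted$group_id
  ), individual_only = base$provider_id[individual_only])
}

sim_snapshots <- function(cfg, base) {
  purrr::map(seq_len(cfg$n_dates), function(d) {
    n <- nrow(base)
    occ <- pmin(100, pmax(0, base$occupancy_base + stats::rnorm(n, 0, 2)))
    tibble::tibble(
      provider_id = base$provider_id, date = as.integer(d),
      zip = base$zip, state = base$state,
      beds = as.numeric(base$beds),
      residents = pmin(base$beds, round(base$beds * occ / 100)),
      occupancy_pct = occ,
      years_in_business = base$years_base + (d - 1) * 0.5,
      ownership_type = base$ownership_type,
      hospital_based = base$hospital_based, sff = base$sff, ccrc = base$ccrc,
      council = base$council, ownership_changed = base$ownership_changed,
      staffing_cna_hrd = pmax(0, base$cna_base + stats::rnorm(n, 0, 0.05)),
      staffing_lpn_hrd = pmax(0, base$lpn_base + stats::rnorm(n, 0, 0.03)),
      staffing_rn_hrd = pmax(0, base$rn_base + stats::rnorm(n, 0, 0.03)),
      five_star = base$five_star
    )
  })
}

sim_mds <- function(cfg, base) {
  codes <- nhc_mds_codes()
  mu <- stats::runif(length(codes), 5, 60)
  purrr::map(seq_len(cfg$n_dates), function(d) {
    vals <- purrr::map(seq_along(codes), function(j) {
      pmin(100, pmax(0, stats::rnorm(nrow(base), mu[j], 8)))
    })
    names(vals) <- paste0("mds_", codes)
    dplyr::bind_cols(tibble::tibble(provider_id = base$provider_id,
                                    date = as.integer(d)),
                     tibble::as_tibble(vals))
  })
}

# Per-HRR metrics implied by the planted structure, computed with direct
# arithmetic over the model-1 complete facilities only (the analysis
# sample the pipeline sees).
sim_truth_metrics <- function(base, planted, complete_ids) {
  fac <- base[base$provider_id %in% complete_ids, c("provider_id", "hrr", "beds")]
  grp <- planted[planted$provider_id %in% complete_ids, ]
  keep <- grp |>
    dplyr::mutate(group_size = dplyr::n(), .by = "group_id") |>
    dplyr::filter(.data$group_size >= 2)
  fac$group_id <- keep$group_id[match(fac$provider_id, keep$provider_id)]
  fac |>
    dplyr::summarise(
      n_facilities = dplyr::n(),
      n_multiple = sum(!is.na(.data$group_id)),
      prevalence_multiple_pct = 100 * sum(!is.na(.data$group_id)) / dplyr::n(),
      n_groups = length(unique(stats::na.omit(.data$group_id))),
      hhi = sum((.data$beds / sum(.data$beds))^2),
      ahhi = {
        unit <- ifelse(is.na(.data$group_id),
                       .data$provider_id, paste0("g", .data$group_id))
        pooled <- tapply(.data$beds, unit, sum)
        sum((pooled / sum(pooled))^2)
      },
      .by = "hrr"
    ) |>
    dplyr::mutate(
      mean_group_size = ifelse(.data$n_groups >= 1,
                               .data$n_multiple / .data$n_groups, 1),
      delta = .data$ahhi - .data$hhi
    )
}

#' Generate a synthetic Nursing Home Compare style panel with ground truth
#'
#' Runs the full generator: geography with cross-classified state/HRR
#' membership, facility covariates with small between-date drift, planted
#' ownership groups realized as shared owner keys (with punctuation-noised
#' raw names), individual owners, configurable missingness, and outcomes
#' drawn from the log-link Poisson mixed model
#' \deqn{y \sim Pois(\exp(X\beta + u_{state} + u_{hrr} + u_{fac} + e))}
#' with known coefficients and variance components.
#'
#' @param config From [nhc_sim_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return List of class `nh_sim`: `providers`, `owners`, `mds` (lists of
#'   per-date tibbles), `crosswalk`, and `truth` (facility table with
#'   planted affiliation/groups, per-HRR metrics, `beta` incl. solved
#'   intercept, `variances`, random-effect values, config echo).
#' @export
simulate_nhc <- function(config = nhc_sim_config(), seed = 1) {
  stopifnot(inherits(config, "nhc_sim_config"))
  set.seed(seed)
  geo <- sim_geography(config)
  base <- sim_facility_base(config, geo)
  own <- sim_ownership(config, base)
  snaps <- sim_snapshots(config, base)
  mds <- sim_mds(config, base)

  # plant missingness
  n <- nrow(base)
  miss_cov <- which(stats::runif(n) < config$covariate_missing_rate)
  for (i in miss_cov) {
    d <- sample.int(config$n_dates, 1)
    snaps[[d]]$staffing_lpn_hrd[i] <- NA_real_
  }
  miss_mds <- which(stats::runif(n) < config$mds_missing_rate)
  for (i in miss_mds) {
    d <- sample.int(config$n_dates, 1)
    col <- sample(paste0("mds_", nhc_mds_codes()), 1)
    mds[[d]][[col]][i] <- NA_real_
  }

  complete1 <- setdiff(base$provider_id,
                       c(own$individual_only, base$provider_id[miss_cov]))
  metrics <- sim_truth_metrics(base, own$planted, complete1)

  out <- sim_outcomes(config, snaps, base, own$planted, metrics, complete1)
  for (d in seq_len(config$n_dates)) {
    snaps[[d]]$twhss <- out$twhss[out$date == d]
    snaps[[d]]$twhss_int <- round_half_away(snaps[[d]]$twhss)
    snaps[[d]]$flags <- snapshot_flags(snaps[[d]])
  }
  owners <- purrr::map(seq_len(config$n_dates),
                       function(d) dplyr::mutate(own$owners, date = as.integer(d)))

  keep <- own$planted |>
    dplyr::filter(.data$provider_id %in% complete1) |>
    dplyr::mutate(group_size = dplyr::n(), .by = "group_id") |>
    dplyr::filter(.data$group_size >= 2)
  gid <- keep$group_id[match(base$provider_id, keep$provider_id)]
  fac_truth <- tibble::tibble(
    provider_id = base$provider_id, hrr = base$hrr, state = base$state,
    beds = base$beds, group_id = gid,
    affiliation = ifelse(is.na(gid), "single", "multiple"),
    complete_model1 = base$provider_id %in% complete1
  )

  structure(list(
    providers = snaps, owners = owners, mds = mds, crosswalk = geo$crosswalk,
    truth = list(facilities = fac_truth, hrr_metrics = metrics,
                 beta = out$beta, variances = config$true_variances,
                 ranef = out$ranef, complete_model1 = complete1,
                 config = config, seed = seed)
  ), class = "nh_sim")
}

# Outcomes are drawn from the exact covariate values the emitted tables
# carry (per-date drift included), with continuous columns centered over
# the complete-case rows exactly as the design matrix will center them —
# so the planted coefficients, intercept included, live on the same scale
# the regression estimates.
sim_outcomes <- function(cfg, snaps, base, planted, metrics, complete_ids) {
  keep <- planted |>
    dplyr::filter(.data$provider_id %in% complete_ids) |>
    dplyr::mutate(group_size = dplyr::n(), .by = "group_id") |>
    dplyr::filter(.data$group_size >= 2)

  s <- dplyr::bind_rows(snaps) |>
    dplyr::arrange(.data$date, match(.data$provider_id, base$provider_id))
  fac_i <- match(s$provider_id, base$provider_id)
  b <- base[fac_i, ]
  m <- metrics[match(b$hrr, metrics$hrr), ]
  single <- !(s$provider_id %in% keep$provider_id)

  X <- cbind(
    staffing_cna_hrd = s$staffing_cna_hrd, staffing_lpn_hrd = s$staffing_lpn_hrd,
    staffing_rn_hrd = s$staffing_rn_hrd,
    residents = s$residents,
    occupancy_pct = s$occupancy_pct,
    years_in_business = s$years_in_business,
    `ownership_type:government` = as.numeric(s$ownership_type == "government"),
    `ownership_type:non-profit` = as.numeric(s$ownership_type == "non-profit"),
    hospital_based = as.numeric(s$hospital_based), sff = as.numeric(s$sff),
    ccrc = as.numeric(s$ccrc), council = as.numeric(s$council),
    ownership_changed = as.numeric(s$ownership_changed),
    `five_star:2` = as.numeric(s$five_star == 2),
    `five_star:3` = as.numeric(s$five_star == 3),
    `five_star:4` = as.numeric(s$five_star == 4),
    `five_star:5` = as.numeric(s$five_star == 5),
    prevalence_multiple_pct = m$prevalence_multiple_pct,
    mean_group_size = m$mean_group_size,
    delta = m$delta,
    `affiliation:single` = as.numeric(single),
    `government:single` = as.numeric(s$ownership_type == "government" & single),
    `non-profit:single` = as.numeric(s$ownership_type == "non-profit" & single)
  )
  # staffing may contain planted NAs; those rows are incomplete and never
  # modelled, so zero-fill for simulation purposes
  X[is.na(X)] <- 0
  cont <- c("staffing_cna_hrd", "staffing_lpn_hrd", "staffing_rn_hrd",
            "residents", "occupancy_pct", "years_in_business",
            "prevalence_multiple_pct", "mean_group_size", "delta")
  analysis_rows <- s$provider_id %in% complete_ids
  mu <- colMeans(X[analysis_rows, cont, drop = FALSE])
  X[, cont] <- sweep(X[, cont, drop = FALSE], 2, mu)

  beta <- cfg$true_beta[colnames(X)]
  beta[is.na(beta)] <- 0
  contrib <- drop(X %*% beta)

  states <- unique(base$state); hrrs <- unique(base$hrr)
  u_state <- stats::rnorm(length(states), 0, sqrt(cfg$true_variances["state"]))
  u_hrr <- stats::rnorm(length(hrrs), 0, sqrt(cfg$true_variances["hrr"]))
  u_fac <- stats::rnorm(nrow(base), 0, sqrt(cfg$true_variances["facility"]))
  e <- stats::rnorm(nrow(s), 0, sqrt(cfg$true_variances["observation"]))

  re <- u_state[match(b$state, states)] + u_hrr[match(b$hrr, hrrs)] +
    u_fac[fac_i] + e
  # solve the intercept so the marginal mean over analysis rows hits twhss_mean
  intercept <- log(cfg$twhss_mean) -
    log(mean(exp(contrib[analysis_rows] + re[analysis_rows])))
  eta <- intercept + contrib + re
  if (max(eta) > 30) stop("config error: linear predictor exceeds overflow guard (eta > 30)", call. = FALSE)
  y <- stats::rpois(length(eta), exp(eta))
  twhss <- pmax(0, y + stats::runif(length(y), -0.45, 0.45))

  list(twhss = twhss, date = s$date,
       beta = c(`(Intercept)` = unname(intercept), beta),
       centers = mu,
       ranef = list(state = stats::setNames(u_state, states),
                    hrr = stats::setNames(u_hrr, hrrs),
                    facility = stats::setNames(u_fac, base$provider_id)))
}

#' Write a synthetic panel as NHC-dialect CSV fixtures
#'
#' Emits per-date provider, ownership and MDS CSVs with the configured
#' NHC column headers, a ZIP-to-HRR crosswalk CSV, and a `truth.json`
#' ground-truth file; the CSVs round-trip through the package readers.
#'
#' @param sim An `nh_sim` from [simulate_nhc()].
#' @param dir Output directory (created if needed).
#' @param columns Column mapping from [nhc_columns()].
#' @return Invisibly, the directory.
#' @export
emit_fixture <- function(sim, dir, columns = nhc_columns()) {
  stopifnot(inherits(sim, "nh_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yn <- function(x) ifelse(x, "YES", "NO")
  for (d in seq_along(sim$providers)) {
    s <- sim$providers[[d]]
    prov <- stats::setNames(tibble::tibble(
      s$provider_id, s$zip, s$state, s$beds, s$residents, s$occupancy_pct,
      s$years_in_business, s$ownership_type, yn(s$hospital_based), yn(s$sff),
      yn(s$ccrc), yn(s$council), yn(s$ownership_changed),
      s$staffing_cna_hrd, s$staffing_lpn_hrd, s$staffing_rn_hrd,
      s$five_star, s$twhss),
      unlist(columns[c("provider_id", "zip", "state", "beds", "residents",
                       "occupancy_pct", "years_in_business", "ownership_type",
                       "hospital_based", "sff", "ccrc", "council",
                       "ownership_changed", "staffing_cna_hrd",
                       "staffing_lpn_hrd", "staffing_rn_hrd",
                       "five_star", "twhss")]))
    readr::write_csv(prov, file.path(dir, sprintf("providers_d%d.csv", d)), na = "")
    o <- sim$owners[[d]]
    own <- stats::setNames(tibble::tibble(
      o$provider_id, o$owner_name_raw,
      ifelse(o$owner_kind == "individual", "Individual", "Organization")),
      unlist(columns[c("provider_id", "owner_name", "owner_type")]))
    readr::write_csv(own, file.path(dir, sprintf("ownership_d%d.csv", d)), na = "")
    m <- sim$mds[[d]] |>
      tidyr::pivot_longer(dplyr::starts_with("mds_"),
                          names_to = "code", values_to = "value") |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::mutate(code = sub("^mds_", "", .data$code))
    mds <- stats::setNames(
      tibble::tibble(m$provider_id, m$code, m$value),
      c(columns$provider_id, "Measure Code", "Measure Value"))
    readr::write_csv(mds, file.path(dir, sprintf("mds_d%d.csv", d)), na = "")
  }
  cw <- stats::setNames(sim$crosswalk,
                        unlist(columns[c("cw_zip", "cw_hrr_id", "cw_hrr_name")]))
  readr::write_csv(cw, file.path(dir, "crosswalk.csv"), na = "")
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a fixture directory written by [emit_fixture()] into a panel
#'
#' @param dir Fixture directory.
#' @param columns Column mapping from [nhc_columns()].
#' @param required_covariates As in [assemble_panel()].
#' @return An `nh_panel`.
#' @export
read_fixture <- function(dir, columns = nhc_columns(),
                         required_covariates = panel_covariates("model1")) {
  dates <- seq_along(list.files(dir, pattern = "^providers_d\\d+\\.csv$"))
  providers <- purrr::map(dates, function(d)
    read_provider_table(file.path(dir, sprintf("providers_d%d.csv", d)), d, columns))
  owners <- purrr::map(dates, function(d)
    read_ownership_table(file.path(dir, sprintf("ownership_d%d.csv", d)), d, columns))
  mds <- purrr::map(dates, function(d)
    read_mds_table(file.path(dir, sprintf("mds_d%d.csv", d)), d, columns))
  crosswalk <- read_crosswalk(file.path(dir, "crosswalk.csv"), columns)
  assemble_panel(providers, owners, crosswalk, mds = mds,
                 required_covariates = required_covariates)
}

#' Assemble an in-memory synthetic panel without touching disk
#'
#' Convenience wrapper binding the generator's tables straight into
#' [assemble_panel()].
#'
#' @param sim An `nh_sim`.
#' @param variant Completeness filter variant, as in [panel_covariates()].
#' @return An `nh_panel`.
#' @export
sim_panel <- function(sim, variant = "model1") {
  assemble_panel(sim$providers, sim$owners, sim$crosswalk, mds = sim$mds,
                 required_covariates = panel_covariates(variant))
}
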
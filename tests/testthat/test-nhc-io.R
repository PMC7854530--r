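test_that("provider reader preserves rows, parses numerics, discretizes the score", {
  path <- write_provider_csv(list(
    list(provider_id = "000001", twhss = 54.48),
    list(provider_id = "000002", twhss = 10.5),
    list(provider_id = "000003", twhss = 0.2)))
  snaps <- read_provider_table(path, date = 1)
  expect_equal(nrow(snaps), 3)
  expect_type(snaps$beds, "double")
  # nearest integer, half away from zero
  expect_equal(snaps$twhss_int, c(54, 11, 0))
  expect_equal(snaps$date, rep(1L, 3))
})

test_that("invariant violations are flagged, not imputed or dropped", {
  path <- write_provider_csv(list(
    list(provider_id = "000001", occupancy_pct = 101),
    list(provider_id = "000002", residents = 150, beds = 100),
    list(provider_id = "000003", staffing_rn_hrd = "")))
  snaps <- read_provider_table(path, 1)
  expect_equal(nrow(snaps), 3)
  expect_match(snaps$flags[1], "occupancy_out_of_range")
  expect_match(snaps$flags[2], "residents_exceed_beds")
  expect_match(snaps$flags[3], "missing_covariate")
  expect_true(is.na(snaps$staffing_rn_hrd[3]))
})

test_that("format and linkage errors name the offending column or id", {
  path <- write_provider_csv(list(list(provider_id = "000001")))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw[[nhc_columns()$beds]] <- NULL
  path2 <- tempfile(fileext = ".csv")
  readr::write_csv(raw, path2)
  expect_error(read_provider_table(path2, 1), "Number of Certified Beds")

  dup <- write_provider_csv(list(list(provider_id = "000009"),
                                 list(provider_id = "000009")))
  expect_error(read_provider_table(dup, 1), "duplicate provider id.*000009")
})

test_that("ownership reader normalizes keys and maps owner kinds", {
  path <- write_ownership_csv(list(
    list(provider_id = "015009", owner_name = "ABC HEALTH, L.L.C.",
         owner_type = "Organization"),
    list(provider_id = "015010", owner_name = "SMITH, JOHN",
         owner_type = "Individual - Director"),
    list(provider_id = "015011", owner_name = "ABC HEALTH, L.L.C.",
         owner_type = "Organization")))
  recs <- read_ownership_table(path, 2)
  expect_equal(recs$owner_key[1], "ABC HEALTH LLC")
  expect_equal(recs$owner_kind, c("organization", "individual", "organization"))
  # same owner name on two providers shares one key
  expect_equal(recs$owner_key[3], recs$owner_key[1])
  expect_equal(recs$date, rep(2L, 3))
})

test_that("empty owner names are skipped with a warning", {
  path <- write_ownership_csv(list(
    list(provider_id = "015009", owner_name = "GOOD CORP", owner_type = "Organization"),
    list(provider_id = "015010", owner_name = "", owner_type = "Organization")))
  expect_warning(recs <- read_ownership_table(path, 1), "empty owner name")
  expect_equal(nrow(recs), 1)
})

test_that("crosswalk lookups are total and duplicates are rejected", {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(zip = c("00101", "00102"),
                                  hrr_id = c("HRR001", "HRR002"),
                                  hrr_name = c("One", "Two")), path)
  cw <- read_crosswalk(path)
  expect_equal(lookup_hrr(cw, c("00102", "00101")), c("HRR002", "HRR001"))
  expect_error(lookup_hrr(cw, "99999"), "99999")

  readr::write_csv(tibble::tibble(zip = c("00101", "00101"),
                                  hrr_id = c("HRR001", "HRR002"),
                                  hrr_name = c("One", "Two")), path)
  expect_error(read_crosswalk(path), "conflicting HRRs.*00101")
})

test_that("a national-scale crosswalk fixture covers all 306 referral regions", {
  sim <- simulate_nhc(tiny_sim_config(n_facilities = 306, n_hrrs = 306,
                                      n_states = 50), seed = 3)
  expect_equal(length(unique(sim$crosswalk$hrr_id)), 306)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(sim$crosswalk, path)
  expect_equal(length(unique(read_crosswalk(path)$hrr_id)), 306)
})

test_that("completeness filter requires every date, organization owners, full covariates", {
  sim <- simulate_nhc(tiny_sim_config(n_facilities = 60, n_hrrs = 2), seed = 11)
  panel <- sim_panel(sim)
  expect_setequal(panel$complete_providers, unique(panel$snapshots$provider_id))

  # provider present at 4 of 5 dates is excluded
  drop_one <- sim$providers
  drop_one[[5]] <- drop_one[[5]][drop_one[[5]]$provider_id != "000001", ]
  p2 <- assemble_panel(drop_one, sim$owners, sim$crosswalk, mds = sim$mds)
  expect_false("000001" %in% p2$complete_providers)

  # provider with only individual owners is excluded
  own2 <- purrr::map(sim$owners, function(o) {
    dplyr::mutate(o, owner_kind = ifelse(provider_id == "000002",
                                         "individual", owner_kind))
  })
  p3 <- assemble_panel(sim$providers, own2, sim$crosswalk, mds = sim$mds)
  expect_false("000002" %in% p3$complete_providers)

  # a missing covariate at one date excludes the provider
  prov2 <- sim$providers
  prov2[[3]]$staffing_cna_hrd[prov2[[3]]$provider_id == "000003"] <- NA
  p4 <- assemble_panel(prov2, sim$owners, sim$crosswalk, mds = sim$mds)
  expect_false("000003" %in% p4$complete_providers)

  # empty intersection yields an empty panel, not an exception
  all_ind <- purrr::map(sim$owners, function(o) dplyr::mutate(o, owner_kind = "individual"))
  p5 <- assemble_panel(sim$providers, all_ind, sim$crosswalk, mds = sim$mds)
  expect_length(p5$complete_providers, 0)
})

test_that("generator bookkeeping: planted missingness shrinks the complete set exactly", {
  sim <- simulate_nhc(tiny_sim_config(n_facilities = 100, n_hrrs = 2), seed = 21)
  prov <- sim$providers
  victims <- sprintf("%06d", 1:10)
  for (v in victims) {
    d <- (match(v, victims) %% 5) + 1
    prov[[d]]$occupancy_pct[prov[[d]]$provider_id == v] <- NA
  }
  panel <- assemble_panel(prov, sim$owners, sim$crosswalk, mds = sim$mds)
  expect_equal(length(panel$complete_providers), 90)
  expect_setequal(setdiff(unique(panel$snapshots$provider_id),
                          panel$complete_providers), victims)
})

test_that("completeness is monotone in the required-covariate set", {
  sim <- simulate_nhc(tiny_sim_config(n_facilities = 80, n_hrrs = 2,
                                      mds_missing_rate = 0.3), seed = 31)
  small <- assemble_panel(sim$providers, sim$owners, sim$crosswalk, mds = sim$mds,
                          required_covariates = panel_covariates("model1"))
  large <- assemble_panel(sim$providers, sim$owners, sim$crosswalk, mds = sim$mds,
                          required_covariates = panel_covariates("model2"))
  expect_true(all(large$complete_providers %in% small$complete_providers))
})

test_that("panel round-trips through CSV unchanged", {
  sim <- simulate_nhc(tiny_sim_config(n_facilities = 40, n_hrrs = 2), seed = 41)
  panel <- sim_panel(sim)
  dir <- tempfile()
  write_panel_csv(panel, dir)
  back <- read_panel_csv(dir, sim$crosswalk)
  expect_equal(back$complete_providers, panel$complete_providers)
  expect_equal(as.data.frame(back$snapshots), as.data.frame(panel$snapshots),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$owners), as.data.frame(panel$owners))
})

test_that("every complete provider resolves an HRR and state at every date", {
  sim <- simulate_nhc(tiny_sim_config(n_facilities = 60, n_hrrs = 3), seed = 51)
  panel <- sim_panel(sim)
  comp <- panel$snapshots[panel$snapshots$complete, ]
  expect_false(anyNA(comp$hrr))
  expect_false(anyNA(comp$state))
  expect_equal(nrow(comp), length(panel$complete_providers) * length(panel$dates))
})
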
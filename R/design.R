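#' Build the regression design for the deficiency-count model
#'
#' Assembles the complete-case facility-date rows into an outcome vector
#' (the integer-discretized weighted health-survey score) and a fixed
#' effects matrix with the study's parameterization: continuous covariates
#' mean-centered over the analysis sample; ownership type with for-profit
#' as reference; yes/no facility characteristics as 0/1; the five-star
#' rating as ordinal dummies with category 1 as reference (model 1) or the
#' 21 MDS measure-code prevalences (model 2; the rating is excluded there
#' to prevent multicollinearity with the measures it is derived from); the
#' three HRR-level super-organization covariates; facility affiliation
#' class with multiple affiliation as reference; and the ownership-type by
#' affiliation-class interaction (reference for-profit x multiple).
#' Grouping indices for state, HRR and facility are attached for the
#' cross-classified random intercepts.
#'
#' @param panel An `nh_panel`.
#' @param metrics HRR-level metrics from [compute_hrr_metrics()].
#' @param affiliation Facility affiliation table (from
#'   [derive_networks()]`$affiliation`).
#' @param variant `"model1"` or `"model2"`.
#' @param center Mean-center continuous columns (the study's choice);
#'   disable only for diagnostics.
#' @return Object of class `nh_design`: list with `y`, `X` (dense matrix,
#'   intercept first), `groups` (integer indices + level names for state,
#'   hrr, facility), `centers`, `variant`, `n`.
#' @export
build_design <- function(panel, metrics, affiliation,
                         variant = c("model1", "model2"), center = TRUE) {
  variant <- match.arg(variant)
  df <- panel$snapshots |>
    dplyr::filter(.data$complete) |>
    dplyr::inner_join(affiliation[, c("provider_id", "date", "class")],
                      by = c("provider_id", "date")) |>
    dplyr::inner_join(
      metrics[, c("hrr", "date", "prevalence_multiple_pct", "mean_group_size", "delta")],
      by = c("hrr", "date"))
  if (variant == "model2") {
    mds_cols <- paste0("mds_", nhc_mds_codes())
    stopifnot(all(mds_cols %in% names(df)))
    # longitudinal complete cases: a facility missing any MDS measure at
    # any date leaves the model-2 sample entirely
    ok <- stats::complete.cases(df[mds_cols])
    drop_ids <- unique(df$provider_id[!ok])
    df <- df[!(df$provider_id %in% drop_ids), ]
  }
  stopifnot(nrow(df) > 0)

  cont <- c("staffing_cna_hrd", "staffing_lpn_hrd", "staffing_rn_hrd",
            "residents", "occupancy_pct", "years_in_business",
            "prevalence_multiple_pct", "mean_group_size", "delta")
  if (variant == "model2") cont <- c(cont, paste0("mds_", nhc_mds_codes()))

  single <- as.numeric(df$class == "single")
  X <- cbind(
    `(Intercept)` = 1,
    as.matrix(df[cont]),
    `ownership_type:government` = as.numeric(df$ownership_type == "government"),
    `ownership_type:non-profit` = as.numeric(df$ownership_type == "non-profit"),
    hospital_based = as.numeric(df$hospital_based),
    sff = as.numeric(df$sff),
    ccrc = as.numeric(df$ccrc),
    council = as.numeric(df$council),
    ownership_changed = as.numeric(df$ownership_changed),
    `affiliation:single` = single,
    `government:single` = as.numeric(df$ownership_type == "government") * single,
    `non-profit:single` = as.numeric(df$ownership_type == "non-profit") * single
  )
  if (variant == "model1") {
    fs <- vapply(2:5, function(k) as.numeric(df$five_star == k), numeric(nrow(df)))
    colnames(fs) <- paste0("five_star:", 2:5)
    X <- cbind(X, fs)
  }

  centers <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (center) {
    mu <- colMeans(X[, cont, drop = FALSE])
    X[, cont] <- sweep(X[, cont, drop = FALSE], 2, mu)
    centers[cont] <- mu
  }

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  grp <- function(f) {
    lev <- sort(unique(f))
    list(index = match(f, lev), levels = lev)
  }
  structure(list(
    y = as.numeric(df$twhss_int),
    X = X,
    groups = list(state = grp(df$state), hrr = grp(df$hrr),
                  facility = grp(df$provider_id)),
    centers = centers, variant = variant, n = nrow(df),
    rows = df[, c("provider_id", "date", "hrr", "state")]
  ), class = "nh_design")
}

#' @export
print.nh_design <- function(x, ...) {
  cat("<nh_design> ", x$n, " rows x ", ncol(x$X), " fixed-effect columns (",
      x$variant, ")\n", sep = "")
  cat("  groups: ", length(x$groups$state$levels), " states, ",
      length(x$groups$hrr$levels), " HRRs, ",
      length(x$groups$facility$levels), " facilities\n", sep = "")
  invisible(x)
}
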
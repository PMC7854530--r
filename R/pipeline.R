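#' Run the two-step analysis end to end
#'
#' Step one derives the per-HRR ownership networks, affiliation classes,
#' ownership groups and concentration indices; step two fits the Bayesian
#' cross-classified Poisson model(s) and summarizes the posterior. When
#' `output_dir` is given, all tables are written as CSV, the per-HRR
#' graphs as GraphML, and a machine-readable manifest (file hashes, seed,
#' settings) is saved; reruns with identical inputs and seeds reproduce
#' identical hashes.
#'
#' A failed model stage does not discard the network-stage outputs: the
#' bundle (and manifest) records the failed stage and retains what
#' completed.
#'
#' @param panel An `nh_panel`.
#' @param variant `"model1"`, `"model2"` or `"both"`.
#' @param settings [mcmc_settings()] for the model stage.
#' @param network_seed Seed for the community-detection stage.
#' @param output_dir Optional directory for the report bundle artifacts.
#' @param keep_graphs Keep igraph objects in the returned bundle.
#' @return List of class `nh_bundle`: `networks`, `metrics`, `national`,
#'   `fits`, `summaries`, `errors`, `manifest`.
#' @export
run_pipeline <- function(panel, variant = c("model1", "model2", "both"),
                         settings = mcmc_settings(),
                         network_seed = 20160301,
                         output_dir = NULL, keep_graphs = FALSE) {
  variant <- match.arg(variant)
  variants <- if (variant == "both") c("model1", "model2") else variant

  networks <- derive_networks(panel, seed = network_seed,
                              keep_graphs = keep_graphs || !is.null(output_dir))
  metrics <- compute_hrr_metrics(networks)
  national <- national_summary(metrics)

  fits <- list(); summaries <- list(); errors <- list()
  for (v in variants) {
    res <- tryCatch({
      des <- build_design(panel, metrics, networks$affiliation, variant = v)
      fit <- fit_poisson_glmm(des, settings)
      list(fit = fit, summary = summarize_fit(fit))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[v]] <- conditionMessage(res)
    } else {
      fits[[v]] <- res$fit
      summaries[[v]] <- res$summary
    }
  }

  bundle <- structure(list(networks = networks, metrics = metrics,
                           national = national, fits = fits,
                           summaries = summaries, errors = errors,
                           settings = settings, network_seed = network_seed,
                           dates = panel$dates, manifest = NULL),
                      class = "nh_bundle")
  if (!is.null(output_dir)) bundle$manifest <- write_bundle(bundle, output_dir)
  if (!keep_graphs) bundle$networks$graphs <- NULL
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p)
    paths[[name]] <<- p
    p
  }
  wr(bundle$networks$affiliation, "affiliation.csv")
  wr(bundle$networks$groups, "ownership_groups.csv")
  wr(bundle$metrics, "hrr_metrics.csv")
  wr(bundle$national, "national_summary.csv")
  for (v in names(bundle$summaries)) {
    wr(bundle$summaries[[v]]$fixed, paste0("coefficients_", v, ".csv"))
    wr(bundle$summaries[[v]]$icc, paste0("icc_", v, ".csv"))
    for (g in names(bundle$summaries[[v]]$ranef)) {
      wr(bundle$summaries[[v]]$ranef[[g]], paste0("ranef_pr_", g, "_", v, ".csv"))
    }
  }
  if (!is.null(bundle$networks$graphs)) {
    gdir <- file.path(dir, "graphml")
    dir.create(gdir, showWarnings = FALSE)
    for (cell in names(bundle$networks$graphs)) {
      nm <- paste0(gsub("/", "_d", cell), ".graphml")
      p <- file.path(gdir, nm)
      export_graphml(bundle$networks$graphs[[cell]]$projection, p)
      paths[[file.path("graphml", nm)]] <- p
    }
  }
  manifest <- list(
    seed = bundle$settings$seed, network_seed = bundle$network_seed,
    settings = unclass(bundle$settings),
    failed_stages = bundle$errors,
    files = lapply(paths, function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Render a Markdown report of a pipeline bundle
#'
#' Human-readable summary: processing dates, HRR-level national summary,
#' coefficient (PR) tables, ICC panel and diagnostics. No figures.
#'
#' @param bundle An `nh_bundle` from [run_pipeline()].
#' @param path Optional file to write.
#' @return The report as a character string (invisibly when written).
#' @export
render_report <- function(bundle, path = NULL) {
  md_table <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~round(.x, 4)))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(header, sep, rows), collapse = "\n")
  }
  n_hrrs <- length(unique(bundle$metrics$hrr))
  lines <- c(
    "# Nursing-home ownership networks and care deficiencies",
    "",
    sprintf("Processing dates analysed: %d (%s)", length(bundle$dates),
            paste(bundle$dates, collapse = ", ")),
    sprintf("HRRs represented: %d", n_hrrs),
    if (n_hrrs == 0) "No HRRs present in the panel; nothing to summarise." else "",
    "",
    "## HRR-level national summary by processing date",
    "",
    if (nrow(bundle$national)) md_table(bundle$national) else "(empty)",
    ""
  )
  for (v in names(bundle$summaries)) {
    s <- bundle$summaries[[v]]
    lines <- c(lines,
               sprintf("## Prevalence ratios (%s)", v), "",
               md_table(s$fixed), "",
               sprintf("## Intraclass correlation coefficients (%s)", v), "",
               md_table(s$icc), "",
               sprintf("## Diagnostics (%s)", v), "",
               md_table(s$glance), "")
  }
  for (v in names(bundle$errors)) {
    lines <- c(lines, sprintf("## Failed stage: %s", v), "",
               bundle$errors[[v]], "")
  }
  report <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(report, path)
    return(invisible(report))
  }
  report
}
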
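#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a fitted deficiency-count model
#'
#' One row per fixed-effect term, on the prevalence-ratio (PR) scale: the
#' PR is the exponentiated posterior mean of the coefficient and the
#' interval is the exponentiated 95% highest posterior density interval on
#' the coefficient scale (so the PR need not lie inside it when the
#' posterior is skewed). `p.value` is the two-sided MCMC tail probability
#' with its floor at one over the kept-draw count, also formatted as a
#' label in `p.label`.
#'
#' @param x An `nh_glmm`.
#' @param prob Interval mass.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log scale), `pr`, `conf.low`,
#'   `conf.high` (PR scale), `p.value`, `p.label`.
#' @export
tidy.nh_glmm <- function(x, prob = 0.95, ...) {
  purrr::map_dfr(x$terms, function(tm) {
    draws <- x$beta[, tm]
    h <- hpdi(draws, prob)
    p <- pmcmc(draws)
    tibble::tibble(term = tm, estimate = mean(draws),
                   pr = exp(mean(draws)),
                   conf.low = exp(h[["lower"]]), conf.high = exp(h[["upper"]]),
                   p.value = p, p.label = format_pmcmc(p, x$n_kept))
  })
}

#' One-row model summary
#'
#' @param x An `nh_glmm`.
#' @param ... Unused.
#' @return Tibble with sample size, kept draws, acceptance rate, max
#'   split-Rhat, min ESS, convergence flag, and the state/HRR ICCs.
#' @export
glance.nh_glmm <- function(x, ...) {
  icc <- compute_icc(x)
  pick <- function(comp) if (comp %in% icc$component) icc$icc[icc$component == comp] else NA_real_
  tibble::tibble(
    nobs = x$n, n_kept = x$n_kept,
    accept_rate = x$accept_rate,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    converged = x$converged,
    icc_state = pick("state"), icc_hrr = pick("hrr")
  )
}

#' Random-effect prevalence ratios by level
#'
#' Exponentiated posterior means of the state or HRR random intercepts:
#' the multiplicative deviation of each state/HRR from the national
#' average deficiency scope (the quantity mapped geographically in the
#' study). Levels of components whose full draws were stored also get a
#' 95% HPDI.
#'
#' @param fit An `nh_glmm`.
#' @param component `"state"` or `"hrr"` (any fitted component).
#' @return Tibble: `level`, `pr`, and when draws were stored `conf.low`,
#'   `conf.high` on the PR scale.
#' @export
ranef_pr <- function(fit, component = "state") {
  stopifnot(inherits(fit, "nh_glmm"), component %in% names(fit$u_mean))
  out <- tibble::tibble(level = names(fit$u_mean[[component]]),
                        pr = exp(fit$u_mean[[component]]))
  draws <- fit$u[[component]]
  if (!is.null(draws)) {
    hs <- apply(draws, 2, hpdi)
    out$conf.low <- exp(hs["lower", ])
    out$conf.high <- exp(hs["upper", ])
  }
  out
}

#' Full posterior summary bundle
#'
#' Fixed-effect PR table, ICC table and per-level random-effect PR tables
#' in one object — the tabular analogue of the study's coefficient table,
#' ICC panel and random-effect maps.
#'
#' @param fit An `nh_glmm`.
#' @param prob Interval mass.
#' @param include_distributional Passed to [compute_icc()].
#' @return List of class `nh_summary`: `fixed`, `icc`, `ranef` (one tibble
#'   per stored component), `glance`.
#' @export
summarize_fit <- function(fit, prob = 0.95, include_distributional = FALSE) {
  structure(list(
    fixed = tidy(fit, prob),
    icc = compute_icc(fit, prob, include_distributional),
    ranef = purrr::map(stats::setNames(nm = names(fit$u_mean)),
                       function(g) ranef_pr(fit, g)),
    glance = glance(fit)
  ), class = "nh_summary")
}

#' @export
print.nh_summary <- function(x, ...) {
  cat("Fixed effects (prevalence-ratio scale):\n")
  print(x$fixed, n = nrow(x$fixed))
  cat("\nVariance components / ICC:\n")
  print(x$icc)
  invisible(x)
}
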
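#' MCMC schedule and prior settings
#'
#' The study schedule is a sampling phase of 115,000 iterations with a
#' 15,000-iteration burn-in and a thinning interval of 10, keeping
#' (115000 - 15000) / 10 = 10,000 posterior draws. The kept-draw count
#' must come out as an integer or the schedule is rejected.
#'
#' Priors are non-informative: fixed effects Normal(0, `beta_prior_var`)
#' with a very large default variance; variance components half-Cauchy(0,
#' `scale_A`) by default, with an inverse-gamma(0.001, 0.001)
#' compatibility option.
#'
#' @param n_iter Total iterations (including burn-in).
#' @param burn_in Burn-in iterations discarded.
#' @param thin Thinning interval.
#' @param seed Integer RNG seed (mandatory: chains must be reproducible).
#' @param prior Variance-component prior family.
#' @param beta_prior_var Fixed-effect prior variance.
#' @param scale_A Half-Cauchy scale.
#' @return List of class `mcmc_settings` with an `n_kept` field.
#' @export
mcmc_settings <- function(n_iter = 115000, burn_in = 15000, thin = 10,
                          seed = 20160301,
                          prior = c("half_cauchy", "inverse_gamma"),
                          beta_prior_var = 1e8, scale_A = 5) {
  prior <- match.arg(prior)
  stopifnot(n_iter > burn_in, thin >= 1, is.numeric(seed), length(seed) == 1)
  if ((n_iter - burn_in) %% thin != 0) {
    stop("(n_iter - burn_in) must be divisible by thin", call. = FALSE)
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 n_kept = as.integer((n_iter - burn_in) / thin),
                 seed = as.integer(seed), prior = prior,
                 beta_prior_var = beta_prior_var, scale_A = scale_A),
            class = "mcmc_settings")
}

#' Fit the Bayesian cross-classified Poisson model
#'
#' Samples the posterior of the log-link Poisson mixed model
#' \deqn{y \sim Pois(\exp(X\beta + u_{state} + u_{hrr} + u_{fac} + e))}
#' by blocked Gibbs with a site-wise Metropolis update of the latent log
#' mean (see the package vignette for the scheme). The state and HRR
#' intercepts are additive and cross-classified; the facility intercept
#' captures the repeated measures across processing dates; the
#' observation-level Gaussian residual `e` absorbs overdispersion
#' (log-normal Poisson).
#'
#' @param design An `nh_design` from [build_design()], or any list with
#'   `y`, `X` and optionally `groups`.
#' @param settings From [mcmc_settings()].
#' @param random_terms Which random intercepts to include (subset of the
#'   design's groups); `character(0)` fits a fixed-effects-only
#'   log-normal Poisson model.
#' @param store_u Components whose full per-level posterior draws are
#'   retained (needed for random-effect prevalence ratios); others keep
#'   posterior means only.
#' @return Object of class `nh_glmm`: kept draws (`beta`, `sigma2`, `u`),
#'   posterior-mean random effects, term names, settings and convergence
#'   diagnostics (split-Rhat and effective sample size per fixed effect;
#'   a `converged` flag with warnings attached when diagnostics fail).
#' @export
fit_poisson_glmm <- function(design, settings = mcmc_settings(),
                             random_terms = c("state", "hrr", "facility"),
                             store_u = c("state", "hrr")) {
  stopifnot(inherits(settings, "mcmc_settings"))
  y <- design$y
  X <- design$X
  stopifnot(length(y) == nrow(X), all(y >= 0))
  groups <- design$groups[intersect(random_terms, names(design$groups))]
  store <- names(groups) %in% store_u

  # columns exactly constant within a component's groups get an extra
  # group-translation move (breaks covariate/random-intercept confounding)
  const_info <- lapply(groups, function(g) {
    G <- length(g$levels)
    cols <- integer(0)
    vals <- matrix(0, G, 0)
    for (j in seq_len(ncol(X))[-1]) {
      z <- rowsum(X[, j], g$index) / as.numeric(table(factor(g$index, levels = seq_len(G))))
      if (max(abs(X[, j] - z[g$index])) < 1e-12) {
        cols <- c(cols, j - 1L)  # 0-based for the sampler
        vals <- cbind(vals, as.numeric(z))
      }
    }
    list(cols = as.integer(cols), vals = vals)
  })

  set.seed(settings$seed)
  raw <- cc_poisson_gibbs(
    y, X,
    group_idx = lapply(groups, `[[`, "index"),
    n_groups = vapply(groups, function(g) length(g$levels), integer(1)),
    n_iter = settings$n_iter, burn_in = settings$burn_in, thin = settings$thin,
    beta_prior_var = settings$beta_prior_var,
    prior_type = if (settings$prior == "half_cauchy") 0L else 1L,
    scale_A = settings$scale_A,
    store_u = store,
    const_cols = lapply(const_info, `[[`, "cols"),
    const_vals = lapply(const_info, `[[`, "vals")
  )
  colnames(raw$beta) <- colnames(X)
  colnames(raw$sigma2) <- c(names(groups), "observation")
  names(raw$u) <- names(groups)
  raw$u_mean <- lapply(raw$u_mean, as.numeric)
  names(raw$u_mean) <- names(groups)
  for (g in names(groups)) {
    names(raw$u_mean[[g]]) <- groups[[g]]$levels
    if (!is.null(raw$u[[g]])) colnames(raw$u[[g]]) <- groups[[g]]$levels
  }

  diag_tbl <- tibble::tibble(
    term = colnames(X),
    ess = apply(raw$beta, 2, ess),
    rhat = apply(raw$beta, 2, split_rhat)
  )
  converged <- all(is.finite(diag_tbl$rhat)) && all(diag_tbl$rhat < 1.1)
  if (!converged) {
    warning("convergence diagnostics flag possible non-convergence (max split-Rhat = ",
            round(max(diag_tbl$rhat, na.rm = TRUE), 3),
            "); summaries are still produced", call. = FALSE)
  }

  structure(list(
    beta = raw$beta, sigma2 = raw$sigma2, u = raw$u, u_mean = raw$u_mean,
    terms = colnames(X), groups = groups, settings = settings,
    n = length(y), n_kept = raw$n_kept, variant = design$variant,
    accept_rate = raw$accept_rate, diagnostics = diag_tbl,
    converged = converged
  ), class = "nh_glmm")
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval of sorted draws containing
#' `ceiling(prob * n)` samples; on ties the earliest window is taken.
#'
#' @param samples Numeric vector of at least 100 posterior draws.
#' @param prob Probability mass, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(samples, prob = 0.95) {
  stopifnot(is.numeric(samples), prob > 0, prob <= 1)
  n <- length(samples)
  if (n < 100) stop("at least 100 samples required for an HPDI", call. = FALSE)
  x <- sort(samples)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Posterior two-sided tail probability (MCMC p-value)
#'
#' `2 * min(Pr(draw > 0), Pr(draw < 0))`, floored at `1 / n` so a
#' one-sided posterior reports a "< 1/n" style bound rather than zero.
#'
#' @param samples Numeric vector of at least 100 coefficient draws.
#' @return Scalar in (0, 1].
#' @export
pmcmc <- function(samples) {
  stopifnot(is.numeric(samples))
  n <- length(samples)
  if (n < 100) stop("at least 100 samples required for pMCMC", call. = FALSE)
  p <- 2 * min(mean(samples > 0), mean(samples < 0))
  max(min(p, 1), 1 / n)
}

format_pmcmc <- function(p, n_kept) {
  ifelse(p <= 1 / n_kept, paste0("<", format(1 / n_kept, scientific = FALSE)),
         format(round(p, 3), scientific = FALSE))
}

#' Intraclass correlation coefficients from variance-component draws
#'
#' Per posterior draw, the ICC of component c is
#' \eqn{\sigma^2_c / \sum_k \sigma^2_k} over the state, HRR, facility and
#' observation-level components jointly; summarized by the posterior mean
#' and 95% HPDI. The Poisson distribution-specific variance is excluded by
#' default; `include_distributional = TRUE` adds the latent-scale term
#' \eqn{\log(1/\lambda + 1)} with \eqn{\lambda} the marginal mean implied
#' by the intercept and total latent variance.
#'
#' @param fit An `nh_glmm`, or a matrix of variance-component draws
#'   (columns = components).
#' @param prob HPDI mass.
#' @param include_distributional Add the Poisson latent-scale variance to
#'   the denominator.
#' @return Tibble: `component`, `variance` (posterior mean), `icc`,
#'   `icc_lower`, `icc_upper`.
#' @export
compute_icc <- function(fit, prob = 0.95, include_distributional = FALSE) {
  sigma2 <- if (inherits(fit, "nh_glmm")) fit$sigma2 else as.matrix(fit)
  stopifnot(ncol(sigma2) >= 1)
  denom <- rowSums(sigma2)
  if (include_distributional) {
    stopifnot(inherits(fit, "nh_glmm"))
    lambda <- exp(fit$beta[, "(Intercept)"] + denom / 2)
    denom <- denom + log(1 / lambda + 1)
  }
  purrr::map_dfr(seq_len(ncol(sigma2)), function(j) {
    icc_draws <- sigma2[, j] / denom
    h <- hpdi(icc_draws, prob)
    tibble::tibble(component = colnames(sigma2)[j],
                   variance = mean(sigma2[, j]),
                   icc = mean(icc_draws),
                   icc_lower = h[["lower"]], icc_upper = h[["upper"]])
  })
}

# effective sample size via the initial positive sequence of autocovariances
ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

# split-Rhat on one chain cut in half
split_rhat <- function(x) {
  n <- length(x) %/% 2
  a <- x[1:n]; b <- x[(n + 1):(2 * n)]
  w <- (stats::var(a) + stats::var(b)) / 2
  if (!is.finite(w) || w == 0) return(NA_real_)
  mu <- c(mean(a), mean(b))
  bvar <- n * stats::var(mu)
  sqrt(((n - 1) / n * w + bvar / n) / w)
}

#' @export
print.nh_glmm <- function(x, ...) {
  cat("<nh_glmm> cross-classified Poisson model (", x$variant %||% "custom",
      "): ", x$n, " observations, ", length(x$terms), " fixed effects\n", sep = "")
  cat("  kept draws: ", x$n_kept, " (", x$settings$n_iter, "/",
      x$settings$burn_in, "/", x$settings$thin, "); Metropolis acceptance ",
      round(x$accept_rate, 2), "\n", sep = "")
  if (!x$converged) cat("  WARNING: convergence diagnostics flagged\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
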
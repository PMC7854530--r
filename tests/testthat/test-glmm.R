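test_that("MCMC schedule bookkeeping is exact and invalid schedules are rejected", {
  s <- mcmc_settings()
  expect_equal(s$n_iter, 115000L)
  expect_equal(s$burn_in, 15000L)
  expect_equal(s$thin, 10L)
  expect_equal(s$n_kept, 10000L)
  expect_equal(mcmc_settings(11500, 1500, 10, seed = 1)$n_kept, 1000L)
  expect_error(mcmc_settings(1007, 100, 10, seed = 1), "divisible")
  expect_error(mcmc_settings(100, 200, 10, seed = 1))
})

test_that("HPDI picks the shortest window, first on ties", {
  expect_equal(unname(hpdi(1:100, 0.95)), c(1, 95))
  expect_equal(unname(hpdi(rep(3, 200))), c(3, 3))
  expect_error(hpdi(1:50), "at least 100")
  # skewed draws: interval is shorter than the equal-tailed one
  set.seed(9); x <- rexp(5e4)
  h <- hpdi(x)
  et <- stats::quantile(x, c(0.025, 0.975))
  expect_lt(h[["upper"]] - h[["lower"]], et[[2]] - et[[1]])
  expect_lt(h[["lower"]], 0.01)
})

test_that("HPDI on seeded standard-normal draws approximates (-1.96, 1.96)", {
  set.seed(10)
  h <- hpdi(rnorm(1e5), 0.95)
  expect_equal(h[["lower"]], -1.96, tolerance = 0.05)
  expect_equal(h[["upper"]], 1.96, tolerance = 0.05)
})

test_that("pMCMC is the doubled minority tail with a 1/n floor", {
  expect_equal(pmcmc(c(rep(1, 9750), rep(-1, 250))), 0.05)
  expect_equal(pmcmc(c(rep(1, 5000), rep(-1, 5000))), 1.0)
  expect_equal(pmcmc(rep(1, 10000)), 1e-4)
  expect_equal(format_pmcmc(1e-4, 10000), "<0.0001")
  expect_error(pmcmc(1:10), "at least 100")
})

test_that("ICC shares follow the variance-component arithmetic", {
  eq <- matrix(1, nrow = 200, ncol = 4,
               dimnames = list(NULL, c("state", "hrr", "facility", "observation")))
  icc <- compute_icc(eq)
  expect_equal(icc$icc, rep(0.25, 4))
  one <- eq; one[, c("hrr", "facility", "observation")] <- 0
  icc1 <- compute_icc(one)
  expect_equal(icc1$icc, c(1, 0, 0, 0))
  expect_true(all(icc$icc_lower < icc$icc_upper |
                    (icc$icc_lower == icc$icc_upper)))
})

test_that("intercept-only fit on constant counts recovers the log constant", {
  k <- 54
  des <- list(y = rep(k, 400), X = matrix(1, 400, 1,
                                          dimnames = list(NULL, "(Intercept)")),
              groups = list())
  fit <- fit_poisson_glmm(des, mcmc_settings(6000, 1000, 5, seed = 2),
                          random_terms = character(0))
  expect_equal(mean(fit$beta[, 1]), log(k), tolerance = 0.02)
  expect_equal(fit$n_kept, 1000L)
})

test_that("identical seed and data give identical summaries; seeds differ otherwise", {
  set.seed(3)
  y <- rpois(200, 20)
  des <- list(y = y, X = cbind(`(Intercept)` = 1, x = rnorm(200)), groups = list())
  f1 <- suppressWarnings(fit_poisson_glmm(des, mcmc_settings(3000, 500, 5, seed = 7),
                         random_terms = character(0)))
  f2 <- suppressWarnings(fit_poisson_glmm(des, mcmc_settings(3000, 500, 5, seed = 7),
                         random_terms = character(0)))
  expect_identical(f1$beta, f2$beta)
  expect_identical(tidy(f1), tidy(f2))
  f3 <- suppressWarnings(fit_poisson_glmm(des, mcmc_settings(3000, 500, 5, seed = 8),
                         random_terms = character(0)))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("doubling a centered covariate halves its coefficient posterior", {
  set.seed(4)
  n <- 600
  x <- rnorm(n)
  y <- rpois(n, exp(2 + 0.3 * x))
  d1 <- list(y = y, X = cbind(`(Intercept)` = 1, x = x), groups = list())
  d2 <- list(y = y, X = cbind(`(Intercept)` = 1, x = 2 * x), groups = list())
  f1 <- fit_poisson_glmm(d1, mcmc_settings(6000, 1000, 5, seed = 5),
                         random_terms = character(0))
  f2 <- fit_poisson_glmm(d2, mcmc_settings(6000, 1000, 5, seed = 5),
                         random_terms = character(0))
  b1 <- mean(f1$beta[, "x"]); b2 <- mean(f2$beta[, "x"])
  mcse <- stats::sd(f1$beta[, "x"]) / sqrt(ess(f1$beta[, "x"]))
  expect_equal(b2, b1 / 2, tolerance = max(4 * mcse, 0.01))
})

test_that("posterior is insensitive to the diffuse fixed-effect prior variance", {
  set.seed(6)
  n <- 400
  x <- rnorm(n)
  y <- rpois(n, exp(2 + 0.25 * x))
  des <- list(y = y, X = cbind(`(Intercept)` = 1, x = x), groups = list())
  f1 <- suppressWarnings(fit_poisson_glmm(des, mcmc_settings(6000, 1000, 5, seed = 9,
                                            beta_prior_var = 1e8),
                         random_terms = character(0)))
  f2 <- suppressWarnings(fit_poisson_glmm(des, mcmc_settings(6000, 1000, 5, seed = 9,
                                            beta_prior_var = 2e8),
                         random_terms = character(0)))
  mcse <- stats::sd(f1$beta[, "x"]) / sqrt(ess(f1$beta[, "x"]))
  expect_lt(abs(mean(f1$beta[, "x"]) - mean(f2$beta[, "x"])), mcse)
})

test_that("exponentiation preserves HPDI ordering and the PR arithmetic", {
  expect_equal(exp(-0.23), 0.7945, tolerance = 1e-4)
  set.seed(12)
  for (rep in 1:100) {
    x <- rnorm(300, mean = runif(1, -1, 1), sd = runif(1, 0.01, 2))
    h <- hpdi(x)
    expect_lt(exp(h[["lower"]]), exp(h[["upper"]]))
    expect_equal(unname(exp(h)), unname(exp(hpdi(x))))
  }
  # all-zero coefficient draws give PR 1 with a (1,1) interval
  des <- list(y = rep(2, 200), X = matrix(1, 200, 1,
                                          dimnames = list(NULL, "(Intercept)")),
              groups = list())
  fit <- suppressWarnings(fit_poisson_glmm(des, mcmc_settings(2000, 500, 5, seed = 13),
                          random_terms = character(0)))
  fit$beta[, 1] <- 0
  td <- tidy(fit)
  expect_equal(td$pr, 1)
  expect_equal(td$conf.low, 1)
  expect_equal(td$conf.high, 1)
})

test_that("fixed effects agree with an independent MCMC implementation (JAGS)", {
  skip_if_not_installed("rjags")
  set.seed(14)
  n <- 300; G <- 10
  g <- rep(1:G, each = n / G)
  u <- rnorm(G, 0, 0.4)
  x <- rnorm(n)
  y <- rpois(n, exp(1.5 + 0.3 * x + u[g]))

  des <- list(y = y, X = cbind(`(Intercept)` = 1, x = x),
              groups = list(grp = list(index = g, levels = as.character(1:G))))
  fit <- fit_poisson_glmm(des, mcmc_settings(11000, 1000, 10, seed = 15),
                          random_terms = "grp", store_u = "grp")

  model_str <- "model {
    for (i in 1:n) {
      y[i] ~ dpois(mu[i])
      log(mu[i]) <- b0 + b1 * x[i] + u[g[i]]
    }
    for (j in 1:G) { u[j] ~ dnorm(0, tau_u) }
    b0 ~ dnorm(0, 1e-6); b1 ~ dnorm(0, 1e-6)
    tau_u ~ dgamma(0.01, 0.01)
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = y, x = x, g = g, n = n, G = G),
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 16),
                          n.chains = 1, quiet = TRUE)
  stats::update(jm, 1000, progress.bar = "none")
  samp <- rjags::jags.samples(jm, c("b0", "b1"), n.iter = 10000, thin = 10,
                              progress.bar = "none")
  # the reference model has no observation-level residual, so compare at a
  # tolerance reflecting that structural difference plus MC error
  expect_equal(mean(fit$beta[, "x"]), mean(samp$b1), tolerance = 0.05)
  expect_equal(mean(fit$beta[, "(Intercept)"]), mean(samp$b0), tolerance = 0.15)
})

test_that("state/HRR variance ratio is recovered on planted cross-classified data", {
  # planted ratio sigma2_state / sigma2_hrr = 2.4
  cfg <- nhc_sim_config(n_facilities = 1200, n_hrrs = 36, n_states = 18,
                        true_variances = c(state = 0.12, hrr = 0.05,
                                           facility = 0.25, observation = 0.25))
  sim <- simulate_nhc(cfg, seed = 17)
  panel <- sim_panel(sim)
  net <- derive_networks(panel)
  des <- build_design(panel, compute_hrr_metrics(net), net$affiliation, "model1")
  fit <- fit_poisson_glmm(des, mcmc_settings(11500, 1500, 10, seed = 18))
  med <- apply(fit$sigma2, 2, stats::median)
  ratio <- med[["state"]] / med[["hrr"]]
  expect_equal(ratio, 2.4, tolerance = 0.5)
  # facility and observation variances recovered on their own scale
  expect_equal(med[["facility"]], 0.25, tolerance = 0.5)
  expect_equal(med[["observation"]], 0.25, tolerance = 0.5)
})
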
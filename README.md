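# carenets

Latent ownership networks of US nursing homes, the market concentration
they induce, and their association with care deficiencies.

## What problem this solves

Many US nursing homes are owned by constellations of registered
organizations (LLCs, trusts, corporations). Facilities that share even one
registered-organization owner operate under a common *super-organization*,
but no public field records that tie. Since exact legal names are required
on statutory documents, the legal name itself is a usable match key.
carenets, aimed at health-services researchers working with Nursing Home
Compare (NHC) style open data, implements the full two-step procedure:

1. **Network step** — per hospital referral region (HRR) and semi-annual
   processing date: normalize owner names into match keys (remove commas,
   periods and multiple spacing; upper-case), build the bipartite
   facility–owner graph of registered organizations, project it onto
   facilities (edge weight = shared-owner count), classify facilities as
   single vs multiple affiliation by projection degree, detect ownership
   groups with the Louvain modularity algorithm, and compute bed-share
   concentration:

   HHI = Σᵢ (bᵢ / Σⱼ bⱼ)², its affiliation-accounted variant AHHI (group
   beds pooled; AHHI ≥ HHI always), and ΔHHI = AHHI − HHI, the
   concentration attributable purely to super-organization.

2. **Model step** — a Bayesian hierarchical Poisson model of the
   integer-discretized Total Weighted Health Survey Score (TWHSS; a
   weighted count of cited care deficiencies):

   y ~ Poisson(exp(Xβ + u_state + u_hrr + u_facility + e)),

   with additive cross-classified state and HRR random intercepts (HRRs
   cross state lines), a facility intercept for repeated measures, and an
   observation-level Gaussian residual for overdispersion. Results are
   reported as prevalence ratios (exponentiated posterior-mean
   coefficients) with 95% highest posterior density intervals, MCMC
   p-values, intraclass correlation coefficients per variance component,
   and per-state/per-HRR random-effect prevalence ratios.

A synthetic-data generator (`simulate_nhc()`) emulates the NHC tables with
planted ownership groups, cross-classified geography and outcomes drawn
from the model with known parameters, so every stage is testable without
downloading anything.

## Worked example

```r
library(carenets)

sim   <- simulate_nhc(nhc_sim_config(n_facilities = 1000), seed = 1)
panel <- sim_panel(sim)                  # assemble_panel() on the tables
panel
#> <nh_panel> 1000 facilities x 5 dates (971 complete-case)
#>   HRRs: 20; states: 8

net     <- derive_networks(panel)
metrics <- compute_hrr_metrics(net)
dplyr::select(national_summary(metrics, date = 1),
              prevalence_multiple_pct_mean, mean_group_size_mean,
              hhi_mean, ahhi_mean, delta_mean)
#> # A tibble: 1 x 5
#>   prevalence_multiple_pct_mean mean_group_size_mean hhi_mean ahhi_mean delta_mean
#> 1                         56.0                 3.03   0.0243    0.0543     0.0300
```

About 56% of facilities share an owner with another facility in their HRR,
in groups averaging ~3 facilities; pooling those groups roughly doubles
measured market concentration (ΔHHI ≈ 0.03 over an HHI of 0.024).

```r
des <- build_design(panel, metrics, net$affiliation, "model1")
fit <- fit_poisson_glmm(des, mcmc_settings(11500, 1500, 10, seed = 1))
dplyr::filter(tidy(fit), term == "staffing_rn_hrd")
#> # A tibble: 1 x 7
#>   term            estimate    pr conf.low conf.high p.value p.label
#> 1 staffing_rn_hrd   -0.238 0.788    0.700     0.881   0.001 <0.001
```

Each additional registered-nurse hour per resident day is associated with
~21% fewer deficiencies on this synthetic panel (the generator's true PR
is exp(−0.2) ≈ 0.82, inside the interval). `compute_icc(fit)` splits the
latent variance across state/HRR/facility/observation components,
`ranef_pr(fit, "state")` gives the per-state prevalence ratios, and
`autoplot(fit)` draws the PR forest plot. `run_pipeline()` chains the
whole procedure and `render_report()` emits a Markdown summary.

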
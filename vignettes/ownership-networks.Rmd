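---
title: "Demarcating nursing-home ownership networks and modelling care deficiencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demarcating nursing-home ownership networks and modelling care deficiencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenets)
library(dplyr)
```

## The problem

US nursing homes are frequently owned by webs of registered organizations
(LLCs, trusts, corporations) rather than by a single visible chain. Two
facilities that share even one registered-organization owner are, for many
practical purposes, under common control — a *super-organization* — yet no
single public field records that relationship. carenets reconstructs these
latent ownership networks from Nursing Home Compare (NHC) style open data,
quantifies the market concentration they induce within hospital referral
regions (HRRs), and relates both to the scope of cited care deficiencies
(the Total Weighted Health Survey Score, TWHSS) with a Bayesian
cross-classified Poisson model.

The analysis is a two-step procedure:

1. **Network step.** Within each HRR and processing date, build the
   two-mode facility–owner graph from exact legal names, project it onto
   facilities (edge weight = number of shared owners), classify facilities
   as single vs multiple affiliation by projection degree, detect
   ownership groups with Louvain modularity, and compute concentration
   indices.
2. **Model step.** Fit a log-link Poisson mixed model of the
   integer-discretized TWHSS with additive cross-classified state and HRR
   random intercepts, a facility intercept for the repeated semi-annual
   measures, and an observation-level Gaussian residual for
   overdispersion.

## Name matching

Ownership ties are keyed on the owner's exact legal name. The match key
removes all commas and periods, collapses runs of whitespace, trims ends,
and upper-cases:

```{r}
normalize_owner_name("Sunrise  Care, L.L.C.")
```

Upper-casing goes slightly beyond the bare punctuation rule; real NHC
names are already upper case, but synthetic and third-party data need not
be, and case-only key splits would be spurious. No further
canonicalization is applied — "LLC" and "L L C" stay distinct — because
the legal-name registration convention is the identifying assumption, and
aggressive suffix folding would merge legitimately distinct entities.
Facilities owned *solely* by individuals are excluded from network
construction; individual-kind owner records never create ties.

An open question in this design is whether identically named
organizations in different states are one owner. carenets builds networks
strictly within HRR (the focal market), so an owner key appearing in two
HRRs yields two independent nodes; this matches the focal-area logic and
sidesteps cross-state disambiguation.

## Networks, affiliation, and ownership groups

Within an HRR × date cell, `build_bipartite()` creates the two-mode
graph (isolated facilities retained), `project_facilities()` the weighted
one-mode projection, and `classify_affiliation()` labels a facility
*multiple-affiliation* iff its unweighted projection degree is at least 1.
`detect_ownership_groups()` runs Louvain on the projection with
shared-owner counts as weights and resolution 1.0 (neither is prescribed
by the source method; both are arguments). Whether community detection
ran on the bipartite graph or the projection is not documented in the
method we implement; we use the projection — ownership groups are groups
*of nursing homes* — and the bipartite alternative can be emulated by
projecting first in any case.

Communities of size ≥ 2 are the ownership groups. Size-1 communities are
exactly the single-affiliation facilities and are reported separately:
counting them as "groups" would drag the mean group size toward 1 and is
inconsistent with observed mean group sizes near 3. In the rare case the
modularity search strands a connected node in a singleton community, it
is merged into its heaviest-weighted neighbour's community, so groups
always partition the multiple-affiliation set — an invariant the test
suite checks against a brute-force pairwise-sharing oracle.

Louvain shuffles node order internally; carenets seeds the RNG (default
seed 20160301) and inserts vertices in sorted-id order, so results are
reproducible and invariant to input row order.

## Market concentration

With $b_i$ the certified beds of facility $i$ in an HRR,

$$\mathrm{HHI} = \sum_i \left(\frac{b_i}{\sum_j b_j}\right)^2,$$

and the affiliation-accounted index AHHI is the same sum after pooling
the beds of each ownership group into one unit. Pooling squared shares is
superadditive, so $\mathrm{AHHI} \ge \mathrm{HHI}$ always;
$\Delta\mathrm{HHI} = \mathrm{AHHI} - \mathrm{HHI}$ is the concentration
attributable purely to super-organization. Indices are reported on the
0–1 scale. Facilities with zero certified beds hold no market share and
are excluded with a warning (their treatment is otherwise undocumented in
the source method). AHHI pools Louvain groups by default; because planted
groups in the generator are realized as disjoint shared-owner cliques,
pooling by connected components gives identical results there, and a
caller can pass any partition to `ahhi()`.

## HRR aggregation

`compute_hrr_metrics()` produces the five HRR-level explanatory
variables: prevalence of multiple-affiliation facilities (%), mean
ownership-group size, HHI, AHHI, ΔHHI. An HRR × date with no groups gets
mean group size 1 (every facility standalone) with a `no_groups` flag, so
the regression covariate is defined everywhere. National summaries are
unweighted means and sample SDs (n−1) across HRRs — the summary table is
captioned at HRR level, so facility-weighted averaging is deliberately
not used.

## The outcome model

For facility $i$ in state $s$, HRR $h$, at date $t$:

$$y_{iht} \sim \mathrm{Poisson}(e^{\eta_{iht}}), \qquad
\eta_{iht} = x_{iht}'\beta + u^{\mathrm{state}}_s + u^{\mathrm{hrr}}_h +
u^{\mathrm{fac}}_i + e_{iht},$$

with $u^{\mathrm{state}} \sim N(0, \sigma^2_{\mathrm{state}})$ etc. and
an observation-level residual $e_{iht} \sim N(0, \sigma^2_{\mathrm{obs}})$
making the counts log-normal-Poisson (overdispersed). States and HRRs are
*cross-classified*: HRR boundaries cross state lines, so the two
intercepts enter additively rather than nested. The facility intercept
carries the repeated measures; the source method names neither the
facility term nor the overdispersion device explicitly, so both are
explicit switches here (`random_terms`).

The outcome is the TWHSS discretized to the nearest integer
(half-away-from-zero; the rule is stated only as "nearest integer").
Continuous covariates are mean-centered over the analysis sample.
Model 1 includes the ordinal five-star rating (dummies, category 1
reference); model 2 replaces it with the 21 MDS measure-code prevalences,
because the rating is derived from those measures and including both
would be collinear. Reference levels: for-profit ownership, multiple
affiliation, and their interaction cell.

### Priors

"Non-informative" is made concrete as: fixed effects
$N(0, 10^8)$; variance components half-Cauchy(0, 5) via the
inverse-gamma mixture representation, with an inverse-gamma(0.001, 0.001)
compatibility option (`prior = "inverse_gamma"`). A prior-sensitivity
test doubles the fixed-effect prior variance and requires posterior means
to move by less than one Monte-Carlo standard error.

### Sampler

Conditional on the latent log-mean $\theta_{iht} = \eta_{iht}$, the model
is a Gaussian linear mixed model, so carenets samples by blocked Gibbs
with one Metropolis block:

* $\theta_i$: site-wise random-walk Metropolis; the proposal scale
  $2.4/\sqrt{e^{\theta_i} + 1/\sigma^2_{\mathrm{obs}}}$ tracks the local
  posterior curvature, giving ~40–45% acceptance without tuning runs.
* $\beta$, each $u$ block, and all variances: exact conjugate draws.
* After each $u$ block, translation-group (Liu–Sabatti) moves shift the
  block mean into the intercept, and analogous moves run along every
  fixed-effect column that is exactly constant within the block's groups
  (HRR-level covariates vs HRR intercepts, facility-constant dummies vs
  facility intercepts). These moves leave the posterior invariant and
  break the random-intercept/covariate confounding that otherwise
  cripples mixing of group-level coefficients.

All randomness flows through R's RNG, so a single seed makes chains
byte-reproducible. The published schedule — 115,000 iterations, 15,000
burn-in, thinning 10, hence exactly 10,000 kept draws — is the default;
the sampler is a contract, not a prescription: any scheme passing the
closed-form-limit, reparameterization and coverage tests is conformant,
and reduced chains (11,500/1,500/10) are used in tests.

### Summaries

Prevalence ratios are `exp(posterior mean coefficient)`; intervals are
the exponentiated 95% highest posterior density interval computed on the
coefficient scale (shortest window over sorted draws, first window on
ties). The PR uses the mean, not the median — so a PR can in principle
fall outside its own interval under extreme skew, which is expected
behaviour, not a bug. pMCMC is `2·min(Pr(>0), Pr(<0))` floored at one
over the kept-draw count and labelled `<1/n` at the floor. ICCs divide
each variance component by the sum of all four; the Poisson
distribution-specific variance is excluded by default and can be added
(`include_distributional = TRUE`, using the latent-scale term
$\log(1/\lambda + 1)$) — whether the source analysis included it is
unreported, hence the switch. Per-state and per-HRR random-intercept PRs
(`ranef_pr()`) are the geographic random-effect summaries.

## The synthetic-data generator

`simulate_nhc()` emulates the study conditions so every stage has ground
truth: five semi-annual dates; ownership-type mix 74.3 / 6.5 / 19.2%
(for-profit / government / non-profit); a target multiple-affiliation
prevalence of 56.8% per HRR; group sizes from a truncated geometric
(minimum 2, mean ≈ 3.15, echoing observed mean group sizes of 3.1–3.2);
log-normal certified beds (median 100); a marginal TWHSS mean of ~58
(observed range 54.5–63.6), with the intercept solved numerically so the
marginal mean is hit exactly; and true variance components (state 0.12,
HRR 0.05, facility 0.25, observation 0.25) whose implied state/HRR ICCs
≈ 0.18/0.075 and ratio 2.4 echo the reported variance structure. A
configurable fraction of HRRs spans two states, so cross-classification
is genuinely present. Planted groups are realized as shared owner keys
whose raw names are decorated with commas, periods, stray spacing and
case noise to exercise normalization; individual owners and
individual-only facilities exercise the exclusion rules; configurable
missingness drives the smaller model-2 sample exactly as the
completeness filter dictates.

What the generator does **not** emulate: real name-typo distributions
(keys always normalize back exactly), facility entry/exit (the panel is
balanced), ownership churn between dates, and spatial correlation beyond
the state/HRR intercepts. Passing tests therefore demonstrate correctness
of the pipeline's logic and calibration of the sampler under the stated
model — not robustness to dirty real-world records.

```{r, eval = FALSE}
sim <- simulate_nhc(nhc_sim_config(n_facilities = 1000), seed = 1)
panel <- sim_panel(sim)
bundle <- run_pipeline(panel, settings = mcmc_settings(11500, 1500, 10, seed = 1))
tidy(bundle$fits$model1)
```

## Numerical choices and degenerate inputs

* Discretization: half-away-from-zero; ties like 54.5 go up.
* Louvain ties: seeded RNG plus sorted vertex insertion make runs
  deterministic and order-invariant.
* Empty projection → empty group table; empty complete-case panel is a
  valid empty result, not an exception; a single-HRR panel fails the
  model stage with a rank-deficiency error naming the aliased columns
  (HRR-level covariates are constant there), while network outputs
  survive in the bundle.
* Zero-bed facilities are dropped from concentration with a warning; an
  all-zero market is an error.
* The linear predictor is guarded at 30 on the log scale; the generator
  refuses configurations that exceed it.

## Problem sizes used in the checks

The test suite runs reduced chains (11,500/1,500/10) on panels of up to
2,000 facilities × 5 dates across 20 HRRs and 8 states, with 20 seeded
replicates for the coverage experiment and a 1k/2k/5k-facility ladder for
the interval-width monotonicity check; these sizes give stable pass/fail
behaviour for the statistical properties being verified while keeping a
full run of the suite comfortably repeatable. The acceptance script uses
a 1,000-facility panel and one reduced-chain fit.

## Known limitations

* Exact-key matching understates connectivity wherever real records
  misspell a legal name; concentration is correspondingly underestimated.
* Network variables feed both models from the model-1 complete-case
  sample; the model-2 subsample does not get its own network pass.
* Lagged effects of ownership change are not modelled.
* The half-Cauchy scale (5) matters for variance components when a
  component has very few levels (e.g. few states); posterior means of
  variances are then heavy-tailed, which is why recovery checks use
  posterior medians.
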
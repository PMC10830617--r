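---
title: "Screen-time-based attentiveness weighting: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screen-time-based attentiveness weighting: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attweights)
```

## The problem

Careless/insufficient-effort responding (C/IER) — answering survey items
without processing their content — contaminates large-scale questionnaire
data: random or patterned responses attenuate associations and distort
group comparisons. Hard screening rules (drop everyone below a time
threshold) force a binary call where the evidence is graded, and the
threshold itself is arbitrary. `attweights` implements a two-step weighting
alternative for computer-administered surveys where each scale sits on one
screen and the time spent on that screen is recorded.

**Step 1 — decompose screen times.** For each group × scale cell, the log
per-item screen time $x_i = \ln(t_i)/J$ is modelled as a $C$-component
Gaussian mixture
$$f(x_i) = \sum_{c=1}^{C} \pi_c\, \varphi(x_i;\, \mu_c, \sigma_c),$$
with $C$ chosen by BIC among $1,\dots,9$. When $C \ge 2$, the component
with the lowest mean is labelled the C/IER component; its mixture
proportion $\pi^{\mathrm{CIER}}$ estimates the cell-level C/IER rate, and
each respondent's posterior probability of belonging to it,
$\pi_i^{\mathrm{CIER}}$, quantifies the evidence that this particular
session was inattentive. A one-component solution is read as "no C/IER
detected".

**Step 2 — weight the analysis model.** The attentiveness weight
$w_i = 1 - \pi_i^{\mathrm{CIER}}$ multiplies respondent $i$'s
log-likelihood contribution in the analysis model — here a multi-group
generalized partial credit model (GPCM) estimated by marginal maximum
likelihood — together with the survey's sampling weight $v_i$
(pseudo-likelihood weighting):
$$\ell = \sum_i w_i v_i \log \int \prod_j p(y_{ij}\mid\theta)\,
  dF_{\gamma_g}(\theta).$$
Threshold screening is the degenerate special case $w_i \in \{0, 1\}$.

## Estimation choices

### Weighted Gaussian mixture

* Case weights multiply every EM sufficient statistic, so an integer weight
  is exactly replication of the observation; weights are normalized to mean
  1 per cell before fitting, keeping the likelihood on the per-observation
  scale.
* Components have unequal variances. This is deliberate: attentive time
  distributions are often heavy-tailed, and a narrow-plus-wide pair of
  near-equal means is a configuration that actually occurs. The flip side
  is discussed under *Limits* below.
* BIC is $-2\ell + (3C-1)\ln n$ with $n$ the number of observations (not
  the weight sum); ties go to the smaller $C$. Cells with fewer than
  $\max(10C, 50)$ observations skip candidate $C$ (a cell below 50
  observations falls back to $C=1$ with a warning).
* Initialization: weighted type-1-quantile seeds refined by a weighted
  Lloyd pass; five restarts (the first unjittered, four jittered) each get
  a 50-iteration preliminary EM and only the best-by-likelihood candidate
  is polished to convergence (relative log-likelihood change $<10^{-8}$,
  at most 500 iterations). Variances are floored at $10^{-4}$ so
  duplicated times cannot produce degenerate spikes. The EM inner loop is
  compiled (Rcpp); a pure-R reference loop is kept and cross-checked in
  the test suite.
* Posteriors are computed in log space, so extreme times give exact 0/1
  rather than NaN. Ties in the minimum component mean go to the lowest
  index with a warning.
* Rows with a missing screen time are not decomposed: there is no evidence
  basis for down-weighting them, so they keep weight 1 and are flagged
  `not_assessed` in the weights table.
* Both prevalence readings are reported: the mixture proportion
  $\pi^{\mathrm{CIER}}$ (primary) and the weighted mean posterior
  (secondary); they differ when the components overlap.
* Two transforms are exposed: the per-item geometric-mean log time
  $\ln(t)/J$ (default — it puts all scales on a per-item scale so the
  C/IER component mean back-transforms to seconds per item) and the total
  log screen time $\ln(t)$.

### Weighted multi-group GPCM

* Identification follows operational practice: item parameters common to
  all groups, group 1 fixed at $N(0,1)$, remaining group means/SDs free.
* Quadrature: 61 rectangle nodes on $[-6, 6]$ in the group-standardized
  metric ($\theta_{gq} = \mu_g + \sigma_g z_q$), deterministic and cheap.
* EM: the E-step computes weighted posteriors over the nodes; the M-step
  updates each item by one damped Newton step in a category-intercept
  parameterization $(a, c_1,\dots,c_K)$ — the multinomial-logit form makes
  gradient and Hessian closed-form — and the free group moments in closed
  form. Convergence: maximum absolute parameter change $< 10^{-5}$, at
  most 1000 cycles.
* Categories never observed with positive weight are collapsed onto the
  adjacent lower category (logged); all-missing rows are dropped from
  estimation but kept in the weight output; zero-weight rows are excluded
  exactly (a zero weight reproduces the fit on the remaining subset).
* The adjusted/unadjusted comparison reports group means in the common
  group-1 metric. "Standardized" group differences are differences in that
  metric; a per-group-SD-scaled variant is emitted alongside, since the
  scaling convention is a genuine open choice.

### Hierarchical Beta regression

Cell-level C/IER proportions are regressed on scale characteristics
(screen position, number of items, number of response options, average
text length) with a group random intercept:
$$y_{sg} \sim \mathrm{Beta}(\mu_{sg}\phi, (1-\mu_{sg})\phi), \qquad
  \mathrm{logit}(\mu_{sg}) = \mu_{\beta_0} + b_g + \textstyle\sum_p
  \beta_p x_{ps}, \qquad b_g \sim N(0, \sigma_{\beta_0}^2).$$

* **Bayesian route** (default): adaptive random-walk Metropolis within
  Gibbs — single-site updates for fixed effects and intercepts, log-scale
  updates for $\sigma_{\beta_0}$ and $\phi$, plus a translation move along
  the $\mu_{\beta_0}$/intercept-mean ridge that leaves the data likelihood
  unchanged and fixes the one slow direction of the sampler. Priors:
  $N(0,10)$ on fixed effects, half-Cauchy(0, 5) on $\sigma_{\beta_0}$ and
  $\phi$. Two chains of 3000 iterations, first half warm-up (where
  proposal scales adapt toward 0.30–0.45 acceptance), EAP point estimates,
  split-$\hat R$ (PSRF) per parameter with 1.05 as the alarm line.
* **ML route**: the random intercepts are integrated out by adaptive
  Gauss–Hermite quadrature (21 nodes, per-group mode and curvature), and
  the marginal likelihood is maximized by BFGS; standard errors come from
  the numeric Hessian. On shared fixtures this route matches glmmTMB's
  Beta-family fit to four decimals, and it is the fast default in the
  pipeline.
* Proportions of exactly 0 or 1 (possible for tiny cells) are moved inside
  the open interval by $(y(n-1)+\tfrac12)/n$ before fitting.
* Covariates enter on their raw scales (positions in screen numbers,
  lengths in words); no centering is applied, so the intercept refers to a
  hypothetical scale at covariate zero and predictions should be made via
  `predict_cier_mean()` at substantive covariate profiles.

## What the generator emulates — and what it does not

`simulate_cier_dataset()` produces grouped respondents with: lognormal
per-item screen times (attentive component(s) around 2.08 s per item, a
C/IER component around 1.13 s, log-scale SDs 0.3 — a standardized
separation near 2, matching the timing texture of a long background
questionnaire); a configurable C/IER session rate (default 0.06);
GPCM-consistent attentive responses at group-distributed trait values;
C/IER responses as a mix of uniform-random, straight-line and
full-omission styles (defaults 0.4/0.3/0.3); item omissions at
label-conditional rates (0.02 attentive, 0.10 C/IER); and lognormal(0,
0.25) sampling weights normalized to mean 1 per group. Group 1 is pinned
at $N(0,1)$; free group means are drawn from $N(0, 0.3)$ and SDs from
$U(0.85, 1.2)$.

The generator deliberately matches the assumptions of the detection model
(normal log-time components, C/IER strictly fastest on average, C/IER
independent of the trait). Passing tests therefore demonstrate internal
consistency and correct estimation, **not** robustness to the ways real
data violate those assumptions: heavy-tailed attentive times, trait-
correlated carelessness, distracted-slow C/IER, or multiple C/IER
components. The style mix is a fixture device, not an empirical claim.

## Numerical behavior worth knowing

* **Separation matters more than sample size.** The $8/d^4$ rule
  (`minimum_sample_size()`) is a floor for detectability, not for
  proportion accuracy. At separation $d \approx 2$ with unequal variances
  the *global* ML solution at $n = 1000$ can put ~0.4–0.6 of the mass in
  the lowest-mean component when the generating rate is 0.15 — an
  independent implementation (mclust) finds the same structure. Recovery
  tests in this package therefore run at $d = 3$, and applied users
  should treat cell-level proportions at small separation as exploratory.
  This is the same failure mode as the heavy-tail artifact: a wide
  low-mean component soaking up an attentive tail.
* **The one-component fallback is conservative**: a cell that genuinely
  contains C/IER but selects $C=1$ assigns everyone weight 1, i.e. reverts
  to the unadjusted analysis rather than guessing.
* **Problem sizes in the test suite** were chosen to exercise each
  guarantee at the smallest size where it is statistically decidable:
  mixture recovery at $n$ = 2000–5000, GPCM recovery at $N$ = 3000, and
  Beta-regression recovery at
  $30 \times 40$ cells (the degenerate-hierarchy check at $30 \times 120$,
  where the SD estimate's noise floor sits safely below the 0.05
  criterion). The contamination experiment (20% uniform-random responders
  down-weighted to near zero) uses $N = 1200$, 6 items and a contaminated
  group mean of 1.8: per-replication "adjusted beats unadjusted" contests
  are only decidable when the contamination bias (here $\approx 0.35$)
  clearly dominates the shared sampling noise of the two estimators
  ($\approx 0.085$); at smaller designs the unadjusted estimate is too
  often accidentally right.

## Known limitations

* One C/IER component, always the lowest-mean one: multiple careless
  regimes, or a slow/distracted careless class, are mislabelled by
  construction.
* Screen-level times only; no reconstruction of item-level response times.
* The GPCM fit reports no standard errors (the pipeline's purpose is the
  adjusted-vs-unadjusted contrast, not inference on single parameters).
* Beta-regression covariates are taken at face value; no interactions or
  random slopes.
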
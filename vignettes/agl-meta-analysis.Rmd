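---
title: "Multilevel meta-analysis of artificial grammar learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel meta-analysis of artificial grammar learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aglmeta)
```

# The problem

Artificial grammar learning (AGL) experiments expose a learner — a human
adult, an infant, a songbird, a tamarin — to sequences generated by a
structured grammar, then test whether the learner discriminates conforming
from non-conforming sequences. The literature is heterogeneous in every way
that matters for synthesis: outcomes are proportions correct, go/no-go hit
rates, head turns, looking times, or reaction-time differences; several
tests are often reported per article; and design features (modality,
training length, vocabulary size, adjacency structure, repetition of
training items at test) vary simultaneously. `aglmeta` implements a
meta-analytic pipeline for this literature: harmonize each reported outcome
into a common standardized effect size, pool with a nested random-effects
model, attribute heterogeneity to coded moderators, and check the funnel
for publication bias. A synthetic coding-sheet generator with the same
statistical structure makes the whole pipeline testable end to end without
any external data.

# Effect-size harmonization

Every outcome is converted to the standardized-mean-difference family.
Cohen's *d* is computed per paradigm and corrected for small-sample bias to
Hedges' *g*:

$$J = 1 - \frac{3}{4\,df - 1}, \qquad g = J \times d, \qquad
  V_g = \left(\frac{1}{n} + \frac{d^2}{2n}\right) J^2 .$$

The variance expression is the Borenstein-convention form for the corrected
standardized mean difference; the correction enters the variance squared
because $g = Jd$ is a linear rescaling. We use $df = n - 1$ throughout:
every design handled here is a one-sample comparison or a within-subject
(paired) contrast, so $n - 1$ is the natural degrees of freedom for both
$J$ and $V_g$.

**Chance-comparison paradigms** (accuracy against chance, yes/no and
go/no-go endorsement, scale judgements, forced choice, head-turn preference,
frequency estimation) are scored as a one-sample difference,
$d = (\bar{x} - \text{chance}) / SD_{\text{within}}$. When similar tests are
reported over several sessions, session means are pooled weighted by
participant count and session SDs are pooled with degrees-of-freedom
weights, $SD_{\text{avg}} = \sqrt{\sum_i (n_i - 1) SD_i^2 / \sum_i (n_i - 1)}$,
generalized to any number of sessions.

**Paired paradigms** (serial reaction time, sequence reproduction, looking
time) are scored as the standardized grammatical-vs-ungrammatical contrast
using the same averaged SD. Using the raw between-condition difference with
$SD_{\text{avg}}$ in the denominator and total $n$ in the variance is the
conservative treatment: it is equivalent to assuming the two within-subject
conditions are perfectly correlated, so the reported effect and its
precision are never overstated by an unknown correlation.

**Sign conventions** are centralized in the `agl_paradigms` table: positive
*g* always means a structure-conforming advantage. For reaction times,
learning is *faster* responses to trained structure; for looking time,
learning is *longer* looking at violating (novel) stimuli. When the
original authors interpreted a grammatical-stimulus preference (a
familiarity effect) as learning, the coding sheet flags the record and the
harmonized effect is re-signed, so the learning direction stays consistent
across the dataset; the flip is an involution and leaves $V_g$ untouched.

**Reporting conversions.** Sessions reported as a mean with a confidence
interval instead of an SD are converted at ingest via
$SD = \sqrt{n}\,(\text{upper} - \text{lower}) / (2\,t_{crit,\,n-1})$,
assuming the interval was built from the *t* distribution — the
conservative choice, since a *z*-based interval would imply a smaller SD.
Proportions arriving on the 0–100 scale (detected by the chance value) are
rescaled to 0–1; *g* is scale-invariant, so this only standardizes the
stored summaries.

# The multilevel model

Articles contribute several non-independent effects (multiple experiments,
multiple tests). The pipeline therefore fits a three-level random-effects
meta-regression,

$$g_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + u_i + w_{ij} +
  \varepsilon_{ij}, \qquad
  u_i \sim N(0, \sigma^2_{\text{article}}),\;
  w_{ij} \sim N(0, \sigma^2_{\text{study}}),\;
  \varepsilon_{ij} \sim N(0, v_{ij}),$$

with $v_{ij}$ the known sampling variances. Marginally the covariance is
block-diagonal by article, compound-symmetric within blocks. The two
variance components are estimated by restricted maximum likelihood (REML),
which corrects the variance estimates for the estimation of
$\boldsymbol\beta$; the coefficients are generalized least squares at the
optimum.

**Inference** uses the *t* method: each coefficient is referred to a *t*
distribution on $k - p$ degrees of freedom ($k$ effects, $p$ coefficients),
and confidence intervals use the corresponding critical value. Omnibus
moderator tests divide the joint Wald chi-square of a moderator's $m$
coefficients by $m$ and refer it to $F(m,\, k - p)$. Heterogeneity is
tested with Cochran's $Q$, computed from the inverse-variance-weighted
fixed-effect fit regardless of the random-effects structure — the standard
definition — on $k - 1$ df for the intercept-only model and $k - p$ with
moderators.

**Moderator coding.** Categorical moderators expand by treatment coding
(reference level first alphabetically) in moderated fits, and by cell-means
coding (no intercept) for subgroup estimation, where each coefficient is
directly that level's weighted mean effect. Subgroup estimates are taken
from the single cell-means model rather than separate per-class fits, so
all classes share one pair of variance components; per-class *moderator*
analyses, by contrast, refit within the class subset, because the question
there is heterogeneity *within* that class. Rows missing a moderator are
excluded from that moderator's analysis only, with a logged count.
Moderators constant within a subset (non-human mammals tested only
auditorily, for instance) are flagged by `filter_subset()` and skipped,
with the skip logged.

# Publication-bias diagnostics

Peters' regression test enters inverse total sample size $1/n$ as the sole
moderator in the same multilevel machinery and *t*-tests its slope on
$k - 2$ df. The original formulation targets log odds ratios with a
specific weighting scheme; for standardized mean differences we run the
$1/n$ moderator inside the nested REML model, which keeps the test
consistent with every other moderator analysis and with the nesting of
effects in articles. A significant slope means small studies report
systematically different effects — the funnel-asymmetry signature of
publication bias. `funnel_coordinates()` returns the $(g, \sqrt{V_g})$
scatter labelled by animal class with the overall multilevel estimate as
the reference line, and `apply_selection_bias()` lets the generator induce
the asymmetry deliberately so the test's power can be demonstrated
(`analysis/05_bias.R`).

# The synthetic-data generator

`synthetic_config()` fixes the study conditions; `simulate_effects()` draws
from exactly the generative model the analysis assumes, with
$v = 1/n + \theta^2/(2n)$ attached to each effect's true value $\theta$.
Defaults emulate the scale of the comparative AGL literature: 66 articles
contributing one to four effects each (~160 effects), a true overall effect
of 1.0, variance components 0.5 (between-article) and 0.25
(within-article) — substantial heterogeneity of the size the large observed
$Q$ statistics in this literature imply — participant counts of 10–40 for
human and 4–12 for non-human studies, and an animal-class mix of 64% human
adult, 7% child, 5% non-human mammal, 24% bird, chosen to match the
relative subgroup sizes of published comparative syntheses. Non-human
animals are always simulated auditory and never with questionnaire-style
responses, reproducing the confounding between class and design that makes
per-class moderator skipping necessary.

`simulate_raw_studies()` then *inverts the harmonization algebra*: it picks
a plausible within-study SD per paradigm (0.15 for proportions, 100 ms for
RTs, 2 s for looking times), backs out the condition means that yield the
target *d*, and emits per-session raw statistics — including two-session
splits (30% of chance-paradigm records), CI-only reporting (20% of
single-session records), and familiarity-flagged looking-time effects (50%
of them). Harmonization of these records recovers the simulated effects to
machine precision, which is the point: the generator tests the pipeline's
algebra, not a behavioural model of learning. What it therefore does *not*
emulate: trial-level response processes, digitization error from
figure-extracted statistics, correlated moderators beyond the class/design
confounds above, or non-normal true-effect distributions. Passing tests
certify the pipeline's statistics, not any claim about real learners.

# Numerical choices

* **Optimizer.** The restricted log-likelihood is maximized over
  $(\sigma^2_{\text{article}}, \sigma^2_{\text{study}})$ by a bounded
  quasi-Newton search (`nlminb`) with the analytic REML gradient, run from
  the fixed starts $(0,0)$, $(0.1,0.1)$, $(1,1)$ and keeping the best
  optimum, so every fit is deterministic. The search works on the natural
  scale with a lower bound of 0 rather than on log-variances: variance
  components genuinely sit on the boundary (a single-effect-per-article
  dataset cannot separate the two), and the boundary is reachable exactly
  on the natural scale. Convergence tolerance is $10^{-10}$ relative.
* **Linear algebra.** The marginal covariance is never formed densely:
  solves use the Sherman–Morrison identity per article block, so one
  likelihood evaluation is $O(k p^2)$. This is what makes the
  1000-replicate calibration studies run in minutes.
* **Degenerate inputs.** $J(1) = 0$, so an effect with $n = 2$ carries
  $g = 0$ with $V_g = 0$ at $d \ne 0$ only in the limiting $df = 1$ case;
  `variance_g()` returns 0 there without error, and `meta_dataset()`
  rejects non-positive $v_g$. Rank-deficient designs error with the
  collinear columns named; constant moderators error rather than silently
  dropping.
* **Determinism.** All simulation is seeded through `synthetic_config()`;
  result tables are written with 17-significant-digit numeric formatting,
  so a write/read/write cycle and repeated pipeline runs are
  byte-identical.

# Known limitations

* **Weighting bias under effect-dependent variances.** Because the sampling
  variance of a standardized mean difference increases with the effect
  itself ($V_g \propto 1 + d^2/2$), inverse-variance weights correlate
  negatively with true effects, and the pooled estimate of a strongly
  heterogeneous literature is pulled slightly toward zero. The calibration
  study run by `scripts/acceptance.R` quantifies this at its settings
  (40 articles × 3 effects, $\mu = 1$, $\tau^2 = 0.3/0.1$): the mean
  estimate falls about 4% below the generating value and CI coverage is
  near 0.91 rather than 0.95. The same figures arise from an independent
  multilevel REML implementation on identical replicates, and the bias
  vanishes when variances are simulated independently of the effects — it
  is a property of SMD weighting, not of the estimator. Interpret small
  differences in pooled estimates accordingly.
* **df approximation.** The *t* method with $k - p$ df does not account
  for the effective number of articles; with few articles and many effects
  per article, intervals can be anti-conservative. A Satterthwaite-type df
  is out of scope here.
* The conservative correlation-1 treatment of paired designs deliberately
  understates those effects' precision.
* The archival coding sheet of the published comparative analysis cannot be
  redistributed; the comparisons against its printed results run only when
  a user supplies it (see `inst/extdata/README.md`).

# Problem sizes used in the shipped studies

The packaged tests and the acceptance script use: the default
literature-scale generator (~66 articles / ~160 effects) for end-to-end
runs; 500 replicates at 40 articles × 3 effects for recovery and coverage;
1000 literature-scale replicates for the Peters type-I study; and $k = 8$
instances for the dense grid-search verification of the REML optimizer
(coarse step 0.05 on $[0,2]^2$, refined to 0.005 around the coarse
maximum).
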
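---
title: "Calibration priors, joint-prior truncation, and cross-validation of fossil calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration priors, joint-prior truncation, and cross-validation of fossil calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chronocal` dissects the prior layer of Bayesian divergence-time
estimation. This vignette records the models it implements, the tunable
parameters and their defaults, the numerical choices, what the synthetic
data emulate (and do not), and the design decisions taken where the design
was genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

A dating analysis places a joint prior on the vector of internal node ages
$\mathbf{t}$ of a rooted, bifurcating tree whose tips are extant (age 0,
Ma before present). Individual fossil calibrations contribute per-node
densities; a tree prior (a branching-process kernel) covers the rest; and
the whole object is *truncated* to the region where every ancestor is
strictly older than its descendants. That truncation, together with the
tree prior, is why the marginal prior actually realised at a node — the
*effective* prior — differs from the density the user wrote down — the
*specified* prior. The package's diagnostics, samplers and statistics exist
to expose and quantify that difference.

### Calibration densities

Two families, both anchored on a hard minimum $t_L$ (zero mass below; a
configurable lower tail mass exists but defaults to 0):

* **Uniform with soft maximum.** Density $(1 - p_R)/(t_U - t_L)$ on
  $[t_L, t_U]$ and an exponential upper tail of total mass $p_R$ (default
  0.025). The tail's functional form is this package's choice: an
  exponential matched so the density is continuous at $t_U$ — the minimal
  contract (fixed tail mass, no density jump) consistent with common
  soft-bound practice. The decay rate follows as
  $\lambda_R = (1-p_R)/(p_R (t_U - t_L))$.
* **Truncated Cauchy.** A Cauchy with location $t_L(1+p)$ and scale
  $c\,t_L$ renormalised on $[t_L,\infty)$, the usual heavy-tailed model of
  how far a divergence may predate its oldest fossil. $p$ (location
  offset) and $c$ (scale factor) are dimensionless; the density peaks at
  $t_L(1+p)$ regardless of $c$. The grid explored by the experiment
  runner is $p \in \{0.1, 0.5\}$, $c \in \{0.1, 0.5, 1, 2\}$.

All four of pdf/cdf/quantile/sampling are closed-form (`dcal`, `pcal`,
`qcal`, `rcal`); sampling is by inverse cdf.

### Two joint-prior constructions

With calibrated set $\mathcal{C}$ and tree-prior kernel $g(\cdot \mid
t_\mathrm{root})$,

* **conditional** (truncation-based, as in dating programs that build the
  time prior before seeing data):
  $\pi(\mathbf{t}) \propto \prod_{i \in \mathcal{C}} f_i(t_i)
  \prod_{j \notin \mathcal{C}} g(t_j \mid t_\mathrm{root})\,
  \mathbf{1}[\text{order valid}]$;
* **multiplicative** (as in programs that multiply calibration densities
  into the tree prior):
  $\pi(\mathbf{t}) \propto \prod_{i \in \mathcal{C}} f_i(t_i)
  \prod_{j \ne \mathrm{root}} g(t_j \mid t_\mathrm{root})\,
  \mathbf{1}[\text{order valid}]$.

The root must carry an upper-bounded calibration under either construction
— there is deliberately no silent default upper limit; an unbounded root is
a configuration error, as is a pair of calibrations whose hard bounds leave
zero support (the infeasibility is named, not silently truncated away).

The conditional construction here is a simplification of full sequential
conditioning between calibrated nodes: uncalibrated nodes receive the
kernel conditional on the root age only, with the order indicator carrying
all interaction. The truncation phenomena under study — marginals reshaped
by overlapping calibrations and by the kernel — only require this
product-times-indicator structure.

### Tree-prior kernels

The default kernel is uniform order statistics on $(0, t_\mathrm{root})$:
$g \equiv 1/t_\mathrm{root}$. A birth–death kernel (per-lineage birth
$\lambda$, death $\mu$, sampling fraction $\rho$; default
$\lambda = 1, \mu = 1, \rho = 0.1$ when selected) is available:
$g(t) \propto P(0,t)^2 e^{(\mu-\lambda) t}$ with
$P(0,t) = \rho(\lambda-\mu)\,/\,(\rho\lambda +
(\lambda(1-\rho)-\mu)e^{(\mu-\lambda)t})$, normalised in closed form on
$(0, t_\mathrm{root})$; at $\lambda = \mu$ it collapses to the uniform
kernel. The uniform default reflects that the truncation effects under
study do not depend on the kernel choice; the choice is documented, not
hidden.

## Sampling

`sample_prior()` and `sample_posterior()` run Metropolis–Hastings over node
ages (plus the clock rate for posteriors):

* per-node uniform slide within (oldest child age, parent age) — the window
  depends only on the neighbours, so the proposal is symmetric and every
  accepted state is order-valid by construction;
* a multiplier move on the root age (log-scale step, Jacobian included;
  soft maxima leave the support unbounded above, so no reflection);
* for posteriors, a multiplier move on the strict-clock rate.

Defaults: `n_iter` 2×10⁶ sweeps, 25% burn-in, thinning 100. Step widths
are auto-tuned towards acceptance 0.2–0.5 during burn-in only, so the
post-burn-in kernel is fixed and detailed balance holds where it matters.
Effective sample sizes (initial positive-sequence estimator) are reported
per node and flagged below 200. Chains are reproducible from a single seed.

The likelihood engine is strict-clock JC69 via Felsenstein pruning over
compressed site patterns (C++), with branch expected substitutions
$r \times$ duration. The rate prior is gamma with shape 2; when no mean is
given it is set so the expected root-to-tip divergence at the root
calibration midpoint is 0.1 substitutions/site — a weak, documented
default. The package's core sanity law, asserted in the tests: with a
zero-site alignment the posterior equals the prior.

## Diagnostics

Effective marginals are summarised by histograms (Freedman–Diaconis bins)
and empirical type-7 quantiles, *not* kernel density estimates: hard minima
create genuine density discontinuities that a KDE would smear. "95% prior
interval" means equal-tail (2.5%, 97.5%); highest-density intervals are
available by flag where relevant. Total-variation distances are computed on
a shared 512-bin grid spanning the union of supports, with specified-prior
mass outside the grid counted as discrepancy. Diagnostics are pure
functions of stored samples: re-running a report on saved draws is
bit-stable.

## Cross-validation of calibrations

Each round dates the tree with only the focal calibration — a uniform with
hard minimum and soft maximum — plus a diffuse uniform at the root carrying
the root's soft maximum (the root minimum is *not* imposed during rounds:
only the maximum limit is, mirroring standard practice and leaving the
round free to drift young). Engines: live prior-only MCMC, live posterior
MCMC on an alignment, or a stub table of externally computed means — the
stub path decouples statistic correctness from sampler stochasticity and
lets users bring summaries from other programs.

Statistics use posterior *mean* ages (medians by flag). Sign conventions
are explicit: minimum-only deviations are estimate − minimum (positive =
estimate predates the minimum); min–max deviations are zero inside the
interval, estimate − maximum above it, estimate − minimum below it. (The
published description of the min–max variant prints a "slightly negative"
range without its sign; the convention here is stated to remove that
ambiguity.)

`sequential_removal()` recomputes every round's SS restricted to the
surviving set at each step and traces $s = \Sigma SS / (n(n-1))$ with the
percent changes of numerator and denominator, exposing the counter-intuitive
regime where removing the worst calibration *raises* $s$. The "is this
change significant?" question has no canonical answer in the consistency
literature; this package attaches a nonparametric bootstrap interval
(default 10⁴ resamples of the per-round SS values at each step) to each
$\Delta s$ and reports the trace regardless — a transparent,
assumption-light heuristic, clearly labelled as this package's own.

## Synthetic data: what it emulates, and not

`simulate_bd_tree()` is a forward birth–death simulation from two lineages,
rejected on extinction, with the present placed an $\mathrm{Exp}(n(\lambda +
\mu))$ waiting time after the first passage to $n$ extant lineages and
extinct subtrees pruned. For the pure-birth case the root age is exactly
$\sum_{k=2}^{n}\mathrm{Exp}(k\lambda)$, giving the closed-form oracle
$E[t_\mathrm{root}] = (H_n - 1)/\lambda$ used in the tests. The
first-passage convention (rather than uniform sampling over the tree's
lifetime) was chosen precisely because it admits that exact oracle; for
$\mu > 0$ it is one of several defensible conditioning conventions and is
documented as such.

`generate_calibrations()` draws fossil gaps exponentially (memoryless,
one-parameter; rate `gap_rate` per Ma): minima are true age − gap (redrawn
until positive), maxima true age + a gap with mean inflated by `inflation`.
The root's maximum gap is kept tight (rate `gap_rate`), emulating the
informative root maxima that practitioners choose deliberately — an
uninformative root maximum lets prior-only rounds drift unboundedly old and
masks every other effect. Two deliberate-violation modes exist for probing
consistency assessment: `mislead` gives one node a minimum *older* than its
true age (the signature of a phylogenetically misplaced calibration
fossil), and `young_nodes` give selected nodes much larger minimum gaps.
Generated sets always bracket the truth except at `mislead`, and
regeneration from (parameters, seed) is bit-identical.

What the synthetic data do **not** emulate: rate variation across lineages
(the engine is strict-clock, so clock-model misspecification is outside
scope), substitution-model complexity beyond JC69, non-contemporaneous
tips, and stratigraphic structure in the fossil record (gaps are
memoryless). Passing tests therefore demonstrate the behaviour of the
*prior machinery* and of the consistency statistics under controlled
conditions — not that any particular empirical timescale is right.

### Study conditions used by the test suite

The simulation experiments in the test suite fix their conditions as
follows (sizes chosen as routine desk-scale analyses):

* coverage/recovery: 50 studies, 8 tips, pure-birth $\lambda = 0.012$/Ma
  (mean root age ≈ 140 Ma), rate 2×10⁻³ subs/site/Ma, 2000 sites, gaps with
  mean 10 Ma and `inflation` 2, 75% of nodes calibrated; 2×10⁴ sweeps per
  posterior;
* consistency inversion: 20 studies, 8 tips, gaps with mean 20 Ma
  (`gap_rate` 0.05, `inflation` 4), all nodes calibrated min–max, one
  misleadingly old minimum at a deep node, prior-only rounds. The
  misleading constraint is what makes minimum-only and minimum–maximum
  scoring disagree systematically: rounds that estimate young sit closest
  to the (gappy) minima yet cross below the erroneous old minimum, while
  old-estimating rounds stay inside everyone's windows;
* the truncated-Cauchy grid runs 10⁵ stored draws per cell on the 23-tip
  turtle fixture.

## The turtle fixture

The packaged fixture encodes one representative tip per calibrated clade of
crown turtles (23 tips, 22 labelled internal nodes) and a calibration table
with two eras: the earlier constraints used by consistency-based
assessments (`"posteriori"`) and the revised, evidence-vetted set
(`"priori"`, root 155.6–251.4 Ma). Fixture node ages are assigned by
recursive top-down midpoint placement: each node sits at the midpoint of
its minimum and the smaller of its maximum and its parent's age — a
deterministic chronogram consistent with all bounds, sufficient for every
prior-level experiment (no claim of being an estimate). Notes carried with
the fixture: the source table's root maximum appears once elsewhere as
251.5 Ma (the fixture follows the table value 251.4); the earlier era lacks
a root maximum, so sampling runs built from it attach the informative
251.4 Ma bound, flagged in a `note` column; one min-only row
(Lindholmemydidae) has no attachable node and is carried with
`attached = FALSE`.

## Numerical choices

* Ages in Ma, tips at exactly 0; strict ordering enforced with tolerance
  10⁻⁹ Ma — ties are rejected because zero-length branches break density
  evaluation and likelihood scaling.
* Polytomies are rejected at parse; the move kernels assume binary trees.
* Quantiles are type-7 throughout; removal-order ties break by node label
  order, making traces deterministic.
* The C++ density code returns −∞ (zero mass) rather than throwing for
  order-invalid states; configuration errors (unbounded root, duplicate or
  infeasible calibrations, unknown labels) are R-level errors raised before
  sampling starts.
* Initial states are built bottom-up from calibration minima, then placed
  top-down inside each feasible window; the chain errors out if no such
  state exists.

## Known limitations

* The conditional construction approximates sequential conditioning (see
  above); both constructions share one truncation mechanism, which is the
  object of study, but neither claims to replicate any external program's
  exact joint prior.
* The strict-clock JC69 engine is intentionally minimal; posterior
  experiments speak to prior-driven effects, not to realistic sequence
  modelling.
* Birth–death conditioning on tip count uses the first-passage convention;
  quantitative root-age distributions for $\mu > 0$ depend on that choice.
* The bootstrap on removal traces is a heuristic for flagging unstable
  steps, not a calibrated hypothesis test.
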
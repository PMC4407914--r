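---
title: "Models and methods in radburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in radburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

radburst tests early-burst predictions of adaptive-radiation theory on
time-calibrated phylogenies: did lineages and phenotypes diversify fastest
near the base of a radiation? The package provides the full simulation and
inference chain — conditioned tree simulation, staged trait simulation,
disparity-through-time analysis, BM/OU model comparison, diversification
rate-shift detection, and per-interval rate estimation — so that observed
patterns can be compared against explicitly stated null worlds. This
vignette records the models, the numerical choices, and the design decisions
that were genuinely open.

## Time conventions

Internally every node carries an age measured forward from the root
(root = 0, tips = crown age). All user-facing tables that report times use
ages before present (tips = 0), converted at the boundary. A tree is
treated as ultrametric when its root-to-tip distances agree to a relative
`1e-9`; stages that require a chronogram reject anything else.

## Tree simulation and conditioning

`sim_bd_tree()` is a Gillespie simulation from the two crown lineages:
waiting times are exponential with total rate $n(\lambda+\mu)$, events are
speciations with probability $\lambda/(\lambda+\mu)$, and extinct lineages
are pruned afterwards. If either crown lineage dies out entirely, the
realized most-recent-common-ancestor age would no longer equal the nominal
crown age, so the replicate is reported as extinct (`NULL`) rather than
silently re-rooted.

`sim_conditioned_tree()` conditions on both a crown age and an exact extant
richness by rejection, re-drawing the speciation rate each attempt when a
uniform range is given. For pure-birth attempts the rejection predicate
(tip count at the crown age) depends only on the event times, so the
simulator draws those first and assembles the topology only for the
accepted attempt; the accepted tree's distribution is identical to building
every attempt in full, and the count phase stops early once the target
richness is exceeded. Acceptance rates were checked against the closed-form
crown tip-count law $P(N=n) = (n-1)p^2(1-p)^{n-2}$ with $p = e^{-\lambda T}$.
`max_attempts` (default $10^6$) failing raises an error rather than
relaxing the condition.

Incomplete sampling (`sample_tips()`) supports uniform random sampling,
diversified sampling (one tip from each subtree below the $k-1$ oldest
nodes), and a "semidiversified" scheme that anchors only the
$\lfloor fk \rfloor$ oldest nodes (default $f = 0.5$) and fills the
remaining slots at random. The exact published definition of the
semidiversified scheme was not available when this package was written; the
implemented rule is a declared stand-in, and $f$ is exposed so users can
move between fully random ($f \to 0$) and fully diversified behaviour.
Ties in node age are broken by node index, deterministically.

## Trait simulation

`sim_trait()` evolves a single continuous trait by the exact
Ornstein-Uhlenbeck transition: over a segment of duration $\Delta$ with
diffusion rate $s^2$,
$$x' \sim N\!\left(x e^{-\alpha\Delta} + \theta(1 - e^{-\alpha\Delta}),\;
  s^2 \frac{1 - e^{-2\alpha\Delta}}{2\alpha}\right),$$
with the Brownian limit (mean $x$, variance $s^2\Delta$) taken analytically
below $\alpha = 10^{-12}$ to avoid catastrophic cancellation. Stages of a
radiation are modelled as rate windows: inside a window the diffusion rate
$\sigma^2$ is multiplied (10-fold by default) while $\alpha$ is untouched —
"rate of trait evolution" is read as the diffusion rate, since the
constraint parameter is the quantity being contrasted with it. Windows are
given in root-forward ages; `stage_windows()` maps the named stages onto
thirds of the crown age, so on a 15-myr tree "early" is the first 5 myr
after the root. One standard-normal draw is consumed per branch segment in
cladewise (preorder) edge order, making runs bit-reproducible given a seed;
the $\alpha = 0$ path is draw-for-draw identical to a plain Brownian
recursion, which the tests exploit as an oracle.

## Disparity through time and the MDI

Disparity is the average squared pairwise Euclidean distance among trait
values, computed in $O(n)$ from sums and sums of squares. The DTT curve
evaluates, at each internal-node age (simultaneous divergences merged
within relative `1e-9`), the mean over all lineages crossing just before
that time of their descendant-tip disparity divided by the whole-clade
disparity; the curve starts at 1 at the root, and single-tip lineages
contribute 0. Curves are right-continuous step functions, and the
morphological disparity index (MDI) is the exact step-function area between
the observed curve and the null median over the first 90% of relative time
(`t_max = 0.9`, discarding the tip-overdispersion zone). No trapezoids are
used anywhere, so there is no interpolation ambiguity.

Null envelopes (`dtt_null()`) simulate trait sets on the same tree under a
Brownian or OU null, by default with parameters fitted to the observed
data by maximum likelihood ("fitted" picks the AICc-better of the two);
quantiles are pointwise type-7 at 5% and 95%. Relative disparity is
scale-free, so a Brownian null curve does not depend on $\sigma^2$ at all —
fitting matters only when the null is OU. For the same reason the MDI is
exactly invariant under affine transformation of the trait.

`run_stage_experiment()` wires these together: conditioned trees (default:
100 tips, 15-myr crown, $\lambda \sim U(0.1, 0.4)$, the classic design),
traits under every combination of $\alpha \in \{0, 0.1, 0.3\}$ and stage,
and MDI against a 100-replicate Brownian null per tree. One null median per
tree serves all conditions (scale freedom again), which is what makes 200
trees across 12 conditions run in well under a minute. The expected
pattern — early bursts depress MDI, late bursts raise it, and constraint
($\alpha > 0$) shifts everything upward until the early-burst signature
disappears — is asserted by the acceptance tests with Wilcoxon comparisons.

## BM and OU likelihoods and fitting

Both models are Gaussian on the tips. Brownian motion has covariance
$\sigma^2 s_{ij}$ (shared root path length); the root-at-optimum OU model
($\theta = z_0$, matching the standard single-optimum fitting default) has
$$V_{ij} = \frac{\sigma^2}{2\alpha}\left(1 - e^{-2\alpha s_{ij}}\right)
  e^{-\alpha(d_i + d_j - 2 s_{ij})}.$$
Two independent evaluation routes are maintained: a dense
covariance-plus-Cholesky route, and an $O(n)$ Felsenstein pruning route.
For ultrametric trees the OU covariance equals a Brownian covariance on a
tree with node heights rescaled as
$h' = (e^{-2\alpha(T-h)} - e^{-2\alpha T})/(2\alpha)$, so the pruning route
serves OU too; below $\alpha = 10^{-9}$ the BM covariance is used directly.
The two routes agree to $10^{-8}$ on trees up to 200 tips (asserted), and
the dense OU covariance is additionally checked against an explicit
root-path construction on small trees.

Fitting profiles the likelihood: given $\alpha$, the GLS root state and the
ML $\sigma^2$ have closed forms from the pruning pass, leaving a
one-dimensional bounded quasi-Newton search over $\log\alpha$ from five
log-spaced starts in $[10^{-8}, 10]$. $\alpha = 0$ (exactly the BM
likelihood) is always a candidate, so the fitted OU log-likelihood can
never fall below BM — the nesting holds by construction rather than by
numerical luck. AICc uses $k = 2$ (BM) or $k = 3$ (OU) with
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$. `compare_over_trees()`
reports medians across a tree sample (medians blunt outlier estimates from
individual posterior trees) and the number of trees preferring each model.

## Diversification-rate shifts on diversity trees

A diversity tree carries an extant richness count on every tip; tips with
richness above 1 are terminally unresolved clades. Each rate regime is
parameterized by net diversification $r = \lambda - \mu$ and turnover
$\varepsilon = \mu/\lambda$, with
$\beta(t) = (e^{rt} - 1)/(e^{rt} - \varepsilon)$ evaluated through `expm1`
so the $r \to 0$ limit $\beta = \lambda t/(1 + \lambda t)$ is reached
continuously. The likelihood decomposes per branch: a branch from age $b$
to age $e$ ending in an observed node contributes the probability that
exactly one descendant chain retains present-day survivors (all side
shoots extinct) times $\lambda$ for the branching event, and each tip
contributes the unconditioned Kendall richness law
$(1-\varepsilon\beta)(1-\beta)\beta^{n-1}$ at its stem age. This
decomposition was validated against brute-force birth-death simulation
(branch propagator and tip terms separately), recovers the Yule estimate
$\hat r = B/L$ exactly under pure birth, and recovers $(r, \varepsilon)$
within a few percent on simulated 200-tip birth-death trees. Each regime
treats its rates as if they applied to the present — the standard
approximation of stepwise shift detection.

Survival conditioning (dividing by the crown lineages' survival
probabilities) is available but off by default: the division factor grows
without bound as $\varepsilon \to 1$, and once a shift strips the tips away
from a regime piece nothing in that piece's own data can pay for it, so
conditioning makes the turnover of tip-free pieces unidentifiable at the
boundary and spawns spurious single-tip shifts. With the unconditioned
joint density the synthetic fixture yields exactly one retained shift, at
the focal clade's crown.

The stepwise search fits the one-regime model, then greedily tries every
branch as a shift point (stem placement: the shift applies from the
branch's parent node tipward), keeping the AICc-best candidate while any
candidate improves the AICc, up to 15 shifts. Each shift adds three
parameters ($r$, $\varepsilon$, location); the AICc sample size is the
number of internal nodes plus the number of richness-bearing tips.
Candidate ties break by the earliest child-node index. Retention by bare
AICc improvement is deliberately liberal; the false-positive calibration in
the tests reports the observed homogeneous-tree shift frequency rather
than hiding it. Turnover is box-bounded to $[0, 0.999]$ — implementations
that allow unbounded excursions can report negative turnover; here boundary
hits are flagged in the output instead.

## Per-interval Kendall-Moran rates

For an interval $(y, o]$ in ages before present, the rate is $B/L$: $B$
counts branching events strictly inside the interval (boundary events go to
the older interval; the root is the conditioning event and is never
counted) and $L$ sums every branch's overlap with the interval. These
conventions make partition sums exact: over any partition of the tree's age
range the $B$ add to the non-root internal node count and the $L$ to the
total tree length, which the tests assert to $10^{-9}$. The five bundled
stage boundaries (Tortonian through Pleistocene) are the standard
geological values. "Floating" per-stage estimation is interpreted as
fixed named stages; a sliding window can be emulated by passing a custom
interval table. `km_rate_envelope()` compares empirical rates with
quantiles from conditioned, optionally trimmed, simulated trees. Note that
the per-tree ratio $B/L$ is slightly biased upward as an estimator of
$\lambda$ (a ratio of correlated sums); $E[B] = \lambda E[L]$ holds
exactly, so the pooled estimator $\sum B/\sum L$ is the consistent one and
is what the calibration tests check.

## The synthetic fixture

`make_fixture()` builds a data set with the statistical signatures the
pipeline is meant to detect, not a reconstruction of any real clade: 49
tips, 13.4-myr crown; three successively diverging species-poor outgroup
lineages (a pectinate spine at 100%, 92% and 86% of the crown age); a
focal clade holding 122 of 132 species; and a very young (1.2-myr crown,
3.5-myr stem) species-rich subclade nested inside it, mimicking a
glacial-cycle diversity pump. Five traits are simulated with
literature-scale parameters: two body-shape axes (one effectively Brownian
with $\sigma^2 = 3.47$, one strongly constrained OU with $\alpha = 0.30$,
$\sigma^2 = 39.05$), log body size (OU, $\alpha = 0.11$), buoyancy (BM,
$\sigma^2 = 0.23$) and habitat temperature (OU, $\alpha = 0.25$), the last
truncated below at -1.86 °C — the freezing point of sea water — with one
recently diverged focal species set to a warm 7.64 °C to mimic a
secondarily temperate lineage. The outlier sits on the shortest pendant
branch on purpose: a huge trait contrast across a very recent divergence is
what drives strongly positive late disparity, and removing that species
lowers the temperature MDI, which the tests assert as a direction. The
fixture is byte-identical given its seed.

What a green test on fixtures does not establish: the fixture's clade
plan is one draw of a stylized topology, its traits are univariate and
uncorrelated, and its richness allocation is deterministic — none of which
real data guarantee. The tests therefore check directions, calibrations
and exact bookkeeping, not agreement with any empirical estimate.

## Known limitations

- Single-optimum, root-at-optimum OU only; no early-burst (ACDC),
  white-noise or multi-optimum models, and no multivariate correlated
  traits.
- Shift regimes are rate-constant; no time-varying rates within a regime
  and no Bayesian (reversible-jump) shift inference.
- The per-regime likelihood ignores that survival probabilities should
  integrate across regime boundaries (as stepwise AICc methods generally
  do).
- The semidiversified sampling rule is a documented approximation.
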
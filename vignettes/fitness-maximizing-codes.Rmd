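---
title: "Fitness-maximizing efficient codes: models, optimizers and synthetic experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness-maximizing efficient codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fitmax)
```

# The scientific problem

Classical efficient-coding theory holds that sensory systems should allocate
their limited signalling resources to transmit as much information about the
world as possible (infomax). This package implements the competing,
fitness-based view: a code should minimize the *consequences* of sensory
errors in the currency that matters to the organism — forfeited reward — not
the errors themselves. For a one-dimensional stimulus with prior density
$f(s)$, the two objectives give different optimal codes, and the package
provides the machinery to derive, simulate, fit and stress-test both.

The running example is edge orientation. Natural scenes over-represent
cardinal orientations, captured by the parametric prior

$$f(s) \propto \frac{1}{a - \cos 4s}, \qquad a > 1,$$

with peaks at 0 and 90 degrees (`orientation_prior()`, default $a = 1.85$).
The binary task asks which of two gratings is closer to diagonal, so the
decision-relevant axis is *diagonality* $d(s) = 45 - |45 - (s \bmod 90)|$,
and two payoff contexts are studied: a fixed payoff per correct choice
(accuracy context) and a payoff linear in the chosen stimulus's diagonality
(reward context).

# Escort codes and the exponent algebra

Candidate response functions are cumulative *escort* transforms of the
prior, $h_\gamma(s) \propto \int^s f^\gamma$. Three classical results tie
the pieces together:

* minimizing the probability of an erroneous binary choice over quantized
  response functions gives $\gamma = 1$ (the prior CDF — infomax);
* minimizing expected forfeited reward under a linear stimulus-reward map
  gives $\gamma = 2/3$;
* $\gamma = 1/(1+p)$ identifies each escort code with an $L_p$
  reconstruction penalty, so the reward-maximizing code corresponds to
  $p = 0.5$;
* under a capacity budget $\int J^\beta \le c$ with the conventional
  $\beta = 0.5$, Fisher information follows the power law
  $J(s) \propto f(s)^q$ with $q = \gamma/\beta$: $q = 2$ for accuracy,
  $q = 4/3$ for reward.

`optimize_escort_exponent()` recovers the first two results numerically by
scanning quantized escort codes (default 1024-point grids, a coarse
$\gamma$ grid at step 0.02 refined by golden-section search). The loss
functionals use the fair-coin tie convention: two stimuli falling in the
same response level are chosen between at random, contributing half the
error (or half the forfeited reward difference). Both functionals are
validated against pairwise Monte-Carlo simulation in the test suite.

```{r escort}
pr <- orientation_prior(domain = stimulus_domain(0, 180, TRUE, 1024))
rmap <- reward_map(stimulus_domain(0, 180, TRUE, 1024), "linear", 0, 1)
optimize_escort_exponent(pr, "accuracy", n = 20) # gamma* = 1.000
optimize_escort_exponent(pr, "reward", reward = rmap, n = 20) # gamma* = 0.662
```

# The Bayesian observer

Encoding is a Gaussian channel whose precision follows the power law,
$r \sim N(s, 1/(k f(s)^q))$; decoding is the posterior mean. In the
high-signal-to-noise regime the estimator has closed-form moments: a bias
proportional to $(1 - 1/q)\,\mathrm{d}/\mathrm{d}s\,[f^{-q}]$ and variance
$1/(k f^q)$ (Cramér–Rao treated as equality, the unknown constant absorbed
into $k$). The two-alternative choice probability is a probit in the
standardized mean difference with lapse $\lambda$ and side bias $\beta_0$
mixed in.

Two unit conventions matter and are deliberate:

* Stimuli, biases and variances are reported in degrees, but the density
  inside the power law is normalized per **radian**. On the diagonality
  axis this puts the cardinal peak above 1 and the oblique trough below 1,
  which is what produces the signature crossover: lowering $q$ at fixed
  $k$ *raises* variance at cardinals and *lowers* it at obliques. A
  per-degree normalization would scale variance monotonically in $q$
  everywhere and erase the pattern.
* The Gaussian channel is kept non-circular even though orientation wraps;
  discrimination noise is small relative to the domain, and the grid
  decoder (`decode_posterior_mean()`, 2048 points) shows the closed forms
  hold to within Monte-Carlo error at the capacities used here.

`estimate_moments()` is checked against the grid decoder at nine
orientations for $q \in \{1, 4/3, 2\}$; `simulate_estimation_report()` adds
independent motor noise (default sd 2 degrees) for realistic synthetic
estimation data — the decision model never includes it.

# Numerical resource allocation

For arbitrary priors and reward maps, `optimize_allocation()` searches
allocation shapes $\tilde f$ (normalized to unit mass) parameterized as the
exponential of a natural-cubic interpolant through 12 knots, under the
capacity budget $c = \int J^{\beta}$ with $\beta = 0.5$. The scale
$k$ is derived from the budget, so every iterate satisfies the
normalization exactly. The expected loss integrates, over i.i.d. stimulus
pairs, the probability of choosing the lower-reward alternative times its
cost (1 per error, or the forfeited difference). Numerical choices:

* The pair integral uses an adaptive band quadrature: an outer trapezoid
  over $s_1$ (with extra nodes inside a boundary layer of one
  discrimination sd at each edge) and an inner trapezoid over $s_2$ on a
  band of width twelve local discrimination sds around $s_1$ (plus a
  mirror band around $2\tau - s_1$ under a categorization threshold, and a
  coarse global grid when reaction-time costs make distant pairs matter).
  Reward ties on the diagonal take the fair-coin limit 0.5 so the error
  kernel's peak is integrated, not punched out.
* The decoded mean is taken equal to the true stimulus. The generic-prior
  bias correction is $O(1/k)$ and negligible at the default capacity, and
  feeding its derivative form to an optimizer lets it exploit the
  high-SNR approximation outside its validity (a steep $1/\tilde f$ fakes
  mean separation).
* The default capacity ($c = \sqrt{2\times 10^5}$ on the unit domain,
  i.e. discrimination sd around 0.2% of the domain) puts the optimizer
  deep in the low-noise limit. At moderate capacity the finite-capacity
  optimum genuinely dips near the domain edges within a boundary layer of
  one discrimination sd — only deep in the low-noise limit does the
  numerical optimum match the asymptotic closed forms $f^2$ and $f^{4/3}$
  at the few-percent level.
* Optimization is BFGS with numerical gradients from multiple starts
  (flat, power-law-shaped, and seeded random); the objective alone picks
  the winner. Threshold search alternates golden-section updates of
  $\tau$ with allocation updates.

Scenario 3 (`scenario_setup(3)`) uses a raised-cosine reward peaking at
0.5 on a right-skewed truncated-exponential prior; the joint optimum puts
$\tau$ at 0.500 and the allocation shows the characteristic dip near
$\tau$, where mistakes are cheap because the reward map is locally flat
and symmetric.

# Reaction-time costs

With a constant-bound drift-diffusion decision stage (unit diffusion
noise), error probability and mean decision time have closed forms in the
evidence $z$ = standardized mean difference: a logistic error curve
$1/(1 + e^{2bz})$ and $E[RT] = (b/z)\tanh(bz)$. `rt_loss()` adds
$\eta \cdot E[RT]$ to the pair loss (logistic replacing the probit, as is
exact for the DDM), and `optimize_allocation_rt()` alternates allocation
updates with a one-dimensional bound search. The closed forms are verified
against Euler–Maruyama path simulation with the standard
$0.5826\sigma\sqrt{dt}$ continuity correction for discretely monitored
bounds. The RT module uses a moderate default capacity
($c = \sqrt{5000}$) so the bound-evidence tradeoff is not degenerate:
optimal bounds shrink as the time cost grows in both payoff contexts.

# Synthetic experiments

`simulate_decision_session()` reproduces the structure of the human
decision task: reference orientations drawn from the natural prior, a
comparison offset by the current staircase separation in diagonality
(random direction, realized in the reference's quadrant), choices from the
observer's probit rule, payoffs of 15 CHF per correct response (accuracy
context) or 1-46 CHF linear in chosen diagonality (reward context). The
staircase is a weighted up-down rule: the separation grows by one step
after an error and shrinks by a third of a step after a correct response,
whose stationary point is 75% accuracy (start 10, floor 0.5, ceiling 30
degrees — the rule's family and target are the design's, the step sizes
ours). With the capacity calibrated so a 10-degree separation is
discriminated at 90% (`calibrate_k()`), 30 simulated subjects hold a
median accuracy near 76%.

`simulate_estimation_session()` generates estimation reports (uniform true
orientations, locations cycled evenly, per-location observers so training
effects can be confined to trained locations), and the analysis helpers
apply the published filters: discard trials with absolute error above
22.5 degrees (a quarter of the maximal 90-degree error; the boundary is
kept, fixed for determinism), then summarize bias and variance in five
9-degree diagonality bins with after-minus-before change scores.

What the generators deliberately do not emulate: actual Gabor rendering
for human display, eye movements, intertrial timing, payment schemes
(per-trial payoffs are recorded; how they convert to a final payment is
the caller's concern), and any learning dynamics — adaptation enters only
as different observer parameters before and after training. Passing tests
on these generators therefore show that the *inference machinery* behaves
as designed under the model's own assumptions, not that the model is true
of human data.

# Hierarchical fitting

`fit_hierarchical()` estimates subject-level $(q, k, \lambda, \beta_0)$
from binary choices with group-level Gaussian pooling on transformed
scales ($\log q$, $\log k$, logit $\lambda$, identity $\beta_0$) —
positivity and boundedness force the links; the hyperpriors are flat
(wide) with one qualification below. The sampler is adaptive
Metropolis-within-Gibbs, built for the strong $\log q$–$\log k$
likelihood ridge (a higher exponent is compensated by a higher capacity):

* componentwise random-walk updates, all subjects scored in one
  vectorized cohort likelihood;
* an adaptive-Metropolis block move per subject using the learned 4x4
  chain covariance (which discovers the ridge orientation);
* collective moves that rigidly translate every subject plus the group
  mean along one coordinate or along a fixed cohort-level ridge
  direction — with tight pooling no individual move can shift the
  cohort-level mode, so these are what make the group posterior mix;
* conjugate draws for the group means and variances.

The transformed scales are bounded to a wide box (e.g. logit
$\lambda \in [-7, 2]$): the lapse direction is likelihood-flat in its
lower tail and a genuinely unbounded flat prior lets chains drift
indefinitely there. Proposal scales adapt during burn-in only. The default
schedule matches the production one (3 chains, 20,000 burn-in, 5,000
draws, thin 5 — 3,000 retained); tests run a reduced schedule
(hundreds of iterations), which the recovery checks show is sufficient
for group-level coverage at the cohort sizes used (25 subjects, 400
trials). `gelman_rubin()` implements the classic potential scale
reduction factor (non-split, non-rank-normalized — the variant is chosen
so that identical chains give exactly 1), cross-checked against the coda
reference; `map_grid_fit()` provides a brute-force likelihood-grid oracle
for the sampler, and `posterior_prob()` the two-sided posterior tail
probability used for contrasts such as the early-to-late drop in $q$.
Whether lapse and bias are subject-level or shared is not dictated by the
design; they are subject-level with group pooling here.

# The capacity-constrained network

`train_vib()` trains a small stochastic-encoder network on rendered
orientation patches: shared conv layer (4x4 kernels, stride 2, 4
filters), a Gaussian latent of dimension 4 with diagonal covariance
(diagonal for desk-scale stability; the head widths are configurable), a
width-20 downstream layer, and a sigmoidal decision unit, trained by Adam
on `E[reward loss] + beta * I` where `I` is the KL of the encoder
posterior from a standard-normal latent prior and the reward loss is the
expected misclassification, weighted in the reward context by the
diagonality difference at stake. Forward, backward and the optimizer are
implemented directly with BLAS matrix operations (no deep-learning
runtime is involved); the gradients are verified against finite
differences in the tests.

Design choices that matter:

* Images default to 16x16 pixels, 2 cycles, envelope sd 0.3 of the image
  (random phase, so many images map to one angle). This is the smallest
  rendering at which the task is comfortably learnable, and it keeps a
  full multi-seed experiment within desk-scale compute; the size is a
  `gabor_spec()` parameter.
* Training pairs are drawn i.i.d. from the orientation prior. This is the
  product pair density of the normative objectives, and it is essential:
  with staircase-style pairs the separation is independent of stimulus
  location, the reward weight then carries no location information, and
  the two contexts provably collapse onto the same objective (we verified
  the collapse empirically before settling on i.i.d. pairs). The reward
  weight is normalized to unit mean over the training pool so the two
  contexts face comparable loss scales — `beta` is defined only up to
  that scale.
* The encoder Fisher information over diagonality (`fisher_curve()`)
  follows the mean latent's derivative after rescaling each latent
  dimension to unit noise variance (encoder variance plus render-to-render
  variability), with central differences on the half-degree grid and a
  5-point moving average. Curves are compared between contexts after
  normalizing to unit mean: the pixel lattice itself carries an
  orientation anisotropy that shifts whole curves between seeds, and the
  context signature is a reallocation, not a change of total information.
* Context comparisons and the freeze-and-retrain transfer experiment are
  gated on matched discrimination accuracy (training stops inside an
  accuracy band, checked on a held-out stream every 100 steps). The
  transfer experiment additionally reports the reward at stake per unit
  error, an accuracy-robust statistic of where an encoder lets errors
  happen. Signatures emerge in the regime where the bottleneck binds
  (held-out accuracy in the 80-90% band); near-ceiling networks look
  alike.

# Problem sizes

The test suite and the acceptance script use: 1024-point grids for the
escort optimizations (20 and 40 levels); 12-knot allocations with the
capacities above; 3,000-5,000 decode draws per Monte-Carlo moment check;
30 subjects x 400 trials for the staircase calibration; 10 cohorts of 25
subjects x 400 trials (3 chains x 400 + 400 iterations) for recovery;
12 subjects x 400 estimation trials per phase for the location-transfer
pattern; and, for the network experiments, 5 seeds x 2 contexts plus a
2-seed transfer study at up to 8,000 Adam steps with 100 renders per
half-degree angle step for Fisher curves. These sizes are the package's
standing choices and are what the reported numbers mean.

# Known limitations

* All theory is for one-dimensional stimulus variables; no population or
  two-dimensional codes.
* The observer is the posterior-mean estimator with a Gaussian
  (non-circular) channel; other estimator families are out of scope.
* The DDM stage has constant bounds; collapsing-bound variants would
  change the reaction-time solutions.
* The allocation optimizer's closed-form agreement is an asymptotic
  (low-noise) statement; at moderate capacity real boundary layers appear
  at domain edges.
* The network experiment is a desk-scale surrogate: orderings and sign
  patterns are meaningful, absolute loss magnitudes are not.
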
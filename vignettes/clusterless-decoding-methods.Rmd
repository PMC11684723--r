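---
title: "Models and methods for clusterless decoding with markvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for clusterless decoding with markvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Extracellular recordings yield spike *events*: a time plus a waveform snippet.
Spike sorting assigns each event to a putative neuron before any downstream
analysis, but sorting is lossy — ambiguous ("hash") spikes are either discarded
or assigned with hard boundaries, and the assignment uncertainty never reaches
the decoder. Clusterless (unsorted) methods skip sorting: each spike keeps its
waveform feature vector $\kappa$ as a *mark*, and the population is modeled as
a marked point process whose joint mark intensity
$\lambda(x, \kappa)$ gives the expected rate of spikes with mark $\kappa$ when
the (possibly hidden) state is $x$. `markvae` implements a latent-variable
neural model of that intensity, a variational training objective tailored to
the point-process likelihood, a state-space wrapper for hidden dynamics, and a
Laplace decoder that reconstructs covariates from spikes alone.

# The intensity model

The joint mark intensity is factored as a positive base rate times a
probability density,

$$\lambda(x, \kappa) = \lambda_0 \int p(x \mid z)\, p(\kappa \mid z)\, p(z)\, dz,$$

where $z$ is a low-dimensional latent, $p(z) = N(0, I)$, and the two decoders
are Gaussians whose mean and diagonal precision are neural networks of $z$
(two tanh layers by default; precision through a softplus with floor
$10^{-4}$, so it is positive definite by construction). State and mark are
conditionally independent given $z$, which makes the ground intensity (the
mark marginal) available from the state decoder alone:
$\lambda(x) = \lambda_0 \int p(x \mid z) p(z)\, dz$. Diagonal precisions keep
every density evaluation cheap; this is a modeling choice, not a requirement
of the math.

Over an interval split into a grid of width $\Delta t$, the discretized
log-likelihood of events $\{(t_i, \kappa_i)\}$ is

$$\sum_i \log \lambda(x_i, \kappa_i) \;-\; \sum_j \lambda(x_j)\,\Delta t .$$

`markvae` keeps $\Delta t$ explicit (so $\lambda_0$ has units of a rate);
passing `dt = 1` absorbs it into $\lambda_0$, which only shifts the objective
by a constant.

# The bound

Both terms above involve intractable evidences. The per-spike term is bounded
*below* with the Rényi ($\alpha$-divergence) bound and the per-grid-point term
— which enters negatively — is bounded *above* with the $\chi$-divergence
bound, so the whole surrogate stays a lower bound:

$$
\sum_i \tfrac1\alpha \log \tfrac1L \sum_l \left(\tfrac{\lambda_0\, p(x_i,\kappa_i\mid z_{il})\, p(z_{il})}{q(z_{il}\mid x_i,\kappa_i)}\right)^{\!\alpha}
\;-\;
\sum_j \left(\tfrac1L \sum_l \left(\tfrac{\lambda_0\, p(x_j\mid z_{jl})\, p(z_{jl})}{q(z_{jl}\mid x_j)}\right)^{\!\beta}\right)^{\!1/\beta}.
$$

Two separate Gaussian-network encoders supply the proposals: $q(z \mid x,
\kappa)$ for spikes and $q(z \mid x)$ for the ground intensity. The
marginalization constraint linking the two optimal encoders is *not* enforced
— they are free networks, which simplifies estimation.

Knobs and defaults, all in `bound_config()`:

* `alpha` $\in (0, 1]$, default **0.5**. At $\alpha = 1$ the spike term is the
  importance-weighted bound (tightest); as $\alpha \to 0$ it approaches the
  classical ELBO. The mid-range default trades tightness against gradient
  variance; the admissible range is what matters and any value in it is valid.
* `beta` $> 1$, default **2**: at $\beta = 2$ the optimal encoder also
  minimizes the variance of the plain evidence estimate.
* `L`, default **10** (5 in the scaled study fixtures): Monte Carlo samples
  per evidence term.
* `use_jackknife`: leave-one-out debiasing applied to the $\chi$ term — the
  term whose $O(1/L)$ bias breaks the bound direction — trading bias for
  variance.
* `use_dreg`: doubly reparameterized spike-term gradients at $\alpha = 1$;
  the encoder gradient uses squared normalized weights with the encoder's
  density parameters detached, removing the high-variance score term.
* `chi_log_clamp`, default 50: the log-domain $\chi$ term is clamped before
  exponentiation so one bad early-training batch cannot produce an overflow.

All computations run in the log domain via log-sum-exp; log weights in
$[-700, 700]$ are safe. All-zero weight batches yield $-\infty$ spike terms
(treated as a diverged step by the trainers) and a zero $\chi$ term.

# State-space wrapper

When the state is hidden, `markvae` uses a black-box state-space model: a
linear-Gaussian chain prior $p(x_1)\prod p(x_r \mid x_{r-1})$ over a hidden
state (dimension 10 by default), a Gaussian-network observation model for the
covariate $y_r$, and the marked point process above for the per-bin spike sets
$\kappa_r$. The variational posterior is *structured*: chain factors plus, per
bin, one Gaussian expert from the covariate encoder, one expert per spike from
the mark encoder, and a constant base expert (the stand-in for the no-spike
exponential factor). The product is Gaussian with block-tridiagonal precision,
so factorization, solves, log-determinants and sampling all cost $O(R)$
(`block_tridiag()` and friends; no dense $Rd \times Rd$ matrix is ever formed).

The ELBO is estimated by reparameterized path samples: the posterior entropy
uses the exact block log-determinant, the chain and covariate terms are exact
Gaussian densities of the sampled paths, and the per-bin spike terms plug in
the bound above. Everything — including the block Cholesky — is
differentiated by the package's reverse-mode tape (`tape_new()` and the
`tp_*` ops), which is finite-difference-checked in the test suite.

Training choices (defaults in `fit_ssm()` / `fit_clusterless()`):

* transition matrices initialized to $0.99 I$, precisions to $I$, offsets to 0
  (slow, stable dynamics);
* SPD precisions parameterized by lower-Cholesky factors with softplus
  diagonals;
* long recordings are swept in contiguous segments (200 bins, one-bin overlap,
  the initial-distribution factors handling segment starts) with one Adam step
  per segment — the chain couples neighbors, so segments rather than shuffled
  minibatches;
* Adam with fresh reparameterization noise per step from a single seeded
  stream, early stopping on a fixed-noise validation ELBO;
* the covariate is standardized inside `fit_clusterless()` (undone at decode
  time), since tanh networks work best on unit-scale inputs;
* multiple probes are merged into a single event stream before fitting: one
  intensity model represents the union of populations.

# Decoding

Given spikes alone, the state posterior $p(x \mid \kappa)$ is approximated by
a Laplace fit at the MAP. The per-bin bound is not concave in $x_r$, so each
term is written as a concave outer function of the vector of frozen importance
weights ($\pi$ = the Rényi log-power-mean for spikes, $\rho$ = the negated
$\beta$-power mean for the ground term) composed with smooth inner maps, and
the inner maps are linearized at the expansion point (the Gauss–Newton
construction). The result matches the frozen bound in value and gradient at
the expansion point and is globally concave, so the Newton direction always
ascends and the final negative Hessian — chain precision plus per-bin
Gauss–Newton blocks — is a valid, positive-definite block-tridiagonal Laplace
precision.

Numerical policy in `newton_map()`:

* latent samples are redrawn at each outer re-expansion with *common random
  numbers* (one noise draw per term, fixed across iterations), which makes the
  frozen objective a deterministic function of the iterate;
* the full Newton step is backtracked (up to 10 halvings) against that frozen
  objective, so the recorded trace is non-decreasing by construction; a step
  that cannot improve it terminates the loop;
* initialization is the prior mean path; convergence at step infinity-norm
  `tol = 1e-6` (1e-4 in the high-level pipeline), `K_max = 50`;
* a non-positive-definite Hessian (which concavity should preclude) is
  jittered by up to $10^{-3} I$ and otherwise reported as non-converged;
* the printed composite forms freeze the encoder arguments at the expansion
  point; refreshing them at each re-expansion (as done here) keeps the
  approximation centered on the current iterate.

The covariate posterior follows by pushing Laplace path samples through the
observation network; the predictive variance combines the observation variance
with the across-sample variance of the means (law of total variance).
`decode_mse()` is the per-bin mean squared Euclidean error.

# Synthetic study conditions

The generator reproduces the study conditions used throughout the tests:

* hidden dynamics: Lorenz attractor ($\sigma = 10$, $\rho = 28$,
  $\gamma = 8/3$), RK4 fixed step $10^{-3}$ s, sampled at $\Delta t = 0.01$ s;
  the covariate is the full state (3D mode) or the first and third coordinates
  (2D mode, one generating coordinate unobserved);
* intensity: per probe, four components with
  $\lambda_l \exp(u_l(t)^\top x)$ tuning, where the direction $u_l(t)$
  interpolates linearly between two random directions over the recording — a
  simple model of tuning plasticity. As printed, the weight $t/T$ attaches to
  `c_dirs`, so the tuning equals `d_dirs` at $t = 0$; `swap_cd = TRUE` swaps
  the roles (both conventions appear in the literature, so the flag keeps the
  choice explicit);
* direction entries are drawn $N(0, 0.05^2)$ and component scales default to
  4, chosen so that (with the Lorenz state's $O(10\text{–}40)$ magnitude)
  peak-to-trough rate modulation is roughly 10–30× — comparable to place-field
  modulation depth — and the multiunit rate lands near 40–80 Hz per probe,
  typical of tetrode multiunit activity;
* marks: a synthetic affine decoder maps a 2-D component latent to a 32-sample
  waveform with a depolarization trough and repolarization hump (no real
  recording parameters are used — the shapes are constructed), plus Gaussian
  noise; the component mark marginal is therefore an exact Gaussian, used as
  the oracle in tests;
* simulation is exact Ogata thinning against a per-segment majorant (1.2× the
  grid maximum of the ground intensity, auto-inflating on violation), so the
  time-rescaling theorem applies exactly up to path interpolation;
* the full setting is $T = 100$ s, four probes; the scaled fixtures used by
  the acceptance checks are $T = 20$ s, one probe, with 80/10/10 contiguous
  train/validation/test splits in whole bins (remainder to training).

What passing tests on this generator do *not* show: real waveforms are not
Gaussian around a component mean, real populations drift in ways other than a
linear direction interpolation, spike collisions on dense probes violate the
independent-mark assumption, and real covariates (positions) are not Lorenz
paths. The generator exercises the machinery, not the biology.

# Baseline and comparisons

The Gaussian-mixture intensity
$\lambda(x, \kappa) = \sum_l \lambda_l N(x \mid \mu^x_l) N(\kappa \mid \mu^\kappa_l)$
(diagonal precisions) has exact likelihood, marginals and decoding objective —
the reference point when comparing against bound-based models, whose reported
NLL is an upper bound and is therefore at a *disadvantage* in such
comparisons. It is fitted by backtracking gradient ascent on the exact
discretized log-likelihood (k-means initialization; 16 components by default;
a closed-form rescale of the common rate factor each iteration, which is an
exact coordinate-ascent step), giving a monotone objective trace. For GMM
decoding, the intensity is defined directly on the covariate space and the
same concavified Newton machinery applies (the spike terms contribute
rank-one Gauss–Newton curvature; an AR(1) prior estimated from training
covariates supplies smoothness).

Model comparisons use paired two-sided Wilcoxon signed-rank tests on per-trial
scores with Holm–Šidák step-down correction
$p_{(i)} = \max_{j \le i}\, 1 - (1 - p_{(j)})^{m - j + 1}$, clipped at 1
(`wilcoxon_holm_sidak()`); significance at $p < 0.05$.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run everything at scaled-down
sizes chosen as the package's own fixtures: tractable-model bound checks with
$10^3$–$10^4$ replications, block-tridiagonal oracles up to $R = 30$, and one
end-to-end Lorenz trial at $T = 20$ s with hidden dimension 10, two-layer
32-unit networks, $L = 5$, around 40 training epochs, and a 2-second decoding
window. Every random quantity flows through explicit integer seeds (a local
RNG stream that never touches the global `.Random.seed`), so all reported
numbers are bit-reproducible given the seed.

# Known limitations

* Intensity values are Monte Carlo estimates, never deterministic; downstream
  uses must budget for that variance.
* Diagonal decoder/encoder precisions cannot represent correlated waveform
  noise within a snippet.
* The per-bin Bernoulli-style discretization ties the likelihood to the bin
  width; results are comparable only at a fixed $\Delta t$.
* Training the state-space model is non-convex; different seeds reach
  different local optima, which is why paired per-trial comparisons (not
  single runs) are the supported comparison method.
* The mark model has no history dependence, so near-coincident spikes on
  dense probes (waveform collisions) violate the model's assumptions.
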
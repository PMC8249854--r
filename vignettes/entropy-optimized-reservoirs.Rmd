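---
title: "Entropy-optimized reservoir computers for chaotic signal classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-optimized reservoir computers for chaotic signal classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoclass)
```

## The problem

A reservoir computer is a recurrent network whose internal weights are
random and fixed; only a linear readout is trained.  To use one as a
classifier, a readout coefficient vector $C_\alpha$ is fitted for each
signal class $\alpha$; a test signal is processed by the *same* network,
its own coefficient vector $K$ is fitted, and the signal is assigned to
$\arg\min_\alpha \lVert K - C_\alpha \rVert_2$.  Tuning the reservoir's
hyperparameters for classification is expensive because estimating the
error probability needs many test realizations (here, 100 per class, i.e.
400 reservoir simulations *per* candidate parameter value).  The
organizing claim of this package is that the hyperparameter that maximizes
the *entropy* of the reservoir response — computable from a single
realization of each signal — also minimizes the classification error, so
entropy can stand in for error during optimization at a fraction of the
cost (`optimize_entropy()` runs exactly 4 simulations per grid point,
independent of the number of test instances).

The signals to be classified are the $x$ components of the four Sprott
flows A–D, algebraically minimal three-dimensional chaotic systems that
are known to be the hardest of the catalogue to tell apart.  These flows
double as the package's synthetic-data generator: every test and
experiment builds its inputs by integrating them from seeded initial
conditions.

## Models

### Drive systems

`integrate_sprott()` integrates systems A–D with fixed-step RK4 (internal
step `dt_out/substeps`, default `dt_out/10`).  System D uses the original
catalogue form $\dot z = xz + 3y^2$: this is the system whose attractor
carries the catalogue's exponents (largest $0.103$, smallest
$-1.320$), which we reproduce; the sign-flipped variant that sometimes appears in
transcriptions has no bounded attractor near the origin (we verified that
all sampled initial conditions in $[-0.1,0.1]^3$ escape).

Initial conditions are drawn uniformly from $[-0.1,0.1]^3$ under a seed,
followed by a 10,000-sample transient.  System D's basin is interwoven
with escaping sets near the origin, so a drawn condition whose trajectory
diverges is rejected and redrawn deterministically (at most 20 attempts).
This makes seeded generation total: every seed yields a trajectory on the
attractor.  Explicitly supplied initial conditions are never rejected;
their divergence raises an error naming the step, guarded at
$|x| > 10^6$.

### Spiking nodes

Each of the $M = 100$ spiking nodes is a two-variable relaxation unit,
$$\dot u_i = T_C\,(-u_i^3 + u_i\, g(v_i,\phi_i)), \qquad
  \dot v_i = \frac{T_C}{R_\tau}\Big(W_i S_V - \gamma v_i +
  \textstyle\sum_j A_{ij} u_j\Big),$$
with $g = 0$ below the firing threshold $\phi_i \sim U[1, 1.1]$ and 1
above it (0 at exact equality), and the hybrid reset
$u_i > 0.5 \Rightarrow v_i = 0$.  The drive $S_V$ is the input signal
spike-encoded by `encode_spikes()`: the normalized signal value at the
read pointer sets the next inter-spike interval,
$\lfloor \tilde s\,(T_{max}-T_{min})\rfloor + T_{min}$ samples with
$T_{min} = 10$, $T_{max} = 100$.  Large amplitudes therefore produce *slow*
spiking.

Two points the defining equations leave open:

* **Initial state.** $u = 0$ is an invariant manifold ($\dot u \propto
  u$), so starting the fast variable at zero silences the network
  permanently.  `simulate_reservoir()` defaults to $u_0 = 0.1$,
  $v_0 = 0$; the zero state remains available explicitly and is tested as
  the equilibrium of the undriven network.
* **Integration.**  One output sample per drive sample (reservoir step 1),
  with 15 internal RK4 sub-steps by default: near the saturated state
  $u \approx 1$ the local rate is $-2 T_C = -30$, and the sub-step count
  must keep $2 T_C/\textrm{substeps}$ inside the RK4 stability region
  ($\lesssim 2.8$); at 10 sub-steps the saturated state shows a bounded
  numerical oscillation, at 15 it is stable.  The reset is applied
  after every internal sub-step so that $v$ cannot overshoot between
  output samples.  Sub-step counts are configurable; sweeps that push
  $T_C$ far above the operating point should raise them proportionally.

### Polynomial ODE nodes

The continuous-variable family is
$$\dot r_i = \alpha\Big(p_1 r_i + p_2 r_i^2 + p_3 r_i^3 +
  \textstyle\sum_j A_{ij} r_j + W_i s(t)\Big),$$
driven directly by the Sprott $x$ signal sampled at `dt_out = 0.1`.  The
cubic coefficients are free parameters of the family; we use
$p_2 = 1$, $p_3 = -1$, the odd-saturating choice that keeps the node's
response sigmoidal.  Both are configurable.

The polynomial family is integrated with RK4 at the literal unit step
(`substeps = 1`).  This is a deliberate modeling decision, not a
shortcut: with accurate integration the saturating cubic is bounded for
*every* $\alpha$, whereas the unit-step discretized system loses numerical
stability near the saturated state once $\alpha$ grows — at the operating
point's network realizations the blow-up appears around
$\alpha \approx 0.45$–$0.5$, giving the family a genuine instability
regime for $\alpha \ge 0.5$ while $\alpha = 0.3$ remains bounded.  The
discrete-time map, step included, *is* the reservoir computer here.

### Networks

`build_adjacency()` fills exactly `round(0.5 M²)` entries with
$U[-1,1]$ draws, zeroes the diagonal, adds the offset (0.5 for the spiking
family — without it the balanced excitation/inhibition cancels and nothing
spikes; 0 for the polynomial family), and rescales so the spectral radius
equals $\sigma$ exactly ($0.5$ spiking, $0.8$ polynomial).  Input weights
are $U[0,1]$ (spiking) or $U[-1,1]$ (polynomial).  One seed fixes the
whole network draw; sweeps hold the network seed fixed across the grid so
curves vary only through the swept parameter.

### Readout training

The design matrix stacks the post-transient node outputs (first 1,000
steps discarded) with a trailing column of ones.  `ridge_fit()` computes
the SVD $\Omega = U S V^T$ and shrinks each singular value to
$S_{ii}/(S_{ii}^2 + k^2)$ with $k = 10^{-5}$ — Tikhonov regularization in
singular-value form, used everywhere (never the bare pseudo-inverse).
Training errors: $\Delta_{RC} = \mathrm{std}(h - g)/\mathrm{std}(g)$ for
continuous targets, and $\Delta_{CC} = 1 - \rho$ (Pearson) for spike
targets.  (A cross-correlation normalized by plain sums of deviations
instead of root-sum-squares would be degenerate; the standard Pearson
form is what "cross-correlation" means here.)  Coefficient vectors keep
all $M + 1$
components (constant term included) both for storage and for the
Euclidean classification distance.

### Entropies

`joint_permutation_entropy()` divides each node's series into
*consecutive, non-overlapping* windows of `window_length = 4` samples (a
trailing partial window is dropped; a sliding mode exists for sensitivity
checks), replaces each window by its ordinal pattern (rank vector, ties
broken by time index), forms the tuple of all nodes' simultaneous
patterns, and returns the Shannon entropy of the observed tuple
distribution in nats.  Natural log is used for both entropies for unit
consistency.  The joint symbol space is astronomically large
($24^{100}$ for $M = 100$, $w = 4$) but the common drive confines the
response to a sparse set, held in a hash table.  How sparse depends on how
synchronously the nodes fire: strongly synchronized reservoirs occupy tens
of symbols, while the realizations explored here occupy up to a few
thousand of the $\sim 5{,}000$ windows — the entropy *comparisons* across
parameters, which are what the optimization uses, are unaffected by this
absolute scale.  One consequence of near-saturation is worth knowing: when
almost every window carries a unique joint symbol, the partitioned
estimator is count-limited, $H \approx \ln(N/w)$, which mechanically
*decreases* with window length.  The growth of entropy with window
length, a richness property, then only shows at a fixed window count —
the sliding mode — and that is how the window-length trend is checked for
the polynomial family in the test suite (the spiking family is far enough
from saturation to show the trend with the partitioned estimator
directly).

`nn_entropy()` treats the state sequence as a point cloud in $M$
dimensions, scales each coordinate by its standard deviation (per-node
scaling; the alternative single global scale differs only by a constant
offset $M \ln c$ in the mean log-distance), draws seeded index points
(default $\min(N, 1000)$), and returns
$\psi(N) - \psi(k) + \langle \ln \epsilon_n \rangle$ with $k = 10$, the
distance $\epsilon_n$ to the $k$-th nearest neighbor, self excluded.
Note the deliberately plain form: the textbook
Kozachenko–Leonenko estimator would multiply the log-distance term by the
dimension and add a unit-ball volume term, so values here differ from
that estimator by a monotone affine transformation — again immaterial for
locating a maximum.  Index points with zero $k$-th-neighbor distance
(duplicated states) are excluded from the mean with a warning; an all-zero
distance set is an error.

### Lyapunov spectra

`lyapunov_spectrum_sprott()` co-integrates the flow and three tangent
vectors with the analytic Jacobian evaluated at the RK4 stage states,
re-orthonormalizing by modified Gram–Schmidt every 10 steps and
accumulating log norms.  Exponents are averaged over the final half of
the run, and a convergence flag compares the two halves.  A pure-R
harness (`lyapunov_spectrum()`) accepts arbitrary derivative/Jacobian
functions and doubles as an independent cross-check of the compiled path
in the tests.

`largest_conditional_le()` evolves one tangent vector of the *driven*
reservoir (2M-dimensional spiking state, M-dimensional polynomial state)
along the trajectory.  The threshold nonlinearity is piecewise constant
(zero derivative), and by default the reset is treated as invisible to
the tangent flow.  The alternative — zeroing the tangent components of
reset variables (`reset_tangent = TRUE`) — adds the contraction of the
reset map itself and makes the exponent an order of magnitude more
negative ($\approx -5\times10^{-2}$ at the operating point versus
$-(T_C/R_\tau)\gamma \approx -1.7\times10^{-3}$).  Under the smooth-flow
convention the exponent tracks $-(T_C/R_\tau)\gamma$ — a
$10^{-4}$–$10^{-3}$ band over the damping sweep — cleanly separating the
slow-variable damping from the reset map's own contraction, which is why
it is the default.  Neither convention applies the full hybrid-systems saltation
correction for state-dependent event times.

## Experiment harness

`sweep_parameter()` rebuilds the reservoir at each grid value (fixed
network seed), trains via `reservoir_classifier()` (one seeded realization
per class; spiking targets are the spike train itself, polynomial targets
the raw signal), evaluates the error fraction over fresh seeded test
realizations, and records per-class permutation entropies, training
errors and the largest conditional exponent on the class-A training
drive.  Divergent grid points are flagged, not fatal.
`optimize_entropy()` runs one realization per class per grid point and
returns the argmax of the mean entropy (ties to the lower grid index).

Default problem sizes are those of the full experiment: 100,000-sample spiking
training signals (21,000 polynomial), test signals of 5,000 (spiking) and
2,000 (polynomial) samples, 100 test instances per class.  The package's
own test suite runs the same machinery at reduced scale — 20,000-sample
training signals, 20 test instances, a 6-point damping grid
$\{0.001, 0.004, 0.016, 0.064, 0.256, 1.0\}$ (log-spaced around the
operating point $\gamma = 0.004$) — chosen so the whole experiment is a
desk-scale computation while preserving the qualitative entropy/error
anti-correlation.  What the reduced scale *cannot* preserve is the
absolute error floor (about 0.1 at full scale) and fine confusion-matrix
structure such as class A's perfect identification: a 5× shorter training
signal leaves visibly noisier coefficient vectors, so those quantities
are only meaningful at full scale.

## What the generator does and does not emulate

The synthetic signals are the classification task itself — chaotic flows with
known Lyapunov structure, one realization per seed, instance variability
entirely from initial conditions.  They contain no observational noise,
no amplitude drift and no channel effects; passing tests therefore
demonstrate the method's behavior under clean, stationary chaotic drive,
not robustness to measurement noise.  Spike encoding is the only
amplitude-to-time conversion considered.

## Numerical choices

* Fixed-step RK4 everywhere, reproducible bit-for-bit given seeds; the
  variable-step routine of the original description is deliberately
  replaced (the flows are non-stiff at these steps).
* Divergence guard $10^6$ with the failing step reported.
* Ridge constant $k = 10^{-5}$; all fits via LAPACK SVD.
* Ties: ordinal patterns break ties by time index; classification breaks
  distance ties by the fixed class order A < B < C < D; entropy
  optimization breaks ties by the lower grid index.
* Derived RNG streams: every training class, test instance and retry
  draws from a deterministic sub-seed of the user seed, so whole
  experiments replay exactly.

## Limitations

* Exponents for the driven spiking reservoir depend on the reset
  convention (above); both conventions are available but only one can be
  reported at a time.
* The absolute permutation-entropy scale depends on reservoir synchrony;
  cross-parameter comparisons are meaningful, cross-implementation
  absolute values need not be.
* `p_2`, `p_3` and the reservoir initial state are gap-filling choices
  where the defining equations leave freedom; they are configurable
  and documented.
* Single network realization per experiment (seed recorded); averaging
  over network draws is left to the user.
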
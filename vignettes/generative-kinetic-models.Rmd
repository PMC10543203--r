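---
title: "Generative adversarial synthesis of kinetic metabolic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative adversarial synthesis of kinetic metabolic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
kinetic model and its assumptions, the saturation-sampling construction, the
eigenvalue relevance criterion, the conditional GAN and its training
diagnostics, transfer learning, the validation statistics, and the design
decisions taken where the design was genuinely open.

## The kinetic model

A `MetabolicNetwork` holds a stoichiometric network whose *internal*
metabolites become ODE states while *boundary* metabolites are clamped
constants. Mass balances are

$$\frac{dX_i}{dt} = \sum_j n_{ij}\, v_j(X; K_M, V_{max}, K_{eq}),$$

with $n_{ij}$ the stoichiometric coefficients. Every reaction uses
**convenience kinetics** — reversible Michaelis–Menten generalized to
arbitrary stoichiometry and Haldane-constrained by the equilibrium constant:

$$v = V_{max} \cdot \frac{\prod_s u_s^{a_s}\,\left(1 - \Gamma/K_{eq}\right)}
      {\prod_s \sum_{k=0}^{a_s} u_s^k + \prod_p \sum_{k=0}^{b_p} u_p^k - 1},
  \qquad u_m = \frac{X_m}{K_M^{m}},$$

where $\Gamma$ is the mass-action ratio. The denominator is positive for
positive concentrations, so the rate is zero exactly at equilibrium and
carries the sign of the thermodynamic drive $1 - \Gamma/K_{eq}$. Choosing
one mechanism family for all stoichiometries keeps the parameter inventory
predictable: one $K_M$ per (reaction, participating metabolite) pair and one
$V_{max}$ per reaction. Irreversible steps use $K_{eq} = \infty$ (no
back-pressure). Concentrations are mM, time is hours internally (minutes at
the interface), eigenvalues h⁻¹.

The Jacobian is assembled from analytic derivatives of the rate law — not
finite differences — and is validated against central finite differences to
below $10^{-6}$ relative error in the test suite. Integration uses lsoda
(deSolve) with relative tolerance $10^{-6}$ and absolute tolerance
$10^{-9}$; a trajectory is flagged diverged when a state becomes nonfinite
or exceeds $10^6$ times its reference value, or the integrator fails before
the horizon.

## Saturation sampling

Instead of sampling $K_M$ directly (unbounded, spanning decades), the
sampler draws the enzyme saturation

$$\sigma = \frac{X/K_M}{1 + X/K_M} \in (0,1), \qquad
  K_M = X\,\frac{1-\sigma}{\sigma},$$

uniformly on $(0.01,\, 0.99)$ — an uninformative prior over saturation
states, bounded away from the singular endpoints. The distribution is a
design choice of this package; uniformity is the natural uninformative
default and the bounds avoid infinite/zero $K_M$. With $K_M$ fixed the rate
is linear in $V_{max}$, so $V_{max} = v_{ref}/v(V_{max}{=}1)$ makes each
sampled model reproduce the reference flux *exactly* — an identity by
construction that the tests assert numerically (residuals at machine
precision, bounded at $10^{-6}$ times the largest flux). Regulatory and
inhibitory saturations are not sampled: the packaged mechanisms have none;
this is a documented limitation for networks with allosteric regulation.

## Biological relevance

A parameter set is *biologically relevant* when its linearized dynamics are
stable and fast enough for perturbations to settle before the next cell
division: all Jacobian eigenvalues at the reference state must satisfy

$$\mathrm{Re}(\lambda) < -\frac{60\,s}{T_d} \;\mathrm{h^{-1}},$$

with doubling time $T_d$ in minutes and speed factor $s = 3$ by default.
For a 21-min doubling time this gives $-60/7 \approx -8.57$, convention-
ally operationalized as the integer bound $-9$ (both are available; the
exact bound is the default for arbitrary doubling times). The inequality is
strict: a model exactly at the bound is irrelevant. The dominant time
constant of a stable model is $\tau = 60/|\max \mathrm{Re}(\lambda)|$
minutes — the slowest relaxation mode; oscillatory fine structure (complex
parts) is not treated specially beyond using real parts.

Preprocessing drops the $V_{max}$ columns (recomputable from $K_M$ and the
reference state), takes natural logs (the parameters span decades; the base
is a recorded constant, so results convert), and splits 9:1 into train and
test by a seeded shuffle without label stratification.

## The conditional GAN

The generator maps Gaussian latent noise (dimension 64 by default)
concatenated with a one-hot class label through dense layers of 128, 256
and 512 units — each with batch normalization, ReLU and dropout 0.5 — to a
linear output in ln-$K_M$ space; no feature scaling beyond the log
transform. The discriminator takes features plus the one-hot label through
32, 64 and 128 dense units with leaky-ReLU (slope 0.2) and dropout 0.5 to a
single logit. Both train with binary cross-entropy and Adam at learning
rate $2\times 10^{-4}$; we set $\beta_1 = 0.5$ (the common stabilizing
choice for adversarial training; configurable). Updates alternate 1:1 — one
discriminator step on a real batch plus an equal-sized generated batch, one
generator step against the frozen discriminator — with generated-batch
labels drawn from the empirical class frequencies. There is no label
smoothing or noise injection. The network engine (dense/batch-norm/dropout
layers with reverse-mode gradients and Adam) is implemented in the package
and its gradients are verified against finite differences in the tests.

Every 10 epochs the generator produces 300 relevant-conditioned sets, which
are labelled by the eigenvalue criterion, and the mean per-feature KL
divergence against the relevant training rows is recorded; the snapshot
with the highest incidence is kept as the best checkpoint. Training is
declared failed when discriminator accuracy stays above 90% for 200
consecutive epochs (the discriminator has overpowered the generator); on a
healthy run it hovers near 50%. A NaN loss aborts with the last good state.

Generated feature vectors are exponentiated back to $K_M$ and $V_{max}$ is
reattached from the reference fluxes, so generated models inherit the exact
steady state. Irrelevant populations are preferably harvested by
*rejection*: keep the irrelevant by-products of relevant-conditioned
generation, which retain the parameters that actually determine
instability; direct conditioning on the irrelevant label is also available.

## Transfer learning

To serve a second physiology (a different set of operating flux directions
with a consistent reference state), the trained generator is re-trained
inside a fresh adversarial game: generator weights start from the source's
best checkpoint (bit-identical before every repeat), the discriminator is
randomly re-initialized each repeat, and only a small target dataset is
used. Batch sizes follow the size map 10→2, 50→5, 100→10, 500→20, 1000→50
and the learning rate switches from $2\times10^{-4}$ to $10^{-3}$ at
$n \ge 500$; training runs 300 epochs by default. Target rows are used with
the labels they carry (no class-balance requirement — at $n = 10$ every
sample counts). Best-of-repeats incidence is reported, and
`transferGrid()` sweeps (source, target, size) cells, recording failures
without aborting the grid.

## Validation statistics

*KL divergence* is computed per feature on 50 equal-width bins spanning the
pooled range of the two samples, with $Q$ floored at $10^{-10}$ where $P$
has mass, and aggregated as the mean over features — a deliberate marginal
estimator: the multivariate pooling is a design choice recorded here.
*Spearman correlation* is rank-then-Pearson with mean ranks on ties.
*Perturbation analysis* multiplies each internal concentration by an
independent factor, log-uniform on $[0.5, 2]$ (symmetric in log space;
reconciles a ±50% additive reading of the same range), integrates to the
doubling time and counts a return when the final state is within 1% of the
reference in relative L2 norm; 10 repeats per model by default, 100
available via the arguments. *Trajectory PCA* stacks all time points of all
trajectories as observations. *Parameter ranking* orders features by the KL
divergence between relevant and irrelevant populations; *stratification*
splits a relevant population into equal-count bins (robust to the skewed
parameter distributions) of one parameter's value and summarizes the
largest eigenvalue per bin, exposing monotone parameter–dynamics
dependences and the sloppiness of the rest.

## The toy physiologies

The packaged fixture is a branched uptake pathway — substrate → A → B,
branching to C and D, interconverted by one reversible shunt (C ↔ D),
re-joining at E → F → product — with 6 internal metabolites, 2 boundary
metabolites and 9 reactions (18 $K_M$ features). Physiologies "A" and "B"
differ in exactly one reference flux sign (the shunt) with consistent
$K_{eq}$ and downstream flux-magnitude adjustments; both reference states
are steady and thermodynamically consistent by validation at construction.
Reference fluxes are tens of mmol gDW⁻¹ h⁻¹ at millimolar concentrations
and the toy doubling time is 50 min, calibrated once so that the eigenvalue
bound $-3.6\ \mathrm{h^{-1}}$ lands mid-distribution: saturation sampling
yields 40–50% relevant models, so both classes are well populated
(mirroring the 55–61% incidence regime of realistically sized training
data). `makeLabelledDataset()` enforces the 0.3–0.7 incidence band and
errors loudly rather than returning a degenerate fixture.

What the toy does *not* emulate: genome-scale dimensionality (hundreds of
features rather than 18), allosteric regulation, conserved moieties,
multi-substrate mechanisms beyond the packaged stoichiometries, and the
long non-normal transients of large networks. Passing fixture benchmarks
therefore demonstrates that the machinery — sampling identities, labelling,
adversarial learning, transfer — behaves correctly and reproducibly, not
that the measured incidences generalize quantitatively to real networks.

## Problem sizes and numerical choices

The benchmark suite trains on 1,000-row fixture datasets for 60 epochs
(three seeds) and runs transfer-vs-scratch comparisons at $n = 10$ for 100
epochs — sizes chosen so the full pipeline exercises every code path in
minutes on one CPU while leaving the adversarial dynamics realistic enough
to measure. Batch-norm inference uses running statistics (momentum 0.99);
generation is bit-reproducible under a fixed seed because all randomness
(weight init, shuffling, noise, dropout) flows from the configured seed.
Equal-count stratification bins, the $10^{-10}$ KL mass floor, the
$10^{-6}/10^{-9}$ integrator tolerances and the $10^6$× divergence guard
are the package's recorded numerical conventions.

One deliberate test-design choice: the toy's convenience-kinetics pathway
is globally well-behaved, so Jacobian-unstable parameter sets essentially
never arise by sampling. The perturbation-contrast checks therefore build
their "escaping" population by breaking the steady-state identity (scaling
one $V_{max}$), which produces trajectories that leave the reference state
— the fixture analogue of pathological escape — rather than by planting
eigenvalue instability.

## Known limitations

- One $V_{max}$ per reaction; mechanism families with additional
  non-$K_M$ parameters (e.g. inhibition constants) are out of scope.
- No SBML import; the model-spec format is the package's own YAML schema.
- Checkpoints serialize via RDS (plus CSV/JSON sidecars); no HDF5.
- The toy physiologies' incidence calibration holds for their packaged
  reference states; new networks need their own calibration pass.
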
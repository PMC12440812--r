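---
title: "Charge equilibration as a differentiable layer: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge equilibration as a differentiable layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(celliq)
```

## The problem

Graph-network interatomic potentials built on chemical locality predict the
energy of an atomic configuration as a sum of contributions that each depend
only on a fixed-radius neighborhood. This makes them fast and parallelizable,
but architecturally blind to two things that matter in ionic and
charge-transfer systems: long-range electrostatics, and the total charge of
the system. A strictly local model produces *bit-identical* output for two
structures that differ only in net charge — there is simply no input through
which the information could enter.

`celliq` addresses this with a charge-equilibration layer: a block inside the
network that (i) converts latent edge features into per-atom
electronegativities, hardnesses, and Gaussian charge radii, (ii) solves the
classical charge-equilibration (Qeq) problem globally under a total-charge
constraint, (iii) adds the resulting screened-Coulomb energy to the
prediction, and (iv) embeds the equilibrated charges back into the latent
features so that downstream short-range terms can condition on the local
charge state. The total energy is split as

    U = U_Coul(Q*) + Delta U,

where `Q*` are the equilibrated charges and `Delta U` is the learned
short-range correction read out from the final edge features.

## Electrostatics of Gaussian charges

Each atomic charge `Q_i` is smeared as a Gaussian of radius `gamma_i`, so two
charges interact through `erf(alpha_ij r)/r` with
`alpha_ij = (1/sqrt(2)) (gamma_i^2 + gamma_j^2)^(-1/2)`, which saturates
smoothly at small separation instead of diverging. The total Coulomb energy is

    U_Coul = k_e [ sum_{i<j} erf(alpha_ij r_ij)/r_ij Q_i Q_j
                   + sum_i (2 alpha_ii / sqrt(pi)) Q_i^2 ],

implemented verbatim, including the self-term prefactor `2 alpha_ii/sqrt(pi)`
(equivalently `1/(gamma_i sqrt(pi))`). Parts of the charge-equilibration
literature use a self-energy half this size; we follow the form above
consistently throughout — energy, operator diagonal, and all derivatives —
so the package is internally exact regardless of convention. The Coulomb
constant `k_e = 14.399645` eV·Å/e² enters once, at the interface, so
electronegativities are learned in eV/e and hardnesses in eV/e².

All charge-space structure is collected in the symmetric operator `M` with
`U_Coul = Q' M Q / 2`. For open boundaries `M` is assembled directly; for
fully periodic cells it is assembled by classic Ewald summation:

* the point-charge part is split into a real-space `erfc(kappa r)` sum, a
  reciprocal sum with weights `exp(-k^2/4 kappa^2)/k^2`, and the self term;
* an absolutely convergent real-space correction
  `-(1/2) sum q_i q_j erfc(alpha_ij r)/r` converts point interactions to the
  screened-Gaussian form;
* net-charged cells receive the uniform neutralizing-background (jellium)
  correction `-pi (sum Q)^2 / (2 V kappa^2)`;
* the surface dipole term `2 pi |sum Q_i R_i|^2 / (3V)` is included
  (vacuum / spherical-summation boundary conditions), so that a neutral
  cluster in a large padded box converges to its open-boundary energy. For
  net-charged cells this term is origin-dependent; users comparing against
  tinfoil-convention codes should subtract it.

The splitting width defaults to an eighth of the smallest perpendicular cell
width; real- and reciprocal-space cutoffs are derived from the requested
accuracy (default 1e-8), and the result is independent of the splitting
parameter to that accuracy. Smooth particle-mesh variants and partial
periodicity are out of scope: at the system sizes this package targets,
classic Ewald is exact to tolerance and considerably simpler.

## The constrained Qeq solve and its differentiation

The charge energy

    U_Qeq(Q) = U_Coul(Q) + sum_i [ chi_i Q_i + (J_i/2) Q_i^2 ]

is minimized subject to `sum(Q) = Q_tot` by solving the bordered KKT system

    [ M + diag(J)   1 ] [ Q      ]   [ -chi  ]
    [ 1'            0 ] [ lambda ] = [ Q_tot ],

by dense factorization with one step of iterative refinement. The multiplier
`lambda` is reported: it is the negative equilibrated electronegativity of
the system. Positive-definiteness is not pre-checked (the softplus
construction upstream makes `J > 0`, which in practice keeps the system
well-posed); a singular solve raises an error carrying the smallest
eigenvalue of the hardness matrix as a diagnostic.

Because the equilibrated charges feed back into the network features, the
envelope-theorem shortcut (differentiating the energy at fixed `Q`) is *not*
sufficient for model gradients. The package differentiates through the solve
with the implicit function theorem: the reverse-mode rule for `A z = b` is a
single extra solve with the same matrix, giving exact sensitivities of the
charges with respect to electronegativities, hardnesses, radii, and
positions. `qeq_jacobians()` exposes these as explicit arrays, verified
against central finite differences in the test suite. One place *does* use
the envelope theorem legitimately: the synthetic reference generator, whose
electronegativities are fixed per species, so the charge-response term of
its force vanishes identically at the constrained optimum.

There is no automatic-differentiation framework underneath: the package
carries its own reverse-mode engine — hand-written vector–Jacobian products
for the MLPs, the aggregation/scatter steps, the Coulomb operator assembly,
and the KKT solve — fused into one forward and one backward pass per
structure. The same backward pass yields parameter gradients (training) and
position gradients (forces). Finite-difference checks on both are part of
the acceptance tests. Analytic position gradients are implemented for open
boundaries; periodic structures currently support energy and charge
prediction only.

## The backbone and the block

The backbone is a strictly local, scalar, directed-edge network. Layer-0
features concatenate a learned species-pair embedding with envelope-weighted
Bessel radial features `sin(n pi r / r_c)/r` (8 functions by default). Each
interaction layer forms an environment sum over edges sharing a source atom,

    w_ij = sum_{k in N(i)} W(x_ij, x_ik),   W(a, b) = A(a) * B(b),

with the two-argument map factorized as an elementwise product of two MLP
embeddings — this preserves the permutation-invariant environment-sum
structure while costing edge-level rather than pair-level work — followed by
an update MLP and a variance-preserving weighted residual
`x <- (x + beta * update)/sqrt(1 + beta^2)` with `beta` learnable from 0.
The envelope is the standard smooth polynomial
`p_env(u) = 1 - (p+1)(p+2)/2 u^p + p(p+2) u^(p+1) - p(p+1)/2 u^(p+2)`,
`u = r/r_c`, `p = 6`: one at the origin, zero with two vanishing derivatives
at the cutoff. Since every quantity depends on positions only through
distances, rotation and translation invariance hold by construction, and
tensorial (equivariant) feature tracks are deliberately omitted — that is
the major simplification relative to full equivariant architectures, traded
for cheap exact gradients and fast tests.

The charge-equilibration block sits at a configurable position among the
interaction layers (default: central, `floor(L/2)` — placing it mid-network
gives the electronegativity MLP access to higher-body-order environment
descriptions while leaving layers after it to correlate charge information).
Its pieces:

* electronegativity: `chi_i = f * sum_{k in N(i)} chi~_ik`, where `chi~` is
  one output channel of an MLP applied to each directed edge feature and `f`
  is a single global learnable scale. Atoms with no neighbors get
  `chi_i = 0` and still receive charge through the constraint.
* hardness: `J_i = softplus(J~Z_{Z_i} [, sum_k J~R_ik])` via the generalized
  softplus `log(1 + sum exp(x_m))`, guaranteeing positivity; the
  environment-dependent channel is off by default and toggleable.
* radii: `gamma_i = softplus(s~_{Z_i})/log(2) * gamma_exp_i`, a learned
  positive species scaling of tabulated single-bond covalent radii; at
  `s~ = 0` the factor is exactly 1.
* charge embedding: `y_ij = MLP_Q(Q_i, Q_j, c_i, c_j)` with a separate
  species-context table `c`, then
  `x^{l+1}_ij = MLP_x(y_ij, x^l_ij) * p_env(r_ij)`.

The readout sums two linear per-edge channels, both zero-initialized so the
untrained correction is exactly zero: a projection of the final latent
features, and a species-pair-resolved weight vector over the raw Bessel
features (a learnable pair potential). The second channel exists because a
large fraction of any short-range correction is pairwise; giving it a direct
linear route speeds training considerably without changing the model class.

On top of the learned terms the model carries a fixed screened nuclear-core
repulsion baseline, `U_core = (1/2) k_e Z_i Z_j erfc(r/d)/r` per directed
edge with `d = 0.2 (R_i^cov + R_j^cov)`. At bonded distances it is
orders of magnitude below the fit accuracy (~1e-5 eV at 2 Å for an Na–Cl
pair), but it walls off the region below the sampled distance range where
any learned correction is pure extrapolation — without such a baseline,
thermally activated close approaches in molecular dynamics can fall into
unphysical minima and collapse. Fixed cores of this kind are standard
practice for learned potentials; the term is reported separately from the
learned correction `ΔU`, which therefore remains exactly zero at
initialization.
Exactly one charge block per model is supported; the baseline
(`use_celli = FALSE`) replaces it with an additional interaction layer,
which is the architecture used for the locality-failure comparisons.

MLPs are two hidden layers of SiLU units; initialization is fan-in-scaled
Gaussian from a single seed, with the electronegativity head small-random
(not zero — a zero head together with `f = 0` would be a stationary point of
the charge pathway) and `f` initialized at 0.5.

## Training

Per-species energy shifts are fit by ridge regression of reference energies
on composition counts (`fit_shifts()`), and models are trained and evaluated
on the shifted scale; absolute energies are recovered by adding the shifts
back (`predict(..., absolute = TRUE)`).

The loss is the standard force-matching form: per structure,
`gamma_U ||U - U_hat||^2 + gamma_F/(3N) ||F - F_hat||^2 +
gamma_Q/N ||Q - Q_hat||^2`, averaged over the batch. The trainer (Adam,
polynomial step-size schedule `lr0 (1 - t/T)^kappa`, decoupled weight decay,
global gradient-norm clipping at 100 as a NaN guard) optimizes the energy
and charge terms; the force term is available in `fm_loss()` for evaluation
but its parameter gradient would require second-order differentiation
through the hand-written engine and is not implemented — `train_potential()`
rejects `gamma_F > 0` explicitly rather than silently ignoring it. On the
synthetic benchmarks, energy plus charge supervision is sufficient:
forces are validated separately against finite differences and in molecular
dynamics. Defaults: `gamma_U = 1`, `gamma_Q = 30` — the charge term is
cheap to satisfy and anchoring the Qeq parameters early resolves the
competition between the electrostatic and correction channels; with equal
weights the energy term drags the Qeq parameters away from the
charge-optimal region for a long transient. `lr0 = 5e-3`, `kappa = 0.7`,
batch 32, 100 epochs reproduce the reference study conditions in the
acceptance run. The checkpoint with the lowest validation loss is returned,
and training is bit-reproducible for a fixed seed on a fixed platform.

## The synthetic reference

Because real reference data would require external quantum-chemistry
computation, the package ships an exact stand-in (`reference_model()`): a
fixed-parameter Qeq model plus a smoothly cut-off Morse pair potential.
Labels are analytic — charges from the constrained solve, energies from
`U_Qeq` plus the pair sum, forces from the exact gradient — so every
downstream test compares against ground truth known to machine precision,
and "label noise" is an explicit, optional, seeded addition (zero by
default; the noiseless labels ride along in an attribute).

The default parameters describe two fictitious species "A" (stored as
Z = 11) and "B" (Z = 17) with an NaCl-flavored electronegativity gap
(2.8 vs 8.5 eV/e), hardnesses 4.6 and 9.9 eV/e², Gaussian radii 1.2 and
0.9 Å, and a heteronuclear Morse well of 0.8 eV at 2.35 Å. The short-range
potential is cut off smoothly at 4 Å with the same polynomial envelope the
model uses, which keeps the ground truth strictly inside the model family's
representational reach — deliberate, so that parameter-recovery experiments
measure optimization and architecture rather than model mismatch. Geometry
families: jittered alternating chains (4–8 atoms), rock-salt fragments with
extra-cation and vacancy variants emitted as geometry-identical twins in
total-charge states 0 and +1, and a scan family displacing one cation along
the body diagonal of a fixed fragment. What the generator does *not*
emulate: conformational diversity of real molecules, label noise correlated
with geometry, many-body exchange effects outside the pair-plus-Qeq form —
passing the recovery tests therefore demonstrates the machinery, not
chemical accuracy on real systems.

The twin sets are the minimal probe of the locality failure: a charge-blind
strictly local model provably assigns both members of a twin pair the same
energy (this is asserted bit-exactly in the tests), so its twin
energy-difference error equals the true difference, while the
charge-equilibrated model recovers the difference from the constraint alone.

## Molecular dynamics

`simulate_md()` implements Langevin dynamics with the BAOAB splitting (half
kick, half drift, exact Ornstein–Uhlenbeck step, half drift, half kick),
chosen for its configurational accuracy at large friction; the discretization
of the thermostat is a declared choice, not prescribed by the method itself.
With zero friction and temperature it reduces to velocity Verlet (energy
drift of a Morse dimer < 1e-4 eV over 10,000 steps at 0.5 fs in the tests);
at high friction it reproduces the target kinetic temperature within a few
percent. Stability diagnostics are computed over every step, not only saved
frames: minimum interatomic distance, maximum stretch of initial-frame
bonds (bonded = within 1.25 times the nearest-neighbor scale), and
non-finite values. `stability_check()` applies the conventional thresholds
(no distance below 0.5 Å, no bond stretched past 2.0 times its initial
length).

## Numerical choices and degenerate inputs

* Neighbor lists use the half-open test `r < cutoff`, so an edge exactly at
  the cutoff (where the envelope is zero) cannot enter; lists are rebuilt
  every evaluation — correctness over speed at these sizes.
* Near-coincident pairs (`r < 1e-6` Å) in the Coulomb kernel use the series
  limit `erf(alpha r)/r -> 2 alpha/sqrt(pi)`; the direct-sum energy refuses
  genuinely coincident atoms (`r < 1e-8` Å).
* The generalized softplus is evaluated with max-shifted exponentials, and
  its backward pass as `exp(x_m - value)`, both overflow-safe.
* Atom indices are 1-based throughout, following R convention.
* Training problem sizes: the recovery experiments use 2000 labeled
  structures (1600/200/200 split), models of 2 interaction layers, width 16,
  8 Bessel functions, cutoff 4 Å; molecular-dynamics validation runs 20,000
  steps on 8–9-atom clusters. These match the scale of the synthetic study
  conditions the package is built around.

## Known limitations

* Scalar features only; no equivariant tensor track, so directional
  many-body effects are representable only through distances.
* No force-weighted training (second-order gradients unimplemented).
* Periodic cells: energies and charges only — no forces, no training, and
  only full 3D periodicity (no slabs/wires).
* The Qeq solve is dense `O(N^3)`; fine for hundreds of atoms, not for
  millions. Iterative and multipole-accelerated solvers are out of scope.
* A single charge block per model; external electric fields and
  charge-dependent dispersion are not modeled.
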
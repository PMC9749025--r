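---
title: "Models and methods behind egressr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind egressr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`egressr` packages the enhanced-sampling workflow used to characterise
ligand unbinding from buried binding sites — biased path discovery,
streamline clustering into guess paths, path-CV well-tempered
metadynamics, grid-based minimum free energy paths, and restrained
alchemical decoupling — and exercises it on analytic model landscapes
instead of a molecular system. This vignette records the models, the
parameters that matter, what the synthetic world does and does not
emulate, and the design choices made where the design was genuinely open.
Units everywhere: kcal/mol, Angstrom, Kelvin, ps; `kB = 0.0019872041
kcal/mol/K`.

## The model world

### Egress landscapes

The stand-in for the protein–ligand complex is a two-dimensional
landscape: in polar coordinates

$$U(r, \theta) = B(\theta)\, f(r) + W(r)$$

with a radial bump $f(r) = (r/r_b)^2 e^{1 - (r/r_b)^2}$ that equals exactly
1 at the barrier ring $r = r_b$ (default 10 A), a compact-support bound
well $W(r) = -D\,(1 - (r/r_w)^2)^2$ for $r < r_w = r_b/2$ (depth $D = 5$),
and an angular profile $B(\theta)$ equal to a base ring height lowered by
von Mises bumps at the channel angles. The bump amplitudes are obtained by
solving a small linear system so each channel's saddle energy at
$(r_b, \theta_j)$ equals its declared barrier *exactly* (residual error
only from sub-$10^{-9}$ cross-talk between channels and the well's compact
support). This is what makes the landscape a fixture: "the barrier of
channel j" is not an estimate but a constructor argument, and
`saddle_energies()` verifies it to $10^{-6}$.

Geometry choices, fixed once: ring radius 10 A (so that a 3 A clean-up
threshold leaves 4–6 frames per egress, enough geometry for clustering),
well depth 5 kcal/mol, base ring `max(barriers) + 15` (high enough that a
ratcheted ligand is funnelled into a channel rather than dragged over the
inter-channel wall), channels spread evenly around the circle with seeded
jitter, channel width $\sigma_\theta = 1/\sqrt{\kappa} \approx 10$–$20°$.
The stop rule ("left the protein") is a radius crossing at 12 A — just
past the saddle, before free diffusion in the outer region can scramble
the exit direction — confirmed over a one-step grace window against
boundary jitter.

### Dynamics

The integrator is overdamped Langevin (Euler–Maruyama),
$dx = -(\beta/\gamma_f)\nabla U\,dt + \sqrt{2 k_B T dt/\gamma_f}\,dW$,
with reflective domain boundaries. Overdamped rather than inertial
dynamics is a deliberate substitution: every quantity the package computes
is configurational (stationary distributions, free energies, path
geometry), and the overdamped choice removes mass/thermostat parameters
that the underlying method descriptions leave open. Scaling the potential
by $\beta$ is distributionally identical to raising the temperature to
$T/\beta$, and the test suite asserts exactly that equivalence
(two-sample KS, three potentials). Friction is 1/ps; the default step
$dt = 0.01$ ps keeps the largest force-step product two orders below the
thermal step.

### The Ratchet&Pawl bias

The RPP equations in the source method descriptions are not printed in
recoverable form; what is constrained is the behaviour (zero bias while
unbinding progresses, damped fluctuations on retreat) and the units of the
force constant, kcal/mol/A$^4$. The only standard form consistent with
those units ratchets $\rho(t) = (s - s_\mathrm{target})^2$ (A$^2$) and
applies $V = \tfrac{k}{2}(\rho - \rho_\mathrm{best})^2$ when $\rho$
exceeds its running minimum. The pawl ($\rho_\mathrm{best}$) moves at step
end, making single-step behaviour well defined. With the published
$k = 0.024$ and these length scales the bias is drag-dominated: a ligand
is pulled out within tens of ps regardless of the saddle height, so the
observed channel split reflects the angular funnels of the landscape (the
deeper the channel, the wider its basin of attraction) more than a
Boltzmann ratio of saddle energies. That is a faithful property of the
method — ratcheted discovery finds *where* paths are, not their rates —
and the acceptance criterion checks only that all channels are found and
the lowest-barrier channel is the most populated.

The ratcheting coordinate is, as in the original method, a scalar
projection $s = (x - x_0)\cdot\hat{u}$; the package adds a radial mode
$s = |x - x_0|$, used by the campaign because the toy channels fan out
isotropically from one site, whereas a single projection direction
presumes the protein/membrane anisotropy the toy does not have.

## Guess paths

Clean-up follows the threshold scan exactly: keep frame 0, then save a
frame whenever its RMSD to the last saved frame is greater than or equal
to the threshold (3 A default; for a point particle the alignment
contract is the identity and RMSD is the Euclidean distance). The scan
discards the final (exit) frame whenever it falls inside the threshold;
the campaign therefore appends the raw exit frame to each streamline, so
guess paths span bound to unbound.

QuickBundles is implemented in its original single-pass, order-dependent
form over the MDF distance (both streamlines arc-length-resampled to 12
points, direct and flipped mean pointwise distances, minimum of the two).
Input order is recorded, so runs are reproducible; the clustering
threshold is a required configuration key (3 A for the bundled fixtures,
which sit in a wide gap between within-channel spread of about 2 A and
between-channel distances above 6 A). MDF is not a metric under flipping;
the test suite reports triangle-inequality violations on random triples
rather than forbidding them.

Guess-path construction selects the pool frame nearest each of
`2 * n_frames` equally spaced centroid arc-length stations, bridges any
adjacent pair whose mean-square gap exceeds 1.5 times the median with a
short targeted ratchet run (logged as a gap-fill event), then smooths the
polyline by endpoint-pinned sliding means with periodic re-parametrisation
until resampling to *N* frames meets the equal-spacing contract. The
contract — coefficient of variation of adjacent-frame msd at most 0.2 —
operationalises the qualitative "equally spaced" requirement that path
CVs inherit from their construction. Smoothing slightly straightens real
curvature; for a reference path this is benign because the deviation
coordinate *Z* absorbs lateral displacement.

## Path collective variables

With reference frames $X_1 \ldots X_N$ and
$w_i \propto e^{-\lambda\,\mathrm{msd}(X, X_i)}$:

$$S = \frac{\sum_i i\, w_i}{\sum_i w_i} \in [1, N], \qquad
Z = -\frac{1}{\lambda}\ln \sum_i e^{-\lambda\,\mathrm{msd}(X, X_i)}.$$

Both are evaluated by log-sum-exp, so they stay finite whenever any msd
is finite; analytic gradients (needed to bias the CVs) follow from the
weight derivatives and are verified against central differences to
$10^{-4}$. $\lambda$ is never published for such setups; the default is
the standard heuristic $\lambda = 2.3/\mathrm{median}$ adjacent-frame msd,
which keeps neighbour weights distinguishable (the auto-tune invariant
$\lambda \cdot \mathrm{msd}_\mathrm{adj} \in [1, 5]$ is asserted).
$S$ runs 1..N internally; published figures often rescale the axis so the
bound state is 0 and the unbound end e.g. 60 — `rescale_progress()` is
that affine presentation transform, nothing more. $Z$ may be negative
(points closer to the path than the reference self-distance scale); it is
not clamped. Deviation is reported in A$^2$; a metadynamics width quoted
as 0.01 nm$^2$ converts to 1 A$^2$.

## Well-tempered metadynamics

Hills of initial height $\omega_0 = 0.2$ kcal/mol are deposited every
2 ps with widths $\sigma_S = 0.1$ and $\sigma_Z = 1$ A$^2$ and tempered by
$h_k = \omega_0 e^{-V(s_k)/k_B \Delta T}$, $\Delta T = (\gamma - 1)T$,
$\gamma = 15$. Two implementation details matter:

* During simulation the bias force is interpolated from a deposit grid
  (spacing $\sigma/5$, 6$\sigma$ deposit cutoff, truncation error below
  $10^{-7}$ of a hill height); but the height of each new hill uses the
  *exact* analytic sum over the ledger, so recorded heights satisfy the
  well-tempered recursion to machine precision — the suite checks
  $h_k = \omega_0 e^{-V_{k-1}/k_B\Delta T}$ directly.
* The FES is estimated from the final bias, $F = -\frac{\gamma}{\gamma-1}
  V$, shifted to min 0 — the standard converged-bias estimator;
  reweighting is out of scope. Error bars on basin differences come from
  block truncations of the deposition history (`ledger_block_error`),
  the estimator being unstated in the method sources.

On a tilted double well the reconstructed basin difference agrees with
the deterministic Boltzmann quadrature oracle within $0.5\,k_BT$ after
10 ns of toy dynamics; that is the headline metadynamics acceptance test.
The pipeline reports the two-CV FES only over the biased CV window
(Z up to ~30 A$^2$): excursions beyond the bias grid were never
compensated and carry no usable free-energy information.

## Minimum free energy paths

On a gridded FES the MFEP objective is lexicographic: minimise the
maximum node energy, then the sum of node energies; remaining exact ties
break by hop count and node index, making the result unique and
deterministic (a flat surface yields the Chebyshev-shortest diagonal
path). The search floods node-by-node — repeatedly accepting the
lowest-energy frontier node until the end is reached — which yields the
minimax level; a Dijkstra pass restricted to nodes at or below that level
settles the sum criterion. 8-connectivity is the default, with a
4-connectivity flag.

The independent oracle is exact but avoids enumerating all simple paths
(combinatorially impossible even on 5×5 king graphs): it derives the
minimax level by sweeping every node energy as a threshold with a DFS
connectivity test, then exhaustively enumerates simple paths *inside* the
restricted subgraph, where every start–end path attains the minimax
maximum, so lexicographic optimality reduces to a sum minimisation and
the sum prune is exact for non-negative energies. Search and oracle agree
on 100 seeded 5×5 grids in the acceptance suite. Minima are interior grid
nodes at or below their 8-neighbourhood, with equal-valued plateaus
merged to their lowest-index representative.

## Alchemical decoupling

The toy complex is one ligand particle in a tetrahedral cage of four
fixed sites at the Lennard-Jones minimum distance, with a weak uniform
attractive charge — the smallest system in which soft-core decoupling,
restraints and the double-decoupling cycle are all meaningful and the
binding free energy is computable by direct 3-D quadrature. The cage
parameters (eps 0.3, sigma 3 A, site charge −0.05 e, ligand +0.5 e, box
14 A) were chosen once so the pocket centre is the global minimum, the
complex is clearly bound (~−7 kcal/mol), and every window pair overlaps
well at a few hundred Monte Carlo samples.

The legs: restrain the coupled ligand (one BAR pair), annihilate
electrostatics over the 11-window schedule at full vdW, decouple vdW over
{0, 0.05, …, 1} with charges off (the λ = 0 endpoint being the
electrostatic leg's final state), then release the restraint
analytically into the reference volume (1660 A$^3$ for the 1 M standard
state). Soft-core uses the shifted distance
$r_\mathrm{eff}^6 = \alpha\sigma^6\lambda^p + r^6$ ($\alpha = 0.5$,
$p = 1$, $\sigma = 3$ A) for both Lennard-Jones and Coulomb terms — the
named GROMACS-style knobs admit exactly this standard construction.

A point ligand has no orientation, so the six-coordinate
distance/angle/dihedral restraint cannot be imposed during sampling; the
cycle uses the distance restraint with its release correction integrated
numerically (exact, no Gaussian approximation). The full six-coordinate
analytic correction — the rigid-rotor/Gaussian formula
$\Delta G = -k_BT \ln\!\big[8\pi^2 V^0 \sqrt{\textstyle\prod_i k_i}\,/\,
(r_0^2 \sin\theta_A \sin\theta_B\,(2\pi k_BT)^3)\big]$ — is implemented
and verified against a six-dimensional quadrature oracle to 1%, with
angle and dihedral force constants read as the per-degree class of the
published pair (10 kcal/mol/A$^2$ and 10 kcal/mol/deg$^2$; dihedral
constants assumed equal to angle constants). Validity requires angle
references at least 10° from 0/180°, which the constructor warns about.

BAR solves the self-consistency equation by bracketing and bisection to a
residual below $10^{-10}$, with Bennett's variance estimate; vanishing
overlap yields an infinite uncertainty and a warning rather than a silent
number. The estimator is validated three independent ways: synthetic
Crooks-consistent Gaussian work samples with known $\Delta G$ (bias under
one pooled SE across 20 seeded repeats), a harmonic system with a closed
form, and agreement with exponential averaging at large *n*.

## What a green test establishes — and what it does not

The synthetic world has analytic gradients, no solvent, no internal
protein degrees of freedom, isotropic friction, and channels whose
barriers are constructor inputs. Green acceptance tests therefore
establish the *machinery*: the integrator samples Boltzmann, the ratchet
never pushes backwards and enormously accelerates escape, clustering
recovers planted structure, the metadynamics estimator converges to
quadrature truth, the MFEP search is exactly optimal, and the alchemical
stack closes its thermodynamic cycle against quadrature. They do not
establish anything about a real protein: path discovery statistics on
CYP-scale systems, the adequacy of two CVs for a ligand plus loop
rearrangement, or force-field accuracy are all outside what this world
can probe.

## Numerical choices and degenerate inputs

* Seeds: every stochastic entry point takes one; replica *i* of a
  campaign uses `base_seed + i - 1`; campaigns rerun bit-identically
  (manifest md5 checks in the acceptance suite).
* Quadrature oracles warn when the Boltzmann weight at the domain edge
  exceeds $10^{-6}$ of the maximum (domain too small) and are asserted
  stable to 0.5% under 2× grid refinement.
* Degenerate guess paths (identical adjacent frames) fail fast in
  `auto_lambda`; the equal-spacing contract is validated at construction.
* The integrator aborts with a diagnostic on non-finite energies rather
  than producing NaN trajectories; masked FES nodes are impassable and an
  unreachable MFEP end is reported distinctly, not as an error.
* Hill ledgers round-trip through HILLS-dialect files exactly at printed
  precision; a reread ledger rewrites byte-identically.
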
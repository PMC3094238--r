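---
title: "Force distribution analysis: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force distribution analysis: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairforce)
```

## The observable

Classical MD sums all forces acting on an atom into one vector before
integrating the equations of motion. That sum averages to zero under
equilibrium fluctuations, so it carries no usable information about how
stress flows through a structure. Force distribution analysis keeps the
information that the summation destroys: the **pair-wise force**
$F_{ij}$ between every two interacting atoms, stored per interaction
type in a sparse $N \times N$ structure for every frame (or every
averaging interval) of a trajectory.

Because molecules translate and rotate, force *vectors* cannot be
meaningfully time-averaged; `pairforce` therefore stores the signed
scalar norm of each pair force. The sign convention is fixed and
documented everywhere: **positive = repulsive** (the interaction pushes
the pair apart), negative = attractive. When vectors are needed — e.g.
for exact residue-pair force sums — they are reconstructed from the
coordinate trajectory as $\vec F_{ij} = F_{ij}\,\hat u_{ij}$ with
$\hat u_{ij}$ pointing from $j$ to $i$.

### Multi-body terms

Angles and proper dihedrals involve three or four atoms, so they have
no unique pair force. `pairforce` uses the outer-atom projection: the
full analytic forces $\vec F_i$, $\vec F_k$ of the harmonic angle
potential $V = \tfrac12 k_\theta(\theta - \theta_0)^2$ are projected on
the i–k axis, and the dihedral forces of
$V = k_\phi(1 + \cos(n\phi - \phi_s))$ on the i–l axis. Two choices in
this projection were genuinely open:

* *Which atom's force to project.* We use the symmetrized
  $\tfrac12(\vec F_i \cdot \hat u_{ki} + \vec F_k \cdot \hat u_{ik})$,
  which makes the scalar invariant under relabelling
  $(i,j,k) \leftrightarrow (k,j,i)$; projecting a single atom's force
  would make the stored value depend on topology file ordering.
* *The discarded remainder.* Forces on the apex/inner atoms are
  dropped. This is an approximation, not an accounting identity: only
  for two-body terms does summing reconstructed pair vectors reproduce
  the exact atomic forces (the test suite checks this conservation to
  $10^{-9}$ relative on random bond/Coulomb/LJ systems, and checks the
  projected kernels against central-difference differentiation of their
  potentials to $10^{-5}$ relative).

Improper dihedrals have no meaningful outer-atom axis and are excluded;
so are mesh-based long-range electrostatics, which cannot be decomposed
into pairs at all. Electrostatics are plain truncated Coulomb
($f\,q_iq_j/r^2$, $f = 138.935458$ kJ mol⁻¹ nm e⁻²) with a default
cutoff of 1.0 nm, where the potential is already flat enough that
truncation little affects pair forces; no reaction field or switching
function is applied. Lennard-Jones parameters of unlike atoms combine
by Lorentz–Berthelot rules (arithmetic $\sigma$, geometric
$\epsilon$). Any pair listed in the topology's exclusions is fully
excluded from non-bonded evaluation and all other pairs interact at
full strength — there is no scaled 1-4 treatment, a deliberate
simplification relative to common biomolecular force fields that keeps
the toy systems analytically transparent.

## Statistics

Strain becomes visible by comparing states (with/without load, apo/holo):

$$\Delta F_{ij} = \bar F^{pert}_{ij} - \bar F^{ref}_{ij},$$

a signed subtraction of time-averaged forces, with a pair absent from
one state counting as exactly zero (sparsity encodes true zeros by
construction, which also keeps averaging linear; no magnitude pruning
is ever applied). The same subtraction between two independent
reference runs gives $\Delta F^{noise}$, the null distribution against
which signals are judged.

The normalized change $\Delta f_{ij} = \Delta F_{ij} / \epsilon_{ij}$
expresses each change in units of its own sampling noise.
$\epsilon_{ij}$ is the standard error of the per-run mean forces:
sample standard deviation across runs (denominator $n-1$, runs are few)
over $\sqrt{n}$. One design question had no single defensible answer:
which runs enter $\epsilon$ for a two-state comparison. Pooling the run
means of *both* states folds the signal itself into the noise estimate
— a large perturbation then inflates its own $\epsilon$ and the
resulting $\Delta f$ saturates near $2\sqrt{n}$ regardless of effect
size, destroying the detection power the normalization exists to
provide. `pairforce` therefore estimates $\epsilon$ within each state
and combines them in quadrature
($\epsilon = \sqrt{\epsilon_{ref}^2 + \epsilon_{pert}^2}$, the standard
error of a difference of independent means, `combine_standard_errors()`);
pairs with $\epsilon = 0$ cannot be normalized and are dropped with a
reported count. Within-trajectory block variances use the population
convention (they describe the blocks at hand, not an inference).

Projection to atoms uses the absolute column sum
$\Delta F_j = \sum_i |\Delta F_{ij}|$; absolute values stop opposing
changes from cancelling. Networks threshold $|\Delta F_{ij}| >$ cutoff
strictly. Residue aggregation sums signed scalars by default (a
documented approximation — norms are not additive) with an `abs` mode
and an exact vector mode; intra-residue pairs are excluded by default
because inter-residue coupling is the object of interest, with a flag
to include them. PCA treats blocks as observations and pairs as
variables, centers but does not scale (forces share units; scaling
would distort relative coupling strengths), and is delegated to
`stats::prcomp` on the dense block × pair matrix.

## File formats and numerical choices

* **Force trajectory (binary)**: little-endian; header `"FDA1"`, u32
  version (1), u32 `n_atoms`, u8 syntax mode (0 atom / 1 residue); per
  block an f64 time (ps), u32 entry count, then per entry a u64 packed
  index $i N + j$ ($i<j$), an f64 signed force and a u8 type code
  (BOND 1, ANGLE 2, DIHEDRAL 3, COULOMB 4, LJ 5). Entries are written
  in canonical (index, type) order, so equal trajectories are
  byte-identical on disk and `write(read(f))` reproduces `f` exactly.
  Byte compatibility with any historical FDA tooling is not promised.
  The historical triangle convention (VdW in the upper, Coulomb in the
  lower matrix triangle) is reproduced only in the dense export
  `dense_nonbonded_matrix()`; the type tag generalizes it to bonded
  terms.
* **ASCII dump**: one `time i j force TYPE` line per entry at 17
  significant digits — full double round-trip precision.
* **Coordinates**: multi-model PDB (Å, converted to nm) and GRO (nm);
  0-based indices internally, 1-based only inside these text formats.
  Missing time stamps fall back to the frame index in ps. The b-factor
  writer rewrites only columns 61–66 of coordinate records; `minmax`
  scaling maps $[\min,\max] \to [0, 99.99]$ (constant input maps to 0).
* **Degeneracy guards**: an angle with $|\sin\theta| < 10^{-10}$ or a
  dihedral with a collinear bond triple has an undefined gradient
  direction; such entries are skipped with a warning, never an error.
  The analytic LJ minimum $2^{1/6}\sigma$ deserves a note: no
  representable separation evaluates the LJ force to an exact 0.0
  there, so the stored force at the minimum is a rounding-level
  residual ($\sim 10^{-15}$) rather than a pruned zero — sparsity
  prunes exact zeros only.

## Synthetic systems: what they emulate, and what not

The generator provides the study conditions for every test: dimers
isolating single kernels, a linear chain of stiff bonds
($b_0 = 0.15$ nm, $k_b = 10^4$ kJ mol⁻¹ nm⁻²; 2 atoms per residue;
collinear equilibrium angles, $k_\phi = 0$ dihedrals because a
collinear chain leaves the dihedral angle undefined), a bent triple and
a trans zigzag quad sitting at exact stationary points of their
potentials, and a two-residue peptide-like chain with mixed charges as
a reference geometry for aggregation tests. The default chain is purely
bonded — the Newton's-cradle experiment needs every cross-section to
carry exactly the applied tension, which non-bonded bridges would
spoil — while `parameters = list(charge = q)` enables alternating
$\pm q$ charges for electrostatic perturbation studies
($q = 0.25$ e, perturbation $+0.4$ e in the shipped experiments, three
runs of ten frames, 0.005 nm jitter).

Thermal sampling is i.i.d. isotropic Gaussian positional jitter about
the equilibrium, not MD integration: the analysis consumes
trajectories and is agnostic to their generator, and jitter reproduces
the one statistical feature that matters here — fluctuating forces
with nonzero pair means — at zero integrator complexity. Consequences
to keep in mind: frames are uncorrelated in time (real MD is
autocorrelated, so real-data $\epsilon$ estimates need independent
runs or block averaging, which is why the multi-run machinery exists),
there is no solvent, no periodic boundary conditions or minimum-image
convention, and no conformational transitions. Passing tests therefore
demonstrate correctness of the force decomposition and statistics, not
convergence behaviour on flexible macromolecules — systems whose force
averages do not converge (intrinsically disordered regions, transitions
on the sampling timescale) remain outside what time-averaged FDA can
resolve.

Chain equilibria (free and under terminal tension $T$) are solved by
Newton iteration on the net axial atomic forces with a
finite-difference Jacobian to a residual below $10^{-10}$; for the
bonds-only chain this reproduces the closed form (every gap
$b_0 + T/k_b$, every bond force $-T$), and it stays correct when
Coulomb/LJ terms couple the bonds. All randomness flows from a single
integer seed per run; run seeds derive deterministically from the
experiment seed.

## Problem sizes

The shipped tests and the acceptance script run on desk-scale problems
chosen to exercise every code path with tight tolerances: ~1000
randomized kernel cases against central differences, 20-atom random
two-body systems for conservation, the 8-atom chain for tension and
perturbation experiments, 40–100-block random trajectories for format
round trips, and 60-observation PCA recovery problems. The sparse
representation and the $O(N^2)$ non-bonded loop are adequate for such
systems; performance engineering for large proteins is explicitly not
a goal of this implementation.

## A worked equilibrium

```{r}
sys <- build_system(toy_system_spec("linear_chain"))
pair <- make_state_pair(toy_system_spec("linear_chain"),
                        "external_tension", magnitude = 100)
m <- suppressWarnings(
  compute_frame(list(time = 0, coords = pair$pert$coords),
                pair$pert$topology))
m$force[m$type == interaction_types()[["BOND"]]]
```

Every bond — including interior ones whose atoms are mutually
undisplaced — reports the transmitted tension of
$-100$ kJ mol⁻¹ nm⁻¹, while the net force on every atom is zero: the
pair-wise representation reveals exactly the strain that atom-wise
forces cannot show.

## Known limitations

No PME/Ewald, improper dihedrals, Urey–Bradley, CMAP or virtual sites;
no periodic boundary conditions; no XTC/TRR/DCD readers (text formats
suffice at this scale); no scaled 1-4 non-bonded interactions; no
time-resolved (windowed) force analysis — the machinery here is built
on time averages and multi-run statistics.
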
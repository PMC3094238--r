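# pairforce

Force distribution analysis (FDA) for molecular dynamics trajectories,
in R.

How a macromolecule distributes mechanical stress internally largely
determines its stability and function, yet strain often propagates
*without* visible atomic displacement — through stiff regions, like the
shock wave travelling through the stationary balls of a Newton's cradle.
Coordinate-based analyses are blind to such signals. FDA observes them
directly by working with **pair-wise forces**: the force `F_ij` that
atom `i` exerts on atom `j` through each interaction of the force field.
Unlike the total (atom-wise) force, which averages to zero at
equilibrium, the pair-wise force between two atoms can be large and
constant — a stretched spring in a taut chain carries its tension even
though every atom is at rest.

`pairforce` is aimed at structural-bioinformatics users who have
coordinate trajectories (from any MD engine, or generated synthetically)
and want to locate mechanical or allosteric signal propagation by
comparing forces between two states of a system.

## What it computes

For every frame of a trajectory, signed scalar pair forces (positive =
repulsive) for harmonic bonds, harmonic angles (projected on the i–k
axis), periodic proper dihedrals (projected on i–l), cutoff Coulomb and
Lennard-Jones interactions, stored sparsely per interaction type in a
compact binary "force trajectory" format, optionally averaged over an
output interval. Improper dihedrals and mesh-based (PME) electrostatics
have no pair-wise decomposition and are excluded by design.

The statistical layer compares a perturbed state against a reference:

- ΔF<sub>ij</sub> = F̄<sub>ij</sub><sup>pert</sup> −
  F̄<sub>ij</sub><sup>ref</sup>, the per-pair change in time-averaged
  force, with ΔF<sup>noise</sup> = F̄<sup>ref</sup> − F̄<sup>ref′</sup>
  from independent reference runs as the null distribution;
- Δf<sub>ij</sub> = ΔF<sub>ij</sub>/ε<sub>ij</sub>, the change
  normalized by the cross-run standard error ε;
- the per-atom projection ΔF<sub>j</sub> = Σ<sub>i</sub>
  |ΔF<sub>ij</sub>| (absolute column sum), written into PDB b-factors
  for colour-coding structures;
- residue-pair aggregation, as scalar sums F<sub>uv</sub> =
  Σ<sub>i∈u,j∈v</sub> F<sub>ij</sub> or as exact vector sums
  reconstructed from the coordinates;
- force networks: edges wherever |ΔF<sub>ij</sub>| exceeds a cutoff;
- PCA of force time series (atom-pair or residue-pair level) to find
  correlated force fluctuations.

A synthetic-systems module builds toy topologies and jittered
trajectories with known analytic force structure (LJ/charged dimers,
linear chains under tension, bent triples, dihedral quads), so every
part of the pipeline is testable without downloads.

## Worked example

An 8-atom chain with alternating ±0.25 e charges; the perturbed state
adds +0.4 e to atom 4. Three independent runs of ten thermally jittered
frames per state:

```r
library(pairforce)

spec <- toy_system_spec("linear_chain", parameters = list(charge = 0.25),
                        thermal_sigma = 0.005, n_frames = 10, n_runs = 3,
                        seed = 2024)
pair <- make_state_pair(spec, "charge_change", magnitude = 0.4,
                        perturb_atom = 4)
runs <- sample_experiment(pair, spec)

d <- delta_force(average_trajectory(concatenate_trajectories(runs$ref)),
                 average_trajectory(concatenate_trajectories(runs$pert)))
round(atom_projection(d), 2)
#> [1]  55.19  89.77  27.75  39.53 232.18  31.13  31.48  97.15
```

The projection (kJ mol⁻¹ nm⁻¹) ranks atom 4 — the perturbed atom —
far above every other: its summed force changes are dominated by the
altered Coulomb interactions, while the other atoms see mostly sampling
noise plus their single shared pair with atom 4. The force network at a
20 kJ mol⁻¹ nm⁻¹ cutoff isolates exactly the perturbed interactions:

```r
extract_network(d, cutoff = 20)
#>   node_i node_j    weight
#> 1      0      4  41.60546
#> 2      1      4 -74.95532
#> 3      4      7 -74.21171
```

(Atoms 2, 3, 5, 6 are bonded neighbours of atom 4 and therefore
excluded from non-bonded interactions; the signal goes to its Coulomb
partners 0, 1 and 7.) `write_pdb_bfactors()` maps the projection onto a
reference structure, and `fda_main()` / `inst/scripts/fda` expose the
same pipeline as a command line:

```sh
fda compute --topology sys.top --trajectory sys.pdb --out forces.fda
fda average --in forces.fda --out avg.tsv
fda network --in delta.tsv --cutoff 20 --out edges.tsv --dot edges.dot
```

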
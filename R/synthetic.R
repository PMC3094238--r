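# Synthetic toy systems with known analytic force structure. These stand
# in for simulated macromolecules in every test and example: trajectories
# are inputs to the analysis, which is agnostic to how they were
# generated, so i.i.d. thermal jitter about a mechanical equilibrium
# reproduces the statistical structure that matters (fluctuating forces
# with nonzero pair means) without an MD integrator.

#' Specify a toy system
#'
#' @param kind One of `"lj_dimer"`, `"charged_dimer"`, `"linear_chain"`,
#'   `"bent_triple"`, `"dihedral_quad"`, `"two_residue_peptide"`.
#' @param n_atoms Atom count (linear_chain only; others are fixed-size).
#' @param parameters Named list overriding the per-kind force-field
#'   defaults (see Details).
#' @param seed Integer seed fixing all randomness derived from this spec.
#' @param thermal_sigma Positional jitter (nm) of thermal sampling.
#' @param n_frames Frames per run.
#' @param n_runs Independent runs per state.
#'
#' @details Defaults per kind (overridable through `parameters`):
#' * `lj_dimer`: `sigma = 0.3` nm, `epsilon = 1` kJ/mol, placed at the LJ
#'   minimum separation `2^(1/6) sigma`.
#' * `charged_dimer`: charges `q = +1/-1` e at `r = 1` nm (`sigma = 0.3`,
#'   `epsilon = 0`). Not an equilibrium: it isolates the Coulomb kernel.
#' * `linear_chain`: `n_atoms = 8` (2 atoms per residue), `b0 = 0.15` nm,
#'   `kb = 1e4` kJ/mol/nm^2, collinear equilibrium angles
#'   (`theta0 = pi`, `ktheta = 400`), dihedrals present with `kphi = 0`,
#'   `charge = 0` (set nonzero for alternating `+q/-q` charges, with
#'   `sigma = 0.15`, `epsilon = 0`). The default is a purely bonded
#'   mechanical chain; the charged variant adds non-bonded terms.
#' * `bent_triple`: two bonds at right angle, `theta0 = pi/2`,
#'   `ktheta = 400`.
#' * `dihedral_quad`: trans zigzag of 4 atoms, tetrahedral angles, one
#'   proper dihedral (`kphi = 5`, `mult = 1`, `phase = 0`) at its minimum
#'   (`phi = pi`).
#' * `two_residue_peptide`: 6 atoms in two residues with mixed charges
#'   (`epsilon = 0.2`, `sigma = 0.25`); a reference geometry for residue
#'   aggregation, not a potential minimum.
#' @return An object of class `toy_spec`.
#' @export
toy_system_spec <- function(kind = c("lj_dimer", "charged_dimer",
                                     "linear_chain", "bent_triple",
                                     "dihedral_quad",
                                     "two_residue_peptide"),
                            n_atoms = NULL, parameters = list(),
                            seed = 1L, thermal_sigma = 0.005,
                            n_frames = 10L, n_runs = 3L) {
  kind <- match.arg(kind)
  if (thermal_sigma < 0) stop_validation("thermal_sigma must be >= 0")
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1) stop_validation("n_frames must be >= 1")
  defaults <- switch(kind,
    lj_dimer = list(sigma = 0.3, epsilon = 1.0),
    charged_dimer = list(q = 1.0, r = 1.0, sigma = 0.3, epsilon = 0),
    linear_chain = list(b0 = 0.15, kb = 1e4, theta0 = pi, ktheta = 400,
                        kphi = 0, mult = 1, phase = 0, charge = 0,
                        sigma = 0.15, epsilon = 0),
    bent_triple = list(b0 = 0.15, kb = 1e4, theta0 = pi / 2, ktheta = 400,
                       sigma = 0.15, epsilon = 0),
    dihedral_quad = list(b0 = 0.15, kb = 1e4, theta0 = acos(-1 / 3),
                         ktheta = 400, kphi = 5, mult = 1, phase = 0,
                         sigma = 0.15, epsilon = 0),
    two_residue_peptide = list(b0 = 0.15, kb = 1e4,
                               theta0 = acos(-1 / 3), ktheta = 400,
                               sigma = 0.25, epsilon = 0.2,
                               charges = c(0.3, -0.3, 0.1,
                                           -0.1, 0.3, -0.3)))
  unknown <- setdiff(names(parameters), names(defaults))
  if (length(unknown))
    stop_validation("unknown parameter(s) for ", kind, ": ",
                    paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, parameters)
  n_default <- switch(kind, lj_dimer = 2L, charged_dimer = 2L,
                      linear_chain = 8L, bent_triple = 3L,
                      dihedral_quad = 4L, two_residue_peptide = 6L)
  n <- if (is.null(n_atoms)) n_default else as.integer(n_atoms)
  if (kind != "linear_chain") n <- n_default
  if (kind == "linear_chain" && n < 2)
    stop_validation("linear_chain needs at least 2 atoms")
  structure(list(kind = kind, n_atoms = n, parameters = p,
                 seed = as.integer(seed), thermal_sigma = thermal_sigma,
                 n_frames = n_frames, n_runs = as.integer(n_runs)),
            class = "toy_spec")
}

.make_atoms <- function(n, resid, charge, sigma, epsilon,
                        resname = "TOY") {
  data.frame(index = seq_len(n) - 1L,
             name = sprintf("C%d", seq_len(n)),
             resid = as.integer(resid),
             resname = rep_len(resname, n),
             charge = rep_len(charge, n),
             sigma = rep_len(sigma, n),
             epsilon = rep_len(epsilon, n),
             stringsAsFactors = FALSE)
}

.empty_bonds <- data.frame(i = integer(), j = integer(), b0 = numeric(),
                           kb = numeric())
.empty_angles <- data.frame(i = integer(), j = integer(), k = integer(),
                            theta0 = numeric(), ktheta = numeric())
.empty_dihedrals <- data.frame(i = integer(), j = integer(), k = integer(),
                               l = integer(), kphi = numeric(),
                               mult = integer(), phase = numeric())

.new_topology <- function(atoms, bonds = .empty_bonds,
                          angles = .empty_angles,
                          dihedrals = .empty_dihedrals,
                          exclusions = NULL) {
  if (is.null(exclusions)) exclusions <- derive_exclusions(bonds)
  top <- structure(list(atoms = atoms, bonds = bonds, angles = angles,
                        dihedrals = dihedrals, exclusions = exclusions),
                   class = "fda_topology", auto_exclusions = TRUE)
  validate_topology(top)
  top
}

# planar zigzag with bond length b and bend angle theta; trans dihedrals
.zigzag_coords <- function(n, b, theta) {
  s <- sin(theta / 2); cc <- cos(theta / 2)
  k <- seq_len(n) - 1
  cbind(k * b * s, (k %% 2) * b * cc, rep(0, n))
}

#' Build a toy system
#'
#' Constructs the topology and equilibrium (or reference) coordinates for
#' a [toy_system_spec()]. For the deterministic mechanical kinds
#' (`lj_dimer`, default `linear_chain`, `bent_triple`, `dihedral_quad`)
#' the coordinates are a stationary point of the implemented potential;
#' the charged chain is relaxed numerically so this remains true when
#' non-bonded terms are enabled. `charged_dimer` and
#' `two_residue_peptide` are reference geometries, not minima.
#'
#' @param spec A `toy_spec`.
#' @param cutoff Non-bonded cutoff (nm) used when relaxing charged
#'   systems.
#' @return List with elements `topology` (`fda_topology`) and `coords`
#'   (n x 3 matrix, nm).
#' @export
build_system <- function(spec, cutoff = 1.0) {
  if (!inherits(spec, "toy_spec")) stop_validation("spec must be a toy_spec")
  p <- spec$parameters
  n <- spec$n_atoms
  switch(spec$kind,
    lj_dimer = {
      atoms <- .make_atoms(2, c(0L, 1L), 0, p$sigma, p$epsilon)
      # the analytic minimum separation; the evaluated force there is a
      # rounding-level residual (the exact zero is not representable)
      coords <- rbind(c(0, 0, 0), c(2^(1 / 6) * p$sigma, 0, 0))
      list(topology = .new_topology(atoms), coords = coords)
    },
    charged_dimer = {
      atoms <- .make_atoms(2, c(0L, 1L), c(p$q, -p$q), p$sigma, p$epsilon)
      coords <- rbind(c(0, 0, 0), c(p$r, 0, 0))
      list(topology = .new_topology(atoms), coords = coords)
    },
    linear_chain = {
      charges <- if (p$charge != 0) p$charge * (-1)^(seq_len(n) - 1) else 0
      atoms <- .make_atoms(n, (seq_len(n) - 1L) %/% 2L, charges,
                           p$sigma, p$epsilon, resname = "CHN")
      bonds <- data.frame(i = 0:(n - 2), j = 1:(n - 1), b0 = p$b0,
                          kb = p$kb)
      angles <- if (n >= 3)
        data.frame(i = 0:(n - 3), j = 1:(n - 2), k = 2:(n - 1),
                   theta0 = p$theta0, ktheta = p$ktheta)
        else .empty_angles
      dihedrals <- if (n >= 4)
        data.frame(i = 0:(n - 4), j = 1:(n - 3), k = 2:(n - 2),
                   l = 3:(n - 1), kphi = p$kphi, mult = p$mult,
                   phase = p$phase)
        else .empty_dihedrals
      top <- .new_topology(atoms, bonds, angles, dihedrals)
      x <- solve_chain_positions(top, tension = 0, cutoff = cutoff)
      list(topology = top, coords = cbind(x, 0, 0))
    },
    bent_triple = {
      atoms <- .make_atoms(3, c(0L, 1L, 2L), 0, p$sigma, p$epsilon)
      bonds <- data.frame(i = c(0L, 1L), j = c(1L, 2L), b0 = p$b0,
                          kb = p$kb)
      angles <- data.frame(i = 0L, j = 1L, k = 2L, theta0 = p$theta0,
                           ktheta = p$ktheta)
      coords <- rbind(c(p$b0, 0, 0), c(0, 0, 0),
                      c(p$b0 * cos(p$theta0), p$b0 * sin(p$theta0), 0))
      list(topology = .new_topology(atoms, bonds, angles), coords = coords)
    },
    dihedral_quad = {
      atoms <- .make_atoms(4, c(0L, 1L, 2L, 3L), 0, p$sigma, p$epsilon)
      bonds <- data.frame(i = 0:2, j = 1:3, b0 = p$b0, kb = p$kb)
      angles <- data.frame(i = 0:1, j = 1:2, k = 2:3, theta0 = p$theta0,
                           ktheta = p$ktheta)
      dihedrals <- data.frame(i = 0L, j = 1L, k = 2L, l = 3L,
                              kphi = p$kphi, mult = p$mult,
                              phase = p$phase)
      coords <- .zigzag_coords(4, p$b0, p$theta0)
      list(topology = .new_topology(atoms, bonds, angles, dihedrals),
           coords = coords)
    },
    two_residue_peptide = {
      atoms <- .make_atoms(6, c(0L, 0L, 0L, 1L, 1L, 1L), p$charges,
                           p$sigma, p$epsilon, resname = c("RSA", "RSB"))
      atoms$resname <- rep(c("RSA", "RSB"), each = 3)
      bonds <- data.frame(i = 0:4, j = 1:5, b0 = p$b0, kb = p$kb)
      angles <- data.frame(i = 0:3, j = 1:4, k = 2:5, theta0 = p$theta0,
                           ktheta = p$ktheta)
      coords <- .zigzag_coords(6, p$b0, p$theta0)
      list(topology = .new_topology(atoms, bonds, angles), coords = coords)
    })
}

# Net axial force on every atom of a collinear chain at positions x,
# including bonds and (non-excluded) Coulomb/LJ within the cutoff.
# Angle terms are at theta = pi and contribute nothing along the axis;
# chain dihedrals have kphi = 0 by construction.
.chain_axial_forces <- function(x, top, cutoff) {
  n <- length(x)
  f <- numeric(n)
  b <- top$bonds
  for (q in seq_len(nrow(b))) {
    i <- b$i[q] + 1L; j <- b$j[q] + 1L
    r <- abs(x[j] - x[i])
    fs <- bond_pair_force(r, b$b0[q], b$kb[q])  # positive = repulsive
    dir <- sign(x[i] - x[j])
    f[i] <- f[i] + fs * dir
    f[j] <- f[j] - fs * dir
  }
  at <- top$atoms
  excl <- paste(top$exclusions$i, top$exclusions$j)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (paste(i - 1L, j - 1L) %in% excl) next
    r <- abs(x[j] - x[i])
    if (r > cutoff || r == 0) next
    fs <- 0
    if (at$charge[i] * at$charge[j] != 0)
      fs <- fs + coulomb_pair_force(r, at$charge[i], at$charge[j])
    lb <- .lb_combine(at$sigma[i], at$sigma[j], at$epsilon[i], at$epsilon[j])
    if (lb$epsilon > 0) fs <- fs + lj_pair_force(r, lb$sigma, lb$epsilon)
    dir <- sign(x[i] - x[j])
    f[i] <- f[i] + fs * dir
    f[j] <- f[j] - fs * dir
  }
  f
}

#' Solve static chain positions under terminal tension
#'
#' Positions of a collinear chain in mechanical equilibrium under a
#' constant external tension `T` pulling the two terminal atoms apart
#' (zero for the free chain). Solved numerically by Newton iteration on
#' the net axial atomic forces — which keeps the solution correct when
#' Coulomb/LJ terms are enabled, where the bonds-only closed form
#' `gap = b0 + T/kb` no longer holds.
#'
#' @param top Chain topology (consecutive bonds along one axis).
#' @param tension External tension in kJ mol^-1 nm^-1 (`>= 0`).
#' @param cutoff Non-bonded cutoff in nm.
#' @param tol Convergence tolerance on the residual net force.
#' @return Numeric vector of axial positions (nm), first atom at 0.
#' @export
solve_chain_positions <- function(top, tension = 0, cutoff = 1.0,
                                  tol = 1e-10) {
  n <- n_atoms(top)
  b0 <- if (nrow(top$bonds)) top$bonds$b0[1] else 0.15
  x <- c(0, cumsum(rep(b0, n - 1)))
  resid <- function(x_free) {
    x_all <- c(0, x_free)
    f <- .chain_axial_forces(x_all, top, cutoff)
    f[1] <- f[1] - tension   # pull ends apart
    f[n] <- f[n] + tension
    f[-1]  # first atom pinned at the origin
  }
  x_free <- x[-1]
  for (iter in 1:60) {
    r <- resid(x_free)
    if (max(abs(r)) < tol) break
    m <- length(x_free)
    Jm <- matrix(0, m, m)
    h <- 1e-7
    for (q in 1:m) {
      xp <- x_free; xm <- x_free
      xp[q] <- xp[q] + h; xm[q] <- xm[q] - h
      Jm[, q] <- (resid(xp) - resid(xm)) / (2 * h)
    }
    step <- tryCatch(solve(Jm, r), error = function(e) qr.solve(Jm, r))
    x_free <- x_free - step
  }
  r <- resid(x_free)
  if (max(abs(r)) >= max(tol, 1e-8))
    stop("chain equilibrium solve did not converge (residual ",
         format(max(abs(r))), ")")
  c(0, x_free)
}

#' Sample thermally jittered frames
#'
#' Adds isotropic i.i.d. Gaussian positional jitter of standard deviation
#' `thermal_sigma` (per coordinate, nm) to the equilibrium coordinates,
#' one independent draw per frame. `thermal_sigma = 0` reproduces the
#' equilibrium exactly in every frame; a fixed seed gives identical
#' output. Frame times are `0, dt, 2 dt, ...` ps.
#'
#' @param coords Equilibrium coordinates (n x 3 matrix, nm).
#' @param thermal_sigma Jitter standard deviation in nm (`>= 0`).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param dt Frame spacing in ps.
#' @return List of frames (`time`, `coords`).
#' @export
sample_frames <- function(coords, thermal_sigma, n_frames, seed, dt = 1) {
  if (thermal_sigma < 0) stop_validation("thermal_sigma must be >= 0")
  n_frames <- as.integer(n_frames)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_frames), function(k) {
    jit <- if (thermal_sigma > 0)
      matrix(stats::rnorm(length(coords), sd = thermal_sigma),
             nrow = nrow(coords))
      else 0
    list(time = (k - 1) * dt, coords = coords + jit)
  })
}

#' Build a reference/perturbed state pair
#'
#' Produces matched inputs for a two-state force-difference experiment:
#' the reference and perturbed systems share everything except the stated
#' perturbation, emulating e.g. a structure with and without external
#' load, or an apo/holo pair.
#'
#' * `charge_change` adds `magnitude` (e) to the charge of one atom
#'   (`parameters$perturb_atom`, default the middle atom); coordinates
#'   are shared, so at zero thermal jitter the force difference is
#'   confined to Coulomb pairs involving that atom.
#' * `external_tension` re-solves the chain equilibrium under a terminal
#'   tension of `magnitude` (kJ mol^-1 nm^-1); topologies are identical.
#' * `parameter_change` adds `magnitude` (nm) to the equilibrium length
#'   `b0` of one bond (default the middle bond); coordinates are shared,
#'   so that bond becomes pre-strained.
#'
#' @param spec A `toy_spec` (chain kinds for tension).
#' @param perturbation One of `"charge_change"`, `"external_tension"`,
#'   `"parameter_change"`.
#' @param magnitude Perturbation size (units above). Zero gives two
#'   identical states.
#' @param perturb_atom,perturb_bond Optional 0-based index selecting the
#'   perturbed atom/bond.
#' @param cutoff Non-bonded cutoff used when re-solving equilibria.
#' @return List with `ref` and `pert` (each `topology` + `coords`),
#'   `perturbation`, `magnitude` and the perturbed index.
#' @export
make_state_pair <- function(spec, perturbation = c("charge_change",
                                                   "external_tension",
                                                   "parameter_change"),
                            magnitude, perturb_atom = NULL,
                            perturb_bond = NULL, cutoff = 1.0) {
  perturbation <- match.arg(perturbation)
  ref <- build_system(spec, cutoff = cutoff)
  n <- n_atoms(ref$topology)
  out <- list(ref = ref, perturbation = perturbation,
              magnitude = magnitude)
  if (perturbation == "charge_change") {
    a <- if (is.null(perturb_atom)) n %/% 2L else as.integer(perturb_atom)
    if (a < 0 || a >= n) stop_validation("perturb_atom out of range")
    pt <- ref$topology
    pt$atoms$charge[a + 1L] <- pt$atoms$charge[a + 1L] + magnitude
    out$pert <- list(topology = pt, coords = ref$coords)
    out$perturbed_index <- a
  } else if (perturbation == "external_tension") {
    if (spec$kind != "linear_chain")
      stop_validation("external_tension applies to linear_chain systems")
    if (magnitude < 0) stop_validation("tension must be >= 0")
    x <- solve_chain_positions(ref$topology, tension = magnitude,
                               cutoff = cutoff)
    out$pert <- list(topology = ref$topology, coords = cbind(x, 0, 0))
  } else {
    if (nrow(ref$topology$bonds) == 0)
      stop_validation("parameter_change needs a bonded system")
    bq <- if (is.null(perturb_bond)) nrow(ref$topology$bonds) %/% 2L + 1L
          else as.integer(perturb_bond) + 1L
    if (bq < 1 || bq > nrow(ref$topology$bonds))
      stop_validation("perturb_bond out of range")
    pt <- ref$topology
    pt$bonds$b0[bq] <- pt$bonds$b0[bq] + magnitude
    out$pert <- list(topology = pt, coords = ref$coords)
    out$perturbed_index <- bq - 1L
  }
  out
}

#' Run a multi-run two-state sampling experiment
#'
#' Convenience driver for signal-detection experiments: samples
#' `spec$n_runs` independent jittered runs of `spec$n_frames` frames for
#' both states of a [make_state_pair()], computes pair forces for every
#' run, and returns the per-run force trajectories. Run seeds are derived
#' deterministically from `spec$seed` (reference runs first).
#'
#' @param pair A [make_state_pair()] result.
#' @param spec The `toy_spec` the pair was built from.
#' @param options [engine_options()] for the force computation.
#' @return List with `ref` and `pert`, each a list of
#'   [force_trajectory()] objects (one per run).
#' @export
sample_experiment <- function(pair, spec, options = engine_options()) {
  run <- function(state, run_idx, offset) {
    frames <- sample_frames(state$coords, spec$thermal_sigma,
                            spec$n_frames,
                            seed = spec$seed + offset + run_idx)
    run_fda(frames, state$topology, options)
  }
  list(ref = lapply(seq_len(spec$n_runs), function(r)
         run(pair$ref, r, 0L)),
       pert = lapply(seq_len(spec$n_runs), function(r)
         run(pair$pert, r, 1000L)))
}
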
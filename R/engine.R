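#' Engine options
#'
#' Parameters of the pair-force computation.
#'
#' @param cutoff Non-bonded cutoff in nm (`> 0`). Pairs farther apart than
#'   this receive no Coulomb/LJ entry. Default 1.0 nm, the typical cutoff
#'   at which truncated Coulomb is an acceptable stand-in for long-range
#'   electrostatics.
#' @param output_interval Number of frames averaged into each stored block
#'   (`>= 1`). With an interval larger than one, forces are arithmetic
#'   means over the interval, with pairs absent in a frame contributing
#'   zero.
#' @param include_types Interaction types to compute, as names or codes;
#'   default all five.
#' @return An object of class `engine_options`.
#' @export
engine_options <- function(cutoff = 1.0, output_interval = 1L,
                           include_types = names(interaction_types())) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) ||
      cutoff <= 0)
    stop_validation("cutoff must be a positive number")
  output_interval <- as.integer(output_interval)
  if (is.na(output_interval) || output_interval < 1)
    stop_validation("output_interval must be >= 1")
  types <- if (is.character(include_types)) .type_code(include_types)
           else as.integer(include_types)
  if (length(types) == 0 || !all(types %in% interaction_types()))
    stop_validation("include_types must be a non-empty subset of the ",
                    "interaction types")
  structure(list(cutoff = cutoff, output_interval = output_interval,
                 include_types = sort(unique(types))),
            class = "engine_options")
}

# Lorentz-Berthelot combination for unlike atoms
.lb_combine <- function(s1, s2, e1, e2) {
  list(sigma = (s1 + s2) / 2, epsilon = sqrt(e1 * e2))
}

#' Compute pair-wise forces for one frame
#'
#' Evaluates every interaction of the topology at the frame's coordinates
#' and returns the sparse signed pair-force matrix: one BOND entry per
#' bond, one ANGLE entry per non-degenerate angle (projected onto the i-k
#' axis), one DIHEDRAL entry per non-degenerate proper dihedral (projected
#' onto i-l), and COULOMB plus LJ entries for every non-excluded pair
#' within the cutoff with a nonzero interaction. Lennard-Jones parameters
#' of unlike atoms are combined by Lorentz-Berthelot rules. Contributions
#' from multiple bonded terms to the same (pair, type) are summed; exact
#' zeros are not stored. Degenerate multi-body geometries are skipped with
#' a warning, never an error.
#'
#' @param frame A trajectory frame (list with `time`, `coords`).
#' @param top An `fda_topology`.
#' @param options An [engine_options()] object.
#' @return A [pairwise_forces()] matrix for the frame.
#' @export
compute_frame <- function(frame, top, options = engine_options()) {
  coords <- frame$coords
  N <- n_atoms(top)
  if (!is.matrix(coords) || nrow(coords) != N || ncol(coords) != 3)
    stop_validation("frame coordinates must be an n_atoms x 3 matrix")
  if (!all(is.finite(coords)))
    stop_validation("frame contains non-finite coordinates")
  types <- options$include_types
  tt <- interaction_types()
  ei <- integer(); ej <- integer(); et <- integer(); ef <- numeric()
  add <- function(i, j, type, f) {
    keep <- is.finite(f)
    ei <<- c(ei, pmin(i, j)[keep])
    ej <<- c(ej, pmax(i, j)[keep])
    et <<- c(et, rep(type, sum(keep)))
    ef <<- c(ef, f[keep])
  }

  if (tt[["BOND"]] %in% types && nrow(top$bonds)) {
    b <- top$bonds
    dr <- coords[b$i + 1L, , drop = FALSE] - coords[b$j + 1L, , drop = FALSE]
    r <- sqrt(rowSums(dr^2))
    add(b$i, b$j, tt[["BOND"]], bond_pair_force(r, b$b0, b$kb))
  }
  if (tt[["ANGLE"]] %in% types && nrow(top$angles)) {
    g <- top$angles
    for (q in seq_len(nrow(g))) {
      f <- angle_pair_force(coords[g$i[q] + 1L, ], coords[g$j[q] + 1L, ],
                            coords[g$k[q] + 1L, ], g$theta0[q], g$ktheta[q])
      if (!is.na(f)) add(g$i[q], g$k[q], tt[["ANGLE"]], f)
    }
  }
  if (tt[["DIHEDRAL"]] %in% types && nrow(top$dihedrals)) {
    d <- top$dihedrals
    for (q in seq_len(nrow(d))) {
      f <- dihedral_pair_force(coords[d$i[q] + 1L, ], coords[d$j[q] + 1L, ],
                               coords[d$k[q] + 1L, ], coords[d$l[q] + 1L, ],
                               d$kphi[q], d$mult[q], d$phase[q])
      if (!is.na(f)) add(d$i[q], d$l[q], tt[["DIHEDRAL"]], f)
    }
  }

  want_coul <- tt[["COULOMB"]] %in% types
  want_lj <- tt[["LJ"]] %in% types
  if ((want_coul || want_lj) && N >= 2) {
    pi_ <- rep(0:(N - 2), times = (N - 1):1)
    pj_ <- unlist(lapply(1:(N - 1), function(a) a:(N - 1)))
    excl_keys <- top$exclusions$i * N + top$exclusions$j
    keep <- !(pi_ * N + pj_) %in% excl_keys
    pi_ <- pi_[keep]; pj_ <- pj_[keep]
    if (length(pi_)) {
      dr <- coords[pi_ + 1L, , drop = FALSE] - coords[pj_ + 1L, , drop = FALSE]
      r <- sqrt(rowSums(dr^2))
      inr <- r <= options$cutoff & r > 0
      pi_ <- pi_[inr]; pj_ <- pj_[inr]; r <- r[inr]
      if (length(r)) {
        at <- top$atoms
        if (want_coul) {
          qq <- at$charge[pi_ + 1L] * at$charge[pj_ + 1L]
          nz <- qq != 0
          if (any(nz))
            add(pi_[nz], pj_[nz], tt[["COULOMB"]],
                coulomb_pair_force(r[nz], at$charge[pi_[nz] + 1L],
                                   at$charge[pj_[nz] + 1L]))
        }
        if (want_lj) {
          lb <- .lb_combine(at$sigma[pi_ + 1L], at$sigma[pj_ + 1L],
                            at$epsilon[pi_ + 1L], at$epsilon[pj_ + 1L])
          nz <- lb$epsilon > 0
          if (any(nz))
            add(pi_[nz], pj_[nz], tt[["LJ"]],
                lj_pair_force(r[nz], lb$sigma[nz], lb$epsilon[nz]))
        }
      }
    }
  }

  # sum duplicate (i, j, type) contributions, drop exact zeros
  if (length(ei)) {
    key <- .entry_key(ei, ej, et, N)
    agg <- rowsum(ef, group = key)
    k <- as.numeric(rownames(agg))
    f <- agg[, 1]
    nz <- f != 0
    dec <- .key_decode(k[nz], N)
    pairwise_forces(frame$time, dec$i, dec$j, dec$type, unname(f[nz]))
  } else {
    pairwise_forces(frame$time)
  }
}

#' Run force distribution analysis over a trajectory
#'
#' Computes pair-wise forces for every frame and accumulates them into a
#' force trajectory with one block per `output_interval` consecutive
#' frames. Each stored value is the arithmetic mean of the pair's
#' per-frame values over the interval (a pair absent in a frame
#' contributes zero there); the block time stamp is the first frame's
#' time. A trailing partial interval is averaged over its actual length.
#'
#' @param frames List of trajectory frames.
#' @param top An `fda_topology`.
#' @param options An [engine_options()] object.
#' @return A [force_trajectory()] in atom syntax.
#' @export
run_fda <- function(frames, top, options = engine_options()) {
  if (length(frames) < 1) stop_validation("need at least one frame")
  N <- n_atoms(top)
  iv <- options$output_interval
  starts <- seq(1L, length(frames), by = iv)
  blocks <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w]:min(starts[w] + iv - 1L, length(frames))
    mats <- lapply(frames[idx], compute_frame, top = top, options = options)
    if (length(idx) == 1L) {
      blocks[[w]] <- mats[[1]]
    } else {
      key <- unlist(lapply(mats, function(m) .entry_key(m$i, m$j, m$type, N)))
      val <- unlist(lapply(mats, function(m) m$force))
      if (length(key)) {
        agg <- rowsum(val, group = key) / length(idx)
        k <- as.numeric(rownames(agg))
        f <- agg[, 1]
        nz <- f != 0
        dec <- .key_decode(k[nz], N)
        blocks[[w]] <- pairwise_forces(frames[[idx[1]]]$time, dec$i, dec$j,
                                       dec$type, unname(f[nz]))
      } else {
        blocks[[w]] <- pairwise_forces(frames[[idx[1]]]$time)
      }
    }
  }
  force_trajectory(blocks, N, "atom")
}

#' Dense matrix export with the triangle convention
#'
#' Exports one pair-force block as a dense `N x N` matrix using the
#' historical triangle convention for the non-bonded types: the upper
#' triangle (column > row) holds van der Waals forces, the lower triangle
#' (row > column) holds Coulomb forces. Bonded types are not part of this
#' convention and are not included.
#'
#' @param block A [pairwise_forces()] object.
#' @param n Number of atoms.
#' @return A dense `n x n` numeric matrix.
#' @export
dense_nonbonded_matrix <- function(block, n) {
  tt <- interaction_types()
  m <- matrix(0, n, n)
  lj <- block$type == tt[["LJ"]]
  cl <- block$type == tt[["COULOMB"]]
  m[cbind(block$i[lj] + 1L, block$j[lj] + 1L)] <- block$force[lj]
  m[cbind(block$j[cl] + 1L, block$i[cl] + 1L)] <- block$force[cl]
  m
}
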
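# Statistics on force trajectories: time averages, cross-run standard
# errors, force differences between states, noise normalization,
# projections and aggregations. Sparse entries are manipulated as data
# frames keyed by (i, j, type); a pair absent from a block or run is an
# exact zero by construction, and all averages/differences honour that.

.entries_df <- function(block, N) {
  data.frame(key = .entry_key(block$i, block$j, block$type, N),
             force = block$force)
}

.df_from_keys <- function(key, N, ...) {
  dec <- .key_decode(key, N)
  out <- data.frame(i = dec$i, j = dec$j, type = dec$type, ...)
  out[order(out$i, out$j, out$type), , drop = FALSE]
}

#' Concatenate force trajectories
#'
#' Joins the blocks of several runs of the same system into one force
#' trajectory (in run order), e.g. to average over all sampling at once.
#' For equal-length runs, the average of the concatenation equals the
#' mean of the per-run averages.
#'
#' @param trajs List of [force_trajectory()] objects sharing `n_atoms`
#'   and syntax.
#' @return A single `force_trajectory`.
#' @export
concatenate_trajectories <- function(trajs) {
  if (!is.list(trajs) || length(trajs) == 0)
    stop_validation("need at least one trajectory")
  N <- unique(vapply(trajs, function(t) t$n_atoms, 0L))
  syn <- unique(vapply(trajs, function(t) t$syntax, ""))
  if (length(N) != 1 || length(syn) != 1)
    stop_validation("trajectories disagree on n_atoms or syntax")
  force_trajectory(do.call(c, lapply(trajs, function(t) t$blocks)), N, syn)
}

#' Average a force trajectory over its blocks
#'
#' Per-pair (and per interaction type) arithmetic mean and population
#' variance over all blocks of a force trajectory; a pair absent from a
#' block counts as zero there. With `combine_types = TRUE` the interaction
#' types of each pair are summed within every block before averaging, so
#' the result has one entry per pair (reported with type code 0).
#'
#' @param traj A [force_trajectory()].
#' @param combine_types Sum interaction types per pair before averaging?
#' @return An object of class `avg_forces`: data frame with columns `i`,
#'   `j`, `type`, `mean`, `var`, plus attributes `n_atoms` and `n_blocks`.
#' @export
average_trajectory <- function(traj, combine_types = FALSE) {
  if (!inherits(traj, "force_trajectory"))
    stop_validation("traj must be a force_trajectory")
  nb <- length(traj$blocks)
  if (nb == 0) stop_validation("empty trajectory")
  N <- traj$n_atoms
  df <- do.call(rbind, lapply(traj$blocks, .entries_df, N = N))
  if (is.null(df) || nrow(df) == 0) {
    out <- data.frame(i = integer(), j = integer(), type = integer(),
                      mean = numeric(), var = numeric())
  } else {
    if (combine_types) df$key <- (df$key %/% 8) * 8  # type slot 0
    s1 <- rowsum(df$force, df$key)
    s2 <- rowsum(df$force^2, df$key)
    key <- as.numeric(rownames(s1))
    mn <- s1[, 1] / nb
    vr <- pmax(0, s2[, 1] / nb - mn^2)
    out <- .df_from_keys(key, N, mean = unname(mn), var = unname(vr))
    out <- out[out$mean != 0 | out$var != 0, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("avg_forces", "data.frame"),
            n_atoms = N, n_blocks = nb)
}

#' Cross-run standard error of average forces
#'
#' Given per-run averaged force matrices from independent trajectories of
#' the same system, computes for every pair the standard error of the run
#' means: sample standard deviation across runs (denominator `n - 1`)
#' divided by `sqrt(n_runs)`. A pair absent from a run enters as zero.
#' This is the noise scale used to normalize force differences.
#'
#' @param run_means List of at least two `avg_forces` objects with equal
#'   `n_atoms`.
#' @return An object of class `stderr_forces`: data frame with columns
#'   `i`, `j`, `type`, `eps`, plus attributes `n_atoms` and `n_runs`.
#' @export
standard_error <- function(run_means) {
  if (!is.list(run_means) || length(run_means) < 2)
    stop_validation("need at least 2 runs")
  Ns <- vapply(run_means, function(x) as.integer(attr(x, "n_atoms")), 0L)
  if (length(unique(Ns)) != 1)
    stop_validation("runs disagree on n_atoms")
  N <- Ns[1]
  n <- length(run_means)
  df <- do.call(rbind, lapply(run_means, function(x)
    data.frame(key = .entry_key(x$i, x$j, x$type, N), force = x$mean)))
  if (is.null(df) || nrow(df) == 0) {
    out <- data.frame(i = integer(), j = integer(), type = integer(),
                      eps = numeric())
  } else {
    s1 <- rowsum(df$force, df$key)
    s2 <- rowsum(df$force^2, df$key)
    key <- as.numeric(rownames(s1))
    mn <- s1[, 1] / n
    ss <- pmax(0, s2[, 1] - n * mn^2)  # sum of squared deviations, absent = 0
    eps <- sqrt(ss / (n - 1)) / sqrt(n)
    out <- .df_from_keys(key, N, eps = unname(eps))
    rownames(out) <- NULL
  }
  structure(out, class = c("stderr_forces", "data.frame"),
            n_atoms = N, n_runs = n)
}

#' Combine per-state standard errors for a force difference
#'
#' The sampling noise of a difference of two independent state means is
#' the quadrature sum of the per-state standard errors:
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_{ij}^{ref\,2} +
#' \epsilon_{ij}^{pert\,2}}}. Normalizing \eqn{\Delta F} by a standard
#' error pooled naively across runs of *both* states would fold the
#' signal itself into the noise estimate and cap the detectable
#' normalized change; combining the within-state errors keeps the
#' normalization a pure noise scale.
#'
#' @param eps_ref,eps_pert [standard_error()] matrices of the two states.
#' @return A `stderr_forces` object over the union of pairs (a pair
#'   absent from one state contributes zero error for that state).
#' @export
combine_standard_errors <- function(eps_ref, eps_pert) {
  N <- as.integer(attr(eps_ref, "n_atoms"))
  if (!identical(N, as.integer(attr(eps_pert, "n_atoms"))))
    stop_validation("states disagree on n_atoms")
  df <- rbind(
    data.frame(key = .entry_key(eps_ref$i, eps_ref$j, eps_ref$type, N),
               e2 = eps_ref$eps^2),
    data.frame(key = .entry_key(eps_pert$i, eps_pert$j, eps_pert$type, N),
               e2 = eps_pert$eps^2))
  if (nrow(df) == 0) {
    out <- data.frame(i = integer(), j = integer(), type = integer(),
                      eps = numeric())
  } else {
    s <- rowsum(df$e2, df$key)
    out <- .df_from_keys(as.numeric(rownames(s)), N,
                         eps = sqrt(unname(s[, 1])))
    rownames(out) <- NULL
  }
  structure(out, class = c("stderr_forces", "data.frame"), n_atoms = N,
            n_runs = min(attr(eps_ref, "n_runs"), attr(eps_pert, "n_runs")))
}

#' Force difference between two states
#'
#' Per-pair signed difference of time-averaged forces,
#' \eqn{\Delta F_{ij} = F_{ij}^{pert} - F_{ij}^{ref}}, the quantity that
#' makes parts under changed mechanical strain visible. A pair absent
#' from one state contributes zero for that state. Comparing two
#' independent runs of the *same* state yields the noise difference
#' \eqn{\Delta F^{noise} = F^{ref} - F^{ref'}}; pass `kind = "noise"` to
#' label such a map.
#'
#' @param ref,pert `avg_forces` objects with equal `n_atoms` (`ref` is
#'   subtracted from `pert`).
#' @param kind `"raw"` for a perturbed-minus-reference difference,
#'   `"noise"` for a reference-minus-reference null map.
#' @return An object of class `delta_forces`: data frame with columns
#'   `i`, `j`, `type`, `delta`, attributes `n_atoms` and `kind`.
#' @export
delta_force <- function(ref, pert, kind = c("raw", "noise")) {
  kind <- match.arg(kind)
  N <- as.integer(attr(ref, "n_atoms"))
  if (!identical(N, as.integer(attr(pert, "n_atoms"))))
    stop_validation("states disagree on n_atoms")
  a <- data.frame(key = .entry_key(pert$i, pert$j, pert$type, N),
                  force = pert$mean)
  b <- data.frame(key = .entry_key(ref$i, ref$j, ref$type, N),
                  force = -ref$mean)
  df <- rbind(a, b)
  if (nrow(df) == 0) {
    out <- data.frame(i = integer(), j = integer(), type = integer(),
                      delta = numeric())
  } else {
    s <- rowsum(df$force, df$key)
    key <- as.numeric(rownames(s))
    d <- s[, 1]
    nz <- d != 0
    out <- .df_from_keys(key[nz], N, delta = unname(d[nz]))
    rownames(out) <- NULL
  }
  structure(out, class = c("delta_forces", "data.frame"),
            n_atoms = N, kind = kind, n_dropped = 0L)
}

#' Normalize a force difference by the cross-run standard error
#'
#' \eqn{\Delta f_{ij} = \Delta F_{ij} / \epsilon_{ij}}: expressing each
#' force change in units of its own sampling noise improves the signal
#' quality when runs are few. Pairs whose standard error is zero (or
#' missing from `eps`) cannot be normalized; they are dropped and counted
#' in the `n_dropped` attribute of the result.
#'
#' @param delta A `delta_forces` map of kind `"raw"` or `"noise"`.
#' @param eps A [standard_error()] matrix.
#' @return A `delta_forces` object with `kind = "normalized"` (or
#'   `"noise_normalized"` when the input was a noise map) and attribute
#'   `n_dropped`.
#' @export
normalize_delta <- function(delta, eps) {
  N <- as.integer(attr(delta, "n_atoms"))
  if (!identical(N, as.integer(attr(eps, "n_atoms"))))
    stop_validation("delta and eps disagree on n_atoms")
  if (attr(delta, "kind") %in% c("normalized", "noise_normalized"))
    stop_validation("delta is already normalized")
  dk <- .entry_key(delta$i, delta$j, delta$type, N)
  ek <- .entry_key(eps$i, eps$j, eps$type, N)
  pos <- match(dk, ek)
  e <- ifelse(is.na(pos), 0, eps$eps[pos])
  keep <- e > 0
  out <- data.frame(i = delta$i[keep], j = delta$j[keep],
                    type = delta$type[keep],
                    delta = delta$delta[keep] / e[keep])
  rownames(out) <- NULL
  kind <- if (attr(delta, "kind") == "noise") "noise_normalized"
          else "normalized"
  structure(out, class = c("delta_forces", "data.frame"),
            n_atoms = N, kind = kind, n_dropped = sum(!keep))
}

#' Project a pair-wise force map onto atoms
#'
#' The absolute column sum \eqn{\Delta F_j = \sum_i |\Delta F_{ij}|}:
#' each atom receives the summed magnitudes of all pair entries it
#' participates in, over all interaction types. Absolute values prevent
#' opposing force changes from cancelling; the result is the per-atom
#' mechanical coupling typically written to PDB b-factors.
#'
#' @param delta A `delta_forces` (or `avg_forces`, using its `mean`
#'   column) object.
#' @return Numeric vector of length `n_atoms`, all entries `>= 0`.
#' @export
atom_projection <- function(delta) {
  N <- as.integer(attr(delta, "n_atoms"))
  val <- if ("delta" %in% names(delta)) delta$delta else delta$mean
  out <- numeric(N)
  if (length(val)) {
    s <- rowsum(c(abs(val), abs(val)), c(delta$i, delta$j))
    at <- as.integer(rownames(s)) + 1L
    out[at] <- s[, 1]
  }
  out
}

.resid_of <- function(top) top$atoms$resid

#' Sum pair-wise forces between residues (scalar mode)
#'
#' Aggregates an atom-pair force map to residue pairs:
#' \eqn{F_{uv} = \sum_{i \in u, j \in v} F_{ij}}, for `u < v`;
#' intra-residue pairs are excluded by default. Because the summands are
#' scalar norms rather than vectors the result is an approximation, but
#' an adequate one for ranking residue couplings; use
#' [residue_sum_vector()] when exact vector sums are needed. The sum can
#' be restricted to interaction types and to an atom group (both atoms of
#' a pair must belong to the group).
#'
#' @param x An `avg_forces` or `delta_forces` object.
#' @param top Matching `fda_topology` (provides the residue map).
#' @param types Optional interaction types (names or codes) to keep.
#' @param atoms Optional 0-based atom indices forming the group filter.
#' @param mode `"signed"` sums signed values; `"abs"` sums magnitudes.
#' @param include_intra Also report `u == v` entries?
#' @return An object of class `residue_forces`: data frame with columns
#'   `u`, `v`, `value`; attribute `n_residues`.
#' @export
residue_sum_scalar <- function(x, top, types = NULL, atoms = NULL,
                               mode = c("signed", "abs"),
                               include_intra = FALSE) {
  mode <- match.arg(mode)
  N <- as.integer(attr(x, "n_atoms"))
  if (!identical(N, n_atoms(top)))
    stop_validation("map and topology disagree on n_atoms")
  val <- if ("delta" %in% names(x)) x$delta else x$mean
  keep <- rep(TRUE, length(val))
  if (!is.null(types)) {
    tc <- if (is.character(types)) .type_code(types) else as.integer(types)
    keep <- keep & x$type %in% tc
  }
  if (!is.null(atoms)) keep <- keep & x$i %in% atoms & x$j %in% atoms
  res <- .resid_of(top)
  u <- res[x$i[keep] + 1L]
  v <- res[x$j[keep] + 1L]
  val <- val[keep]
  if (mode == "abs") val <- abs(val)
  uu <- pmin(u, v); vv <- pmax(u, v)
  if (!include_intra) {
    inter <- uu != vv
    uu <- uu[inter]; vv <- vv[inter]; val <- val[inter]
  }
  nres <- length(unique(res))
  if (length(val)) {
    key <- as.numeric(uu) * nres + vv
    s <- rowsum(val, key)
    k <- as.numeric(rownames(s))
    out <- data.frame(u = as.integer(k %/% nres), v = as.integer(k %% nres),
                      value = unname(s[, 1]))
    out <- out[order(out$u, out$v), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(u = integer(), v = integer(), value = numeric())
  }
  structure(out, class = c("residue_forces", "data.frame"),
            n_residues = nres, mode = "scalar")
}

#' Sum residue-pair force vectors from a force trajectory
#'
#' Restores exact atomic force vectors by multiplying each stored scalar
#' force with the unit coordinate vector between its atoms
#' (\eqn{\vec F_{ij} = F_{ij} \hat u_{ij}}, \eqn{\hat u_{ij}} pointing
#' from `j` to `i`, so that a positive scalar pushes the pair apart),
#' then sums the vectors over all atom pairs between each residue pair.
#' Each force block needs a coordinate frame whose time stamp matches
#' within half the block spacing. Returns x, y, z components and the norm
#' per residue pair and block.
#'
#' @param traj A [force_trajectory()] in atom syntax.
#' @param frames Coordinate frames covering the block times.
#' @param top Matching `fda_topology`.
#' @param types,atoms Optional filters as in [residue_sum_scalar()].
#' @param include_intra Also report `u == v` entries?
#' @return List of `residue_forces` objects (one per block) with columns
#'   `u`, `v`, `x`, `y`, `z`, `norm`.
#' @export
residue_sum_vector <- function(traj, frames, top, types = NULL,
                               atoms = NULL, include_intra = FALSE) {
  N <- traj$n_atoms
  if (!identical(as.integer(N), n_atoms(top)))
    stop_validation("trajectory and topology disagree on n_atoms")
  ft <- vapply(frames, function(f) f$time, 0)
  bt <- vapply(traj$blocks, function(b) b$time, 0)
  tol <- if (length(bt) > 1) min(diff(sort(bt))) / 2
         else if (length(ft) > 1) min(diff(sort(ft))) / 2
         else 0.5
  res <- .resid_of(top)
  nres <- length(unique(res))
  lapply(seq_along(traj$blocks), function(w) {
    b <- traj$blocks[[w]]
    d <- abs(ft - b$time)
    m <- which.min(d)
    if (length(m) == 0 || d[m] > tol)
      stop_validation("no coordinate frame matches block at t = ", b$time)
    coords <- frames[[m]]$coords
    keep <- rep(TRUE, length(b$i))
    if (!is.null(types)) {
      tc <- if (is.character(types)) .type_code(types) else as.integer(types)
      keep <- keep & b$type %in% tc
    }
    if (!is.null(atoms)) keep <- keep & b$i %in% atoms & b$j %in% atoms
    i <- b$i[keep]; j <- b$j[keep]; f <- b$force[keep]
    dr <- coords[i + 1L, , drop = FALSE] - coords[j + 1L, , drop = FALSE]
    nr <- sqrt(rowSums(dr^2))
    ok <- nr > 0
    i <- i[ok]; j <- j[ok]; f <- f[ok]
    uhat <- dr[ok, , drop = FALSE] / nr[ok]
    vec <- uhat * f  # force vector on atom i from atom j
    u <- res[i + 1L]; v <- res[j + 1L]
    # orient every contribution as the force on the lower residue
    flip <- u > v
    vec[flip, ] <- -vec[flip, , drop = FALSE]
    uu <- pmin(u, v); vv <- pmax(u, v)
    if (!include_intra) {
      inter <- uu != vv
      uu <- uu[inter]; vv <- vv[inter]
      vec <- vec[inter, , drop = FALSE]
    }
    if (length(uu)) {
      key <- as.numeric(uu) * nres + vv
      sx <- rowsum(vec[, 1], key); sy <- rowsum(vec[, 2], key)
      sz <- rowsum(vec[, 3], key)
      k <- as.numeric(rownames(sx))
      out <- data.frame(u = as.integer(k %/% nres),
                        v = as.integer(k %% nres),
                        x = unname(sx[, 1]), y = unname(sy[, 1]),
                        z = unname(sz[, 1]))
      out$norm <- sqrt(out$x^2 + out$y^2 + out$z^2)
      out <- out[order(out$u, out$v), , drop = FALSE]
      rownames(out) <- NULL
    } else {
      out <- data.frame(u = integer(), v = integer(), x = numeric(),
                        y = numeric(), z = numeric(), norm = numeric())
    }
    structure(out, class = c("residue_forces", "data.frame"),
              n_residues = nres, mode = "vector", time = b$time)
  })
}

#' Extract a force network
#'
#' Edges between nodes whose absolute force (change) strictly exceeds a
#' cutoff, the standard visualization of strain-propagation pathways. For
#' an atom-pair map the interaction types of each pair are summed first;
#' a residue matrix is thresholded as-is (its `norm` in vector mode).
#' Edge weights keep their sign; edges are ordered by `(i, j)`.
#'
#' @param x A `delta_forces`, `avg_forces` or `residue_forces` object.
#' @param cutoff Non-negative force threshold (strict).
#' @return Data frame with columns `node_i`, `node_j`, `weight`.
#' @export
extract_network <- function(x, cutoff) {
  if (!is.numeric(cutoff) || cutoff < 0)
    stop_validation("cutoff must be >= 0")
  if (inherits(x, "residue_forces")) {
    w <- if (identical(attr(x, "mode"), "vector")) x$norm else x$value
    out <- data.frame(node_i = x$u, node_j = x$v, weight = w)
  } else {
    N <- attr(x, "n_atoms")
    val <- if ("delta" %in% names(x)) x$delta else x$mean
    if (length(val)) {
      key <- as.numeric(x$i) * N + x$j
      s <- rowsum(val, key)
      k <- as.numeric(rownames(s))
      out <- data.frame(node_i = as.integer(k %/% N),
                        node_j = as.integer(k %% N),
                        weight = unname(s[, 1]))
    } else {
      out <- data.frame(node_i = integer(), node_j = integer(),
                        weight = numeric())
    }
  }
  out <- out[abs(out$weight) > cutoff, , drop = FALSE]
  out <- out[order(out$node_i, out$node_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Principal component analysis of force trajectories
#'
#' Treats each block as an observation and each pair (atom pair, or
#' residue pair after scalar aggregation) as a variable, centers the
#' columns, and performs PCA via [stats::prcomp()] (covariance,
#' unscaled: forces share units, and scaling would distort relative
#' coupling strengths). Blocks from multiple runs are concatenated over
#' the union of their pairs, absent entries being exact zeros. Working at
#' residue level shrinks the variable space considerably for large
#' systems and often exposes collective force modes more clearly.
#'
#' @param trajs A [force_trajectory()] or list of them (same `n_atoms`).
#' @param top `fda_topology`, required for `level = "residue_pair"`.
#' @param level `"atom_pair"` or `"residue_pair"`.
#' @return List with `components` (orthonormal loadings, one column per
#'   component), `explained_variance` (non-increasing), `scores` (one row
#'   per block), `pairs` (data frame labelling the variables).
#' @export
pca_forces <- function(trajs, top = NULL,
                       level = c("atom_pair", "residue_pair")) {
  level <- match.arg(level)
  if (inherits(trajs, "force_trajectory")) trajs <- list(trajs)
  N <- unique(vapply(trajs, function(t) t$n_atoms, 0L))
  if (length(N) != 1) stop_validation("trajectories disagree on n_atoms")
  blocks <- do.call(c, lapply(trajs, function(t) t$blocks))
  if (length(blocks) < 2) stop_validation("need at least 2 blocks for PCA")

  if (level == "residue_pair") {
    if (is.null(top)) stop_validation("residue_pair level needs a topology")
    res <- .resid_of(top)
    rows <- lapply(blocks, function(b) {
      u <- res[b$i + 1L]; v <- res[b$j + 1L]
      keep <- u != v
      data.frame(a = pmin(u, v)[keep], b = pmax(u, v)[keep],
                 val = b$force[keep])
    })
    dim_n <- length(unique(res))
  } else {
    rows <- lapply(blocks, function(b)
      data.frame(a = b$i, b = b$j, val = b$force))
    dim_n <- N
  }
  keys <- lapply(rows, function(r) as.numeric(r$a) * dim_n + r$b)
  univ <- sort(unique(unlist(keys)))
  if (length(univ) == 0) stop_validation("no pair entries to analyze")
  X <- matrix(0, nrow = length(blocks), ncol = length(univ))
  for (w in seq_along(rows)) {
    if (nrow(rows[[w]]) == 0) next
    s <- rowsum(rows[[w]]$val, keys[[w]])  # types collapse by summation
    X[w, match(as.numeric(rownames(s)), univ)] <- s[, 1]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(components = p$rotation,
       explained_variance = p$sdev^2,
       scores = p$x,
       pairs = data.frame(a = as.integer(univ %/% dim_n),
                          b = as.integer(univ %% dim_n)))
}
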
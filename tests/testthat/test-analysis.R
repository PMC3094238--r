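pf <- function(time, i = integer(), j = integer(), type = integer(),
               force = numeric())
  pairwise_forces(time, i, j, type, force)

toy_traj <- function(blocks, n = 4) force_trajectory(blocks, n)

test_that("average_trajectory computes means and population variances", {
  # single block: mean equals the block, variance zero
  a1 <- average_trajectory(toy_traj(list(pf(0, 0, 1, 1, 10))))
  expect_equal(a1$mean, 10)
  expect_equal(a1$var, 0)

  # pair present as 10 in one of two blocks: {10, 0} population stats
  a2 <- average_trajectory(toy_traj(list(pf(0, 0, 1, 1, 10),
                                         pf(1))))
  expect_equal(a2$mean, 5)
  expect_equal(a2$var, 25)

  # combine_types sums types within a block before averaging
  b <- pf(0, c(0, 0), c(1, 1), c(4, 5), c(3, -1))
  a3 <- average_trajectory(toy_traj(list(b)), combine_types = TRUE)
  expect_equal(nrow(a3), 1)
  expect_equal(a3$mean, 2)

  expect_error(average_trajectory(toy_traj(list())), "empty")
})

test_that("average_trajectory agrees with a dense-matrix oracle", {
  traj <- random_force_trajectory(25, 12, seed = 61)
  avg <- average_trajectory(traj)
  # dense oracle over (i, j, type) cells
  dense <- array(0, dim = c(25, 12 * 12 * 6))
  for (w in seq_along(traj$blocks)) {
    b <- traj$blocks[[w]]
    idx <- (b$i * 12 + b$j) * 6 + b$type
    dense[w, idx] <- b$force
  }
  for (q in seq_len(nrow(avg))) {
    cell <- dense[, (avg$i[q] * 12 + avg$j[q]) * 6 + avg$type[q]]
    expect_equal(avg$mean[q], mean(cell))
    expect_equal(avg$var[q], mean(cell^2) - mean(cell)^2)
  }
})

test_that("averaging is linear over concatenated equal-length runs", {
  t1 <- random_force_trajectory(10, 8, seed = 71)
  t2 <- random_force_trajectory(10, 8, seed = 72)
  joint <- average_trajectory(concatenate_trajectories(list(t1, t2)))
  a1 <- average_trajectory(t1)
  a2 <- average_trajectory(t2)
  d1 <- delta_force(a1, joint)  # joint - a1
  d2 <- delta_force(joint, a2)  # a2 - joint
  # joint - a1 == a2 - joint  <=>  joint == (a1 + a2) / 2
  expect_equal(d1$i, d2$i)
  expect_equal(d1$delta, d2$delta)
})

test_that("standard_error matches the textbook formula", {
  mk_avg <- function(force, n = 4) {
    structure(data.frame(i = 0L, j = 1L, type = 1L, mean = force, var = 0),
              class = c("avg_forces", "data.frame"), n_atoms = n,
              n_blocks = 1L)
  }
  # identical runs: zero everywhere
  e0 <- standard_error(list(mk_avg(7), mk_avg(7), mk_avg(7)))
  expect_equal(e0$eps, 0)
  # run means {8, 12}: sd = 2 sqrt(2), eps = sd / sqrt(2) = 2
  e1 <- standard_error(list(mk_avg(8), mk_avg(12)))
  expect_equal(e1$eps, 2)
  expect_error(standard_error(list(mk_avg(1))), "at least 2")

  # random inputs against sd()/sqrt(n), absent runs counting as zero
  set.seed(83)
  vals <- rnorm(5, sd = 10)
  runs <- lapply(vals, mk_avg)
  runs[[3]] <- structure(data.frame(i = integer(), j = integer(),
                                    type = integer(), mean = numeric(),
                                    var = numeric()),
                         class = c("avg_forces", "data.frame"),
                         n_atoms = 4L, n_blocks = 1L)
  vals[3] <- 0
  e2 <- standard_error(runs)
  expect_equal(e2$eps, stats::sd(vals) / sqrt(5))
})

test_that("delta_force subtracts states with the absent-equals-zero rule", {
  mk <- function(df, n = 4) structure(df, class = c("avg_forces",
                                                    "data.frame"),
                                      n_atoms = n, n_blocks = 1L)
  ref <- mk(data.frame(i = 0L, j = 1L, type = 1L, mean = 10, var = 0))
  pert <- mk(data.frame(i = c(0L, 0L), j = c(1L, 2L), type = c(1L, 1L),
                        mean = c(14, 3), var = c(0, 0)))
  d <- delta_force(ref, pert)
  expect_equal(d$delta[d$j == 1], 4)
  expect_equal(d$delta[d$j == 2], 3)   # only in pert: 3 - 0
  # identical inputs give an empty map
  expect_equal(nrow(delta_force(ref, ref)), 0)
  # antisymmetry
  d2 <- delta_force(pert, ref)
  expect_equal(d2$delta, -d$delta)
  expect_error(delta_force(ref, mk(data.frame(i = 0L, j = 1L, type = 1L,
                                              mean = 1, var = 0), n = 9)),
               "n_atoms")
})

test_that("normalize_delta divides by eps and drops eps = 0 pairs", {
  d <- structure(data.frame(i = c(0L, 0L), j = c(1L, 2L),
                            type = c(1L, 1L), delta = c(4, 4)),
                 class = c("delta_forces", "data.frame"), n_atoms = 4L,
                 kind = "raw", n_dropped = 0L)
  e <- structure(data.frame(i = c(0L, 0L), j = c(1L, 2L),
                            type = c(1L, 1L), eps = c(2, 0)),
                 class = c("stderr_forces", "data.frame"), n_atoms = 4L,
                 n_runs = 3L)
  nd <- normalize_delta(d, e)
  expect_equal(nrow(nd), 1)
  expect_equal(nd$delta, 2)
  expect_equal(attr(nd, "n_dropped"), 1L)
  expect_equal(attr(nd, "kind"), "normalized")
})

test_that("combined per-state errors add in quadrature over the pair union", {
  mk_eps <- function(i, j, eps) structure(
    data.frame(i = i, j = j, type = 1L, eps = eps),
    class = c("stderr_forces", "data.frame"), n_atoms = 4L, n_runs = 3L)
  ce <- combine_standard_errors(mk_eps(0L, 1L, 3), mk_eps(c(0L, 0L),
                                                          c(1L, 2L),
                                                          c(4, 5)))
  expect_equal(ce$eps[ce$j == 1], 5)     # sqrt(9 + 16)
  expect_equal(ce$eps[ce$j == 2], 5)     # only one state contributes
})

test_that("atom projection is the absolute column sum", {
  d <- structure(data.frame(i = c(0L, 0L), j = c(1L, 2L),
                            type = c(1L, 1L), delta = c(3, -4)),
                 class = c("delta_forces", "data.frame"), n_atoms = 3L,
                 kind = "raw", n_dropped = 0L)
  expect_equal(atom_projection(d), c(7, 3, 4))
  # sign-flip invariance
  d2 <- d; d2$delta <- -d2$delta
  expect_equal(atom_projection(d2), atom_projection(d))
  # empty map projects to exact zeros
  d0 <- d[0, ]
  attr(d0, "n_atoms") <- 3L
  class(d0) <- c("delta_forces", "data.frame")
  expect_identical(atom_projection(d0), c(0, 0, 0))
})

test_that("residue scalar sums aggregate, filter and exclude intra pairs", {
  sys <- build_system(toy_system_spec("two_residue_peptide"))
  mk <- function(df) structure(df, class = c("avg_forces", "data.frame"),
                               n_atoms = 6L, n_blocks = 1L)
  # atoms 0-2 in residue 0; atoms 3-5 in residue 1
  x <- mk(data.frame(i = c(0L, 1L, 2L, 0L), j = c(3L, 4L, 3L, 1L),
                     type = c(4L, 5L, 4L, 4L), mean = c(5, -3, 2, 99),
                     var = 0))
  rs <- residue_sum_scalar(x, sys$topology)
  expect_equal(nrow(rs), 1)        # intra-residue (0,1) pair excluded
  expect_equal(rs$value, 5 - 3 + 2)
  # type filter
  rc <- residue_sum_scalar(x, sys$topology, types = "COULOMB")
  expect_equal(rc$value, 7)
  # magnitude mode
  ra <- residue_sum_scalar(x, sys$topology, mode = "abs")
  expect_equal(ra$value, 10)
  # atom-group filter: both endpoints must belong to the group
  rg <- residue_sum_scalar(x, sys$topology, atoms = c(0L, 3L))
  expect_equal(rg$value, 5)
  # intra pairs reported on request
  ri <- residue_sum_scalar(x, sys$topology, include_intra = TRUE)
  expect_equal(ri$value[ri$u == 0 & ri$v == 0], 99)
})

test_that("residue vector sums restore geometry-consistent force vectors", {
  sys <- build_system(toy_system_spec("two_residue_peptide"))
  n <- 6L
  # synthetic coordinates: atoms on a grid so pair directions are known
  coords <- cbind(c(0, 1, 2, 0, 1, 2), c(0, 0, 0, 1, 1, 1), rep(0, 6))
  frames <- list(list(time = 0, coords = coords))
  # parallel pair forces between the residues: norms add
  b1 <- pairwise_forces(0, c(0L, 1L), c(3L, 4L), c(4L, 4L), c(3, 3))
  tr1 <- force_trajectory(list(b1), n)
  rv1 <- residue_sum_vector(tr1, frames, sys$topology)[[1]]
  expect_equal(rv1$norm, 6)
  expect_equal(rv1$x, 0)
  # orthogonal 3 and 4 give norm 5
  coords2 <- coords; coords2[5, ] <- c(2, 0, 1)  # pair (1,4) now along -z
  frames2 <- list(list(time = 0, coords = coords2))
  b2 <- pairwise_forces(0, c(0L, 1L), c(3L, 4L), c(4L, 4L), c(3, 4))
  # pair (0,3): along -y; pair (1,4): atom1=(1,0,0), atom4=(2,0,1)
  rv2 <- residue_sum_vector(force_trajectory(list(b2), n), frames2,
                            sys$topology)[[1]]
  d14 <- (coords2[2, ] - coords2[5, ]) / sqrt(2)
  expected <- c(0, -3, 0) + 4 * d14
  expect_equal(rv2$norm, sqrt(sum(expected^2)))
  # triangle inequality against the scalar absolute sum
  abs_sum <- residue_sum_scalar(structure(
    data.frame(i = b2$i, j = b2$j, type = b2$type, mean = b2$force,
               var = 0),
    class = c("avg_forces", "data.frame"), n_atoms = n, n_blocks = 1L),
    sys$topology, mode = "abs")
  expect_lte(rv2$norm, abs_sum$value + 1e-12)
  # norm column is consistent with the components
  expect_equal(rv2$norm, sqrt(rv2$x^2 + rv2$y^2 + rv2$z^2))
  # a block with no matching frame is an error
  late <- force_trajectory(list(pairwise_forces(99, 0L, 3L, 4L, 1)), n)
  expect_error(residue_sum_vector(late, frames, sys$topology), "matches")
})

test_that("network extraction applies a strict threshold in (i, j) order", {
  d <- structure(data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L),
                            type = c(1L, 1L, 1L), delta = c(5, -5, 2)),
                 class = c("delta_forces", "data.frame"), n_atoms = 3L,
                 kind = "raw", n_dropped = 0L)
  e3 <- extract_network(d, 3)
  expect_equal(e3$node_i, c(0L, 0L))
  expect_equal(e3$weight, c(5, -5))
  # strict: |value| == cutoff is not an edge
  expect_equal(nrow(extract_network(d, 5)), 0)
  # cutoff 0 keeps every nonzero entry
  expect_equal(nrow(extract_network(d, 0)), 3)
  # a cutoff above the maximum leaves nothing
  expect_equal(nrow(extract_network(d, 100)), 0)
})

test_that("PCA conserves variance and returns orthonormal components", {
  traj <- random_force_trajectory(30, 10, seed = 91)
  p <- pca_forces(traj)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # variance conservation against dense per-pair variances
  X <- matrix(0, 30, nrow(p$pairs))
  for (w in seq_along(traj$blocks)) {
    b <- traj$blocks[[w]]
    if (length(b$i) == 0) next
    s <- rowsum(b$force, as.numeric(b$i) * 10 + b$j)
    X[w, match(as.numeric(rownames(s)),
               as.numeric(p$pairs$a) * 10 + p$pairs$b)] <- s[, 1]
  }
  expect_lt(abs(sum(p$explained_variance) -
                  sum(apply(X, 2, stats::var))) /
              sum(apply(X, 2, stats::var)), 1e-8)
  G <- t(p$components) %*% p$components
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
})

test_that("PCA recovers planted correlated force modes", {
  # identical blocks: no variance at all
  b <- pairwise_forces(0, 0L, 1L, 1L, 5)
  same <- force_trajectory(list(b, b, b), 4)
  p0 <- pca_forces(same)
  expect_lt(max(p0$explained_variance), 1e-20)

  # two pairs fluctuating as x and -x: one component, loadings (1,-1)/sqrt 2
  set.seed(7)
  xs <- rnorm(40)
  blocks <- lapply(seq_along(xs), function(k)
    pairwise_forces(k - 1, c(0L, 0L), c(1L, 2L), c(1L, 1L),
                    c(xs[k], -xs[k])))
  p1 <- pca_forces(force_trajectory(blocks, 4))
  expect_lt(p1$explained_variance[2] / p1$explained_variance[1], 1e-20)
  expect_equal(abs(p1$components[, 1]), c(1, 1) / sqrt(2))

  # planted 3-pair mode + weak independent noise: PC1 recovers the support
  set.seed(8)
  load <- c(1, 1, -1) / sqrt(3)
  blocks <- lapply(1:60, function(k) {
    z <- rnorm(1, sd = 3)
    noise <- rnorm(5, sd = 0.05)
    pairwise_forces(k - 1, rep(0L, 5), 1:5, rep(4L, 5),
                    c(load * z, 0, 0) + noise)
  })
  p2 <- pca_forces(force_trajectory(blocks, 6))
  v <- p2$components[, 1]
  planted <- c(load, 0, 0)
  cosim <- abs(sum(v * planted)) / sqrt(sum(v^2) * sum(planted^2))
  expect_gt(cosim, 0.99)
})

test_that("TSV serialization round-trips every analysis object", {
  traj <- random_force_trajectory(8, 10, seed = 3)
  avg <- average_trajectory(traj)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_forces_tsv(avg, f)
  back <- read_forces_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(avg))
  expect_identical(attr(back, "n_atoms"), attr(avg, "n_atoms"))

  eps <- standard_error(list(avg, average_trajectory(
    random_force_trajectory(8, 10, seed = 4))))
  write_forces_tsv(eps, f)
  expect_equal(as.data.frame(read_forces_tsv(f)), as.data.frame(eps))

  d <- delta_force(avg, average_trajectory(
    random_force_trajectory(8, 10, seed = 5)))
  write_forces_tsv(d, f)
  back <- read_forces_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(d))
  expect_identical(attr(back, "kind"), "raw")
})
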
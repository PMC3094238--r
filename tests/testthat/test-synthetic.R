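test_that("deterministic toy systems sit at stationary points", {
  # net analytic force per atom below tolerance, checked against a
  # numerical gradient of the total potential energy
  total_V <- function(top, coords, cutoff = 1.0) {
    V <- 0
    for (q in seq_len(nrow(top$bonds))) {
      b <- top$bonds[q, ]
      r <- sqrt(sum((coords[b$i + 1, ] - coords[b$j + 1, ])^2))
      V <- V + V_bond(r, b$b0, b$kb)
    }
    for (q in seq_len(nrow(top$angles))) {
      g <- top$angles[q, ]
      V <- V + V_angle(c(coords[g$i + 1, ], coords[g$j + 1, ],
                         coords[g$k + 1, ]), g$theta0, g$ktheta)
    }
    for (q in seq_len(nrow(top$dihedrals))) {
      d <- top$dihedrals[q, ]
      if (d$kphi == 0) next
      V <- V + V_dihedral(c(coords[d$i + 1, ], coords[d$j + 1, ],
                            coords[d$k + 1, ], coords[d$l + 1, ]),
                          d$kphi, d$mult, d$phase)
    }
    ex <- paste(top$exclusions$i, top$exclusions$j)
    n <- nrow(coords)
    if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (paste(i - 1, j - 1) %in% ex) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r > cutoff) next
      qq <- top$atoms$charge[i] * top$atoms$charge[j]
      if (qq != 0) V <- V + V_coul(r, top$atoms$charge[i],
                                   top$atoms$charge[j])
      ep <- sqrt(top$atoms$epsilon[i] * top$atoms$epsilon[j])
      if (ep > 0) V <- V + V_lj(r, (top$atoms$sigma[i] +
                                      top$atoms$sigma[j]) / 2, ep)
    }
    V
  }
  for (kind in c("lj_dimer", "linear_chain", "bent_triple",
                 "dihedral_quad")) {
    sys <- build_system(toy_system_spec(kind))
    g <- num_grad_vec(function(x)
      total_V(sys$topology, matrix(x, ncol = 3)), as.numeric(sys$coords),
      h = 1e-7)
    expect_lt(max(abs(g)), 1e-4, label = paste("net force for", kind))
  }
  # the charged chain is relaxed numerically to a much tighter residual
  sys <- build_system(toy_system_spec("linear_chain",
                                      parameters = list(charge = 0.25)))
  m <- suppressWarnings(
    compute_frame(list(time = 0, coords = sys$coords), sys$topology,
                  engine_options(cutoff = 1.0)))
  n <- nrow(sys$coords)
  fx <- numeric(n)
  for (q in seq_along(m$i)) {
    d <- sys$coords[m$i[q] + 1, 1] - sys$coords[m$j[q] + 1, 1]
    fx[m$i[q] + 1] <- fx[m$i[q] + 1] + m$force[q] * sign(d)
    fx[m$j[q] + 1] <- fx[m$j[q] + 1] - m$force[q] * sign(d)
  }
  expect_lt(max(abs(fx)), 1e-7)
})

test_that("the LJ dimer and chain produce the advertised trivial matrices", {
  ld <- build_system(toy_system_spec("lj_dimer"))
  m <- compute_frame(list(time = 0, coords = ld$coords), ld$topology)
  # at the minimum separation the force is zero up to the rounding
  # residual of the kernel (an exact 0.0 is not representable there)
  expect_lt(max(abs(m$force), 0), 1e-12)

  cd <- build_system(toy_system_spec("charged_dimer"))
  m <- compute_frame(list(time = 0, coords = cd$coords), cd$topology)
  expect_equal(m$force, -138.935458)
})

test_that("thermal sampling is seeded, unbiased and honours sigma = 0", {
  sys <- build_system(toy_system_spec("bent_triple"))
  f0 <- sample_frames(sys$coords, 0, 5, seed = 42)
  for (fr in f0) expect_identical(fr$coords, sys$coords)
  expect_equal(vapply(f0, function(f) f$time, 0), 0:4)

  fa <- sample_frames(sys$coords, 0.01, 5, seed = 42)
  fb <- sample_frames(sys$coords, 0.01, 5, seed = 42)
  expect_identical(fa, fb)
  fc <- sample_frames(sys$coords, 0.01, 5, seed = 43)
  expect_false(identical(fa, fc))

  # sample sd over many frames approaches the requested sigma
  many <- sample_frames(sys$coords, 0.02, 4000, seed = 1)
  dev <- vapply(many, function(f) f$coords[1, 1] - sys$coords[1, 1], 0)
  expect_lt(abs(stats::sd(dev) - 0.02) / 0.02, 0.05)
})

test_that("chain equilibria under tension carry the load in every bond", {
  spec <- toy_system_spec("linear_chain")
  for (T_ in c(25, 100)) {
    pair <- make_state_pair(spec, "external_tension", magnitude = T_)
    m <- suppressWarnings(
      compute_frame(list(time = 0, coords = pair$pert$coords),
                    pair$pert$topology))
    bonds <- m$force[m$type == 1L]
    expect_length(bonds, 7)
    expect_lt(max(abs(bonds + T_)) / T_, 1e-6)
    # bonds-only chain: closed form gap b0 + T/kb
    gaps <- diff(pair$pert$coords[, 1])
    expect_equal(gaps, rep(0.15 + T_ / 1e4, 7), tolerance = 1e-9)
  }
  # zero magnitude leaves the states identical
  p0 <- make_state_pair(spec, "external_tension", magnitude = 0)
  expect_equal(p0$pert$coords, p0$ref$coords, tolerance = 1e-12)
})

test_that("charge perturbations at sigma = 0 touch only the atom's pairs", {
  spec <- toy_system_spec("linear_chain",
                          parameters = list(charge = 0.25))
  pair <- make_state_pair(spec, "charge_change", magnitude = 0.4,
                          perturb_atom = 4L)
  mr <- suppressWarnings(compute_frame(list(time = 0,
                                             coords = pair$ref$coords),
                                        pair$ref$topology))
  mp <- suppressWarnings(compute_frame(list(time = 0,
                                            coords = pair$pert$coords),
                                       pair$pert$topology))
  ar <- average_trajectory(force_trajectory(list(mr), 8))
  ap <- average_trajectory(force_trajectory(list(mp), 8))
  d <- delta_force(ar, ap)
  expect_gt(nrow(d), 0)
  expect_true(all(d$i == 4L | d$j == 4L))
  expect_true(all(d$type == 4L))

  # magnitude zero: identical states, empty delta
  p0 <- make_state_pair(spec, "charge_change", magnitude = 0)
  m0r <- suppressWarnings(compute_frame(list(time = 0,
                                              coords = p0$ref$coords),
                                         p0$ref$topology))
  m0p <- suppressWarnings(compute_frame(list(time = 0,
                                             coords = p0$pert$coords),
                                        p0$pert$topology))
  expect_identical(m0r$force, m0p$force)
})

test_that("inapplicable perturbations are rejected", {
  expect_error(make_state_pair(toy_system_spec("charged_dimer"),
                               "external_tension", magnitude = 10),
               "linear_chain")
  expect_error(make_state_pair(toy_system_spec("charged_dimer"),
                               "parameter_change", magnitude = 0.01),
               "bonded")
})
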
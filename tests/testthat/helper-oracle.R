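# Independent oracles. Everything here recomputes expected values from
# first principles (potentials + central differences, or a plain double
# loop) without touching the package's kernel/engine code paths.

F_ELEC_ORACLE <- 138.935458

num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

num_grad_vec <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (q in seq_along(x)) {
    xp <- x; xm <- x
    xp[q] <- xp[q] + h
    xm[q] <- xm[q] - h
    g[q] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

V_lj <- function(r, sigma, epsilon) 4 * epsilon * ((sigma / r)^12 - (sigma / r)^6)
V_coul <- function(r, qi, qj) F_ELEC_ORACLE * qi * qj / r
V_bond <- function(r, b0, kb) 0.5 * kb * (r - b0)^2

cross_o <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

V_angle <- function(x, theta0, ktheta) {
  ri <- x[1:3]; rj <- x[4:6]; rk <- x[7:9]
  u <- ri - rj; v <- rk - rj
  cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  th <- acos(max(-1, min(1, cosv)))
  0.5 * ktheta * (th - theta0)^2
}

V_dihedral <- function(x, kphi, mult, phase) {
  ri <- x[1:3]; rj <- x[4:6]; rk <- x[7:9]; rl <- x[10:12]
  b1 <- rj - ri; b2 <- rk - rj; b3 <- rl - rk
  n1 <- cross_o(b1, b2); n2 <- cross_o(b2, b3)
  phi <- atan2(sum(cross_o(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  kphi * (1 + cos(mult * phi - phase))
}

# projected pair scalar from numerically differentiated atomic forces
oracle_angle_scalar <- function(ri, rj, rk, theta0, ktheta) {
  g <- num_grad_vec(function(x) V_angle(x, theta0, ktheta), c(ri, rj, rk))
  Fi <- -g[1:3]; Fk <- -g[7:9]
  uki <- (ri - rk) / sqrt(sum((ri - rk)^2))
  0.5 * (sum(Fi * uki) + sum(Fk * (-uki)))
}

oracle_dihedral_scalar <- function(ri, rj, rk, rl, kphi, mult, phase) {
  g <- num_grad_vec(function(x) V_dihedral(x, kphi, mult, phase),
                    c(ri, rj, rk, rl))
  Fi <- -g[1:3]; Fl <- -g[10:12]
  uli <- (ri - rl) / sqrt(sum((ri - rl)^2))
  0.5 * (sum(Fi * uli) + sum(Fl * (-uli)))
}

rel_err <- function(a, b, floor = 1e-8) abs(a - b) / pmax(abs(a), abs(b), floor)

# Brute-force O(N^2) frame reference: plain loops, analytic formulas
# written out independently of the engine. Two-body terms only (bonds,
# Coulomb, LJ), which is what the conservation acceptance check uses.
brute_force_frame <- function(coords, top, cutoff) {
  n <- nrow(coords)
  ex <- paste(top$exclusions$i, top$exclusions$j)
  rows <- list()
  dist_ij <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  for (q in seq_len(nrow(top$bonds))) {
    b <- top$bonds[q, ]
    r <- dist_ij(b$i + 1, b$j + 1)
    rows[[length(rows) + 1]] <- data.frame(
      i = min(b$i, b$j), j = max(b$i, b$j), type = 1L,
      force = -b$kb * (r - b$b0))
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (paste(i - 1, j - 1) %in% ex) next
    r <- dist_ij(i, j)
    if (r > cutoff || r == 0) next
    qi <- top$atoms$charge[i]; qj <- top$atoms$charge[j]
    if (qi * qj != 0)
      rows[[length(rows) + 1]] <- data.frame(
        i = i - 1L, j = j - 1L, type = 4L,
        force = F_ELEC_ORACLE * qi * qj / r^2)
    sg <- (top$atoms$sigma[i] + top$atoms$sigma[j]) / 2
    ep <- sqrt(top$atoms$epsilon[i] * top$atoms$epsilon[j])
    if (ep > 0) {
      s6 <- (sg / r)^6
      f <- 4 * ep * (12 * s6^2 - 6 * s6) / r
      rows[[length(rows) + 1]] <- data.frame(i = i - 1L, j = j - 1L,
                                             type = 5L, force = f)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame(i = integer(), j = integer(),
                                     type = integer(), force = numeric()))
  agg <- aggregate(force ~ i + j + type, data = df, FUN = sum)
  agg <- agg[agg$force != 0, ]
  agg[order(agg$i, agg$j, agg$type), c("i", "j", "type", "force")]
}

# analytic total force vectors for two-body-only systems: direct vector
# sums of -dV/dr along the pair axis
analytic_total_forces <- function(coords, top, cutoff) {
  n <- nrow(coords)
  Ftot <- matrix(0, n, 3)
  addpair <- function(i, j, fscalar) {
    # positive scalar pushes apart: force on i along (ri - rj)
    d <- coords[i, ] - coords[j, ]
    u <- d / sqrt(sum(d^2))
    Ftot[i, ] <<- Ftot[i, ] + fscalar * u
    Ftot[j, ] <<- Ftot[j, ] - fscalar * u
  }
  ex <- paste(top$exclusions$i, top$exclusions$j)
  for (q in seq_len(nrow(top$bonds))) {
    b <- top$bonds[q, ]
    r <- sqrt(sum((coords[b$i + 1, ] - coords[b$j + 1, ])^2))
    addpair(b$i + 1, b$j + 1, -b$kb * (r - b$b0))
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (paste(i - 1, j - 1) %in% ex) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (r > cutoff || r == 0) next
    f <- 0
    qi <- top$atoms$charge[i]; qj <- top$atoms$charge[j]
    if (qi * qj != 0) f <- f + F_ELEC_ORACLE * qi * qj / r^2
    sg <- (top$atoms$sigma[i] + top$atoms$sigma[j]) / 2
    ep <- sqrt(top$atoms$epsilon[i] * top$atoms$epsilon[j])
    if (ep > 0) {
      s6 <- (sg / r)^6
      f <- f + 4 * ep * (12 * s6^2 - 6 * s6) / r
    }
    if (f != 0) addpair(i, j, f)
  }
  Ftot
}

# random two-body-only test system: n atoms, a random spanning set of
# bonds, random charges and LJ parameters
random_twobody_system <- function(n, seed) {
  set.seed(seed)
  coords <- matrix(runif(n * 3, 0, 1.2), n, 3)
  # chain bonds keep the exclusion structure non-trivial
  bonds <- data.frame(i = 0:(n - 2), j = 1:(n - 1),
                      b0 = runif(n - 1, 0.1, 0.2),
                      kb = runif(n - 1, 500, 2000))
  atoms <- data.frame(index = 0:(n - 1),
                      name = sprintf("C%d", 1:n),
                      resid = (0:(n - 1)) %/% 2L,
                      resname = "RND",
                      charge = round(runif(n, -0.5, 0.5), 3),
                      sigma = runif(n, 0.1, 0.3),
                      epsilon = runif(n, 0.05, 0.5),
                      stringsAsFactors = FALSE)
  top <- structure(list(atoms = atoms, bonds = bonds,
                        angles = data.frame(i = integer(), j = integer(),
                                            k = integer(),
                                            theta0 = numeric(),
                                            ktheta = numeric()),
                        dihedrals = data.frame(i = integer(), j = integer(),
                                               k = integer(), l = integer(),
                                               kphi = numeric(),
                                               mult = integer(),
                                               phase = numeric()),
                        exclusions = derive_exclusions(bonds)),
                   class = "fda_topology", auto_exclusions = TRUE)
  validate_topology(top)
  list(topology = top, coords = coords)
}

# random sparse force trajectory for serialization round trips
random_force_trajectory <- function(n_blocks, n_atoms, seed,
                                    max_entries = 12) {
  set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(k) {
    ne <- sample(0:max_entries, 1)
    if (ne == 0) return(pairwise_forces(k - 1))
    pr <- matrix(nrow = 0, ncol = 2)
    while (nrow(pr) < ne) {
      cand <- sort(sample(0:(n_atoms - 1), 2))
      pr <- unique(rbind(pr, cand))
    }
    types <- sample(1:5, nrow(pr), replace = TRUE)
    pairwise_forces(k - 1, pr[, 1], pr[, 2], types,
                    round(rnorm(nrow(pr), sd = 50), 6))
  })
  force_trajectory(blocks, n_atoms)
}

expect_traj_equal <- function(a, b) {
  expect_equal(a$n_atoms, b$n_atoms)
  expect_equal(a$syntax, b$syntax)
  expect_equal(length(a$blocks), length(b$blocks))
  for (k in seq_along(a$blocks)) {
    expect_identical(a$blocks[[k]]$time, b$blocks[[k]]$time)
    expect_identical(a$blocks[[k]]$i, b$blocks[[k]]$i)
    expect_identical(a$blocks[[k]]$j, b$blocks[[k]]$j)
    expect_identical(a$blocks[[k]]$type, b$blocks[[k]]$type)
    expect_identical(a$blocks[[k]]$force, b$blocks[[k]]$force)
  }
}
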
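# Analytic pair-force kernels. All forces are signed scalars in
# kJ mol^-1 nm^-1 with the convention: positive = repulsive (pushes the
# pair apart), negative = attractive. Each kernel is -dV/dr of its
# potential along the pair axis; for the multi-body terms (angle, proper
# dihedral) the full analytic atomic forces are computed first and then
# projected onto the outer-atom axis, which is the pair-wise
# approximation that makes multi-body terms storable in a pair matrix.

# Coulomb prefactor 1/(4 pi eps0) in MD units, kJ mol^-1 nm e^-2
F_ELEC <- 138.935458

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Lennard-Jones pair force
#'
#' Signed scalar force of the 12-6 potential
#' \eqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}, i.e.
#' \eqn{-dV/dr = 4\epsilon(12\sigma^{12}/r^{13} - 6\sigma^6/r^7)}.
#' Positive (repulsive) for \eqn{r < 2^{1/6}\sigma}, zero at the minimum,
#' negative beyond.
#'
#' @param r Pair distance in nm, `> 0`.
#' @param sigma LJ sigma in nm.
#' @param epsilon LJ well depth in kJ mol^-1.
#' @return Signed scalar force in kJ mol^-1 nm^-1.
#' @export
lj_pair_force <- function(r, sigma, epsilon) {
  if (any(r <= 0)) stop_validation("r must be > 0")
  sr6 <- (sigma / r)^6
  4 * epsilon * (12 * sr6 * sr6 - 6 * sr6) / r
}

#' Coulomb pair force (plain cutoff electrostatics)
#'
#' \eqn{F(r) = f q_i q_j / r^2} with
#' \eqn{f = 138.935458} kJ mol^-1 nm e^-2. Like charges give a positive
#' (repulsive) force. Mesh-based long-range electrostatics cannot be
#' decomposed into pairs and are deliberately not supported; beyond the
#' typical cutoff of 1 nm the potential is flat enough that truncation
#' changes pair forces little.
#'
#' @param r Pair distance in nm, `> 0`.
#' @param qi,qj Partial charges in units of the elementary charge.
#' @return Signed scalar force in kJ mol^-1 nm^-1.
#' @export
coulomb_pair_force <- function(r, qi, qj) {
  if (any(r <= 0)) stop_validation("r must be > 0")
  F_ELEC * qi * qj / r^2
}

#' Harmonic bond pair force
#'
#' \eqn{-dV/dr} for \eqn{V = \frac{1}{2} k_b (r - b_0)^2}, i.e.
#' \eqn{-k_b (r - b_0)}: a stretched bond gives a negative (attractive,
#' restoring) force.
#'
#' @param r Pair distance in nm, `> 0`.
#' @param b0 Equilibrium length in nm.
#' @param kb Force constant in kJ mol^-1 nm^-2.
#' @return Signed scalar force in kJ mol^-1 nm^-1.
#' @export
bond_pair_force <- function(r, b0, kb) {
  if (any(r <= 0)) stop_validation("r must be > 0")
  -kb * (r - b0)
}

#' Projected pair force of a harmonic angle
#'
#' Computes the full analytic forces on the outer atoms `i` and `k` of the
#' harmonic angle potential \eqn{V = \frac{1}{2} k_\theta (\theta -
#' \theta_0)^2} and returns their symmetrized projection onto the i-k
#' axis: \eqn{\frac{1}{2}(F_i \cdot \hat u_{ki} + F_k \cdot \hat
#' u_{ik})} with \eqn{\hat u_{ki} = (r_i - r_k)/|r_i - r_k|}. This is the
#' pair-wise approximation for three-body terms: only the component along
#' the outer-atom axis is kept, and the force on the apex atom `j` is
#' discarded. The symmetrization makes the value invariant under
#' relabelling `(i,j,k) <-> (k,j,i)`.
#'
#' @param ri,rj,rk Atom coordinates (length-3, nm); `j` is the apex.
#' @param theta0 Equilibrium angle in rad.
#' @param ktheta Force constant in kJ mol^-1 rad^-2.
#' @return Signed scalar force on the (i, k) pair, or `NA` with a warning
#'   when the geometry is collinear (|sin theta| < 1e-10) and the angle
#'   gradient is undefined.
#' @export
angle_pair_force <- function(ri, rj, rk, theta0, ktheta) {
  u <- ri - rj
  v <- rk - rj
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  d_ik <- ri - rk
  n_ik <- sqrt(sum(d_ik^2))
  if (nu == 0 || nv == 0 || n_ik == 0)
    stop_validation("coincident atoms in angle term")
  cosT <- sum(u * v) / (nu * nv)
  cosT <- max(-1, min(1, cosT))
  sinT <- sqrt(max(0, 1 - cosT^2))
  if (sinT < 1e-10) {
    warning("collinear angle geometry; entry skipped")
    return(NA_real_)
  }
  theta <- acos(cosT)
  dVdT <- ktheta * (theta - theta0)
  # dtheta/dri and dtheta/drk
  dT_du <- -(v / (nu * nv) - cosT * u / nu^2) / sinT
  dT_dv <- -(u / (nu * nv) - cosT * v / nv^2) / sinT
  Fi <- -dVdT * dT_du
  Fk <- -dVdT * dT_dv
  u_ki <- d_ik / n_ik
  0.5 * (sum(Fi * u_ki) + sum(Fk * (-u_ki)))
}

#' Projected pair force of a periodic proper dihedral
#'
#' Computes the analytic forces on the outer atoms `i` and `l` of the
#' proper dihedral potential \eqn{V = k_\phi (1 + \cos(n\phi -
#' \phi_s))} and returns their symmetrized projection onto the i-l axis,
#' \eqn{\frac{1}{2}(F_i \cdot \hat u_{li} + F_l \cdot \hat u_{il})}. The
#' forces on the inner atoms `j`, `k` are discarded, as in the pair-wise
#' approximation for four-body terms. Improper dihedrals are not
#' supported: their outer atoms have no meaningful pair axis.
#'
#' @param ri,rj,rk,rl Atom coordinates (length-3, nm) along the dihedral.
#' @param kphi Barrier constant in kJ mol^-1.
#' @param mult Multiplicity `n` (integer >= 1).
#' @param phase Phase angle \eqn{\phi_s} in rad.
#' @return Signed scalar force on the (i, l) pair, or `NA` with a warning
#'   for degenerate geometry (a collinear bond triple, plane normals
#'   undefined).
#' @export
dihedral_pair_force <- function(ri, rj, rk, rl, kphi, mult, phase) {
  b1 <- rj - ri
  b2 <- rk - rj
  b3 <- rl - rk
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  sq1 <- sum(n1^2)
  sq2 <- sum(n2^2)
  scale1 <- sum(b1^2) * sum(b2^2)
  scale2 <- sum(b2^2) * sum(b3^2)
  if (nb2 == 0 || scale1 == 0 || scale2 == 0 ||
      sqrt(sq1 / scale1) < 1e-10 || sqrt(sq2 / scale2) < 1e-10) {
    warning("degenerate dihedral geometry; entry skipped")
    return(NA_real_)
  }
  d_il <- ri - rl
  n_il <- sqrt(sum(d_il^2))
  if (n_il == 0) stop_validation("coincident outer atoms in dihedral term")
  phi <- atan2(sum(.cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
  dVdphi <- -kphi * mult * sin(mult * phi - phase)
  # dphi/dri = -|b2|/|n1|^2 n1 ; dphi/drl = |b2|/|n2|^2 n2
  Fi <- dVdphi * (nb2 / sq1) * n1
  Fl <- -dVdphi * (nb2 / sq2) * n2
  u_li <- d_il / n_il
  0.5 * (sum(Fi * u_li) + sum(Fl * (-u_li)))
}
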
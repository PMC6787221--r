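options(linkerflex.quiet = TRUE)

# closed-form scattering intensity of a homogeneous sphere of radius R
sphere_intensity <- function(q, R, i0 = 1) {
  x <- q * R
  i0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# closed-form pair-distance distribution of a homogeneous sphere
sphere_pofr <- function(r, R) {
  ifelse(r >= 0 & r <= 2 * R,
         r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3)), 0)
}

# equilibrium oracle for the 1:1 isotherm: solve free-ligand concentration
# by root finding, then bound fraction (independent of binding_curve algebra)
bound_fraction_1to1 <- function(kd, p0, l0) {
  if (l0 == 0) return(0)
  fr <- stats::uniroot(function(L) L + p0 * L / (kd + L) - l0,
                       c(0, l0), tol = 1e-12)$root
  fr / (kd + fr)
}

# equilibrium oracle for the bivalent 2:1 isotherm: each ligand carries two
# binding units; solve for free units
bound_fraction_2to1 <- function(kd, p0, l0) {
  if (l0 == 0) return(0)
  fr <- stats::uniroot(function(U) U + p0 * U / (kd + U) - 2 * l0,
                       c(0, 2 * l0), tol = 1e-12)$root
  fr / (kd + fr)
}

make_titration_truth <- function(n = 20, domain = "UIM", seed = 99) {
  set.seed(seed)
  tibble::tibble(residue = seq_len(n), domain = domain,
                 dd_bound = runif(n, 0.2, 0.8))
}

# small uniformly filled sphere of beads for Debye tests
sphere_beads <- function(n, R, seed = 1) {
  set.seed(seed)
  pts <- matrix(runif(8 * 3 * n, -R, R), ncol = 3)
  pts <- pts[rowSums(pts^2) <= R^2, , drop = FALSE]
  pts[seq_len(n), ]
}
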
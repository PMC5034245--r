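# Shared generators for property-style tests. All randomness is controlled
# by set.seed() at the call sites.

randUnit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

randomHelixParams <- function() {
  omega <- stats::runif(1, 75, 125)
  rise <- stats::runif(1, 1.2, 2.0)
  helixParameters(
    P = stats::runif(3, -10, 10), n = randUnit(),
    radii = stats::runif(4, 1, 3), s = 360 * rise / omega, omega = omega,
    t = c(stats::runif(1, -1.5, -0.5), 0, stats::runif(2, 0.5, 2.5)),
    phi = stats::runif(4, -180, 180))
}

# HelixFit with zero residuals built directly from exact model coordinates;
# used where tests exercise geometry downstream of fitting, not the fit.
exactFit <- function(params, nres = 18, label = "helix") {
  coords <- generateHelixCoordinates(params, residueIndices = 0:(nres - 1))
  seg <- helixSegment(coords, label = label)
  free <- rep(0, 19)
  names(free) <- c("P_x", "P_y", "P_z", "n_x", "n_y", "n_z",
                   "r_N", "r_CA", "r_C", "r_O", "s", "omega",
                   "t_N", "t_C", "t_O", "phi_N", "phi_CA", "phi_C", "phi_O")
  methods::new("HelixFit", params = params, segment = seg, rmsd = 0,
               converged = TRUE, nAtoms = as.integer(4 * nres),
               perAtomResiduals = rep(0, 4 * nres), free = free,
               leftHanded = params@omega < 0)
}

# independent dihedral formulation (plane-normal angle with signed triple
# product), deliberately different from the package's atan2 kernel
oracleDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                         x[3] * y[1] - x[1] * y[3],
                         x[1] * y[2] - x[2] * y[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  if (ang >= 180) ang <- -180
  ang
}

wrapDeg <- function(x) ((x + 180) %% 360) - 180

rigidTransformCoords <- function(coords, R, tr) {
  out <- coords
  for (A in dimnames(coords)[[2]])
    out[, A, ] <- sweep(coords[, A, ] %*% t(R), 2, tr, "+")
  out
}

rotMat <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
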
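#' @include AllClasses.R utils-geometry.R
NULL

# Ideal backbone internal coordinates (Engh & Huber style): bond lengths in
# Angstrom, bond angles in degrees, planar trans peptide (omega = 180).
.BB_GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.8,
  omega_pep = 180)

#' Deterministic orthonormal basis perpendicular to a helix axis
#'
#' Builds the pair of unit vectors `a`, `b` normal to each other and to the
#' axis `n`, from an auxiliary vector `c`: `a = normalize(n x c)`,
#' `b = n x a`. The auxiliary vector is chosen deterministically (global +z,
#' or global +x when `|n . z| > 0.9`), so the same axis always yields the
#' same frame — which is what makes sub-helix phases comparable between
#' fits.
#'
#' @param n unit 3-vector (axis direction cosines).
#' @return list with unit vectors `a`, `b` and the auxiliary vector `c`.
#' @examples
#' f <- buildBasis(c(0, 0, 1))
#' crossprod(f$a, f$b)  # 0
#' @export
buildBasis <- function(n) {
  if (length(n) != 3 || .norm3(n) < 1e-12)
    stop("axis n must be a nonzero 3-vector")
  if (abs(.norm3(n) - 1) > 1e-9)
    stop("axis n must be a unit vector")
  cvec <- if (abs(n[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  a <- .unit3(.cross3(n, cvec))
  b <- .cross3(n, a)
  list(a = a, b = b, c = cvec)
}

#' Generate backbone coordinates from helix parameters
#'
#' The forward model: the position of the atom of type A at residue index i
#' is
#' \deqn{x_A(i) = P + (i s \Omega/360 + t_A)\,n
#'   + r_A \cos(i\Omega + \phi_A)\,a + r_A \sin(i\Omega + \phi_A)\,b}
#' with angles in degrees, so the axial rise per residue is
#' \eqn{s\Omega/360} (equivalently \eqn{s\Omega/2\pi} with \eqn{\Omega} in
#' radians).
#'
#' @param params a [HelixParameters-class].
#' @param frame basis frame from [buildBasis()]; defaults to the
#'   deterministic frame of the params' axis.
#' @param residueIndices strictly increasing integers; by convention index 0
#'   is the segment N-terminus.
#' @return numeric array `[residue, atom, xyz]` with atoms N, CA, C, O, in
#'   the order of `residueIndices`.
#' @examples
#' p <- helixParameters(c(0, 0, 0), c(0, 0, 1), c(1.5, 2.3, 1.7, 2.0),
#'                      5.4, 100, c(-0.9, 0, 1.1, 2.3), c(-27, 0, 27, 20))
#' x <- generateHelixCoordinates(p, residueIndices = 0:17)
#' diff(x[, "CA", 3])  # constant 1.5 A axial rise
#' @export
generateHelixCoordinates <- function(params, frame = buildBasis(params@n),
                                     residueIndices = NULL) {
  validObject(params)
  if (is.null(residueIndices) || length(residueIndices) == 0)
    stop("residueIndices must be a non-empty integer sequence")
  if (any(diff(residueIndices) <= 0))
    stop("residueIndices must be strictly increasing")
  i <- as.numeric(residueIndices)
  rise <- params@s * params@omega / 360
  out <- array(NA_real_, c(length(i), 4, 3),
               dimnames = list(NULL, .ATOM_TYPES, c("x", "y", "z")))
  for (A in .ATOM_TYPES) {
    theta <- .deg2rad(i * params@omega + params@phi[[A]])
    z <- i * rise + params@t[[A]]
    pos <- outer(z, params@n) +
      outer(params@radii[[A]] * cos(theta), frame$a) +
      outer(params@radii[[A]] * sin(theta), frame$b)
    out[, A, ] <- sweep(pos, 2, params@P, "+")
  }
  out
}

# Closed-form derivation of canonical helix parameters from backbone
# coordinates and a given axis line. Exact when the coordinates lie on the
# model; a deterministic least-squares-flavoured estimate otherwise (used
# both for optimizer initialization and for post-convergence gauge
# normalization).
.deriveParams <- function(coords, P0, n) {
  nres <- dim(coords)[1]
  idx <- seq_len(nres) - 1
  # g1: orient the axis from the first to the last residue
  if (sum(n * (coords[nres, "CA", ] - coords[1, "CA", ])) < 0) n <- -n
  n <- .unit3(n)
  frame <- buildBasis(n)
  z <- az <- matrix(NA_real_, nres, 4, dimnames = list(NULL, .ATOM_TYPES))
  rad <- numeric(4); names(rad) <- .ATOM_TYPES
  for (A in .ATOM_TYPES) {
    v <- sweep(coords[, A, , drop = FALSE][, 1, ], 2, P0)
    if (nres == 1) v <- matrix(coords[, A, ] - P0, 1, 3)
    z[, A] <- v %*% n
    va <- v %*% frame$a
    vb <- v %*% frame$b
    az[, A] <- .rad2deg(atan2(vb, va))
    rad[A] <- mean(sqrt(va^2 + vb^2))
  }
  # signed angular turn per residue from wrapped azimuth increments,
  # pooled over the four sub-helix tracks
  omega <- mean(apply(az, 2, function(x) mean(.wrapAngle(diff(x)))))
  rise <- mean(apply(z, 2, function(x) mean(diff(x))))
  s <- 360 * rise / omega
  c0 <- mean(z[, "CA"] - idx * rise)
  tA <- vapply(.ATOM_TYPES, function(A) mean(z[, A] - idx * rise) - c0, 0)
  phiA <- vapply(.ATOM_TYPES, function(A) .circMean(az[, A] - idx * omega), 0)
  params <- helixParameters(P = P0 + c0 * n, n = n, radii = rad, s = s,
                            omega = omega, t = tA - tA[["CA"]], phi = phiA)
  list(params = params, frame = buildBasis(n))
}

# Pack / unpack the 19 free scalars seen by the optimizer. The axis enters
# as 3 direction cosines normalized inside the model (its magnitude is a
# gauge direction absorbed by the Levenberg-Marquardt damping); the C-alpha
# axial offset is structurally excluded. Angles are radians internally.
.packFree <- function(params) {
  c(P_x = params@P[1], P_y = params@P[2], P_z = params@P[3],
    n_x = params@n[1], n_y = params@n[2], n_z = params@n[3],
    r_N = params@radii[["N"]], r_CA = params@radii[["CA"]],
    r_C = params@radii[["C"]], r_O = params@radii[["O"]],
    s = params@s, omega = .deg2rad(params@omega),
    t_N = params@t[["N"]], t_C = params@t[["C"]], t_O = params@t[["O"]],
    phi_N = .deg2rad(params@phi[["N"]]), phi_CA = .deg2rad(params@phi[["CA"]]),
    phi_C = .deg2rad(params@phi[["C"]]), phi_O = .deg2rad(params@phi[["O"]]))
}

.unpackFree <- function(p) {
  n <- .unit3(p[4:6])
  helixParameters(P = p[1:3], n = n,
                  radii = pmax(p[7:10], 1e-6),
                  s = p[11], omega = .rad2deg(p[12]),
                  t = c(p[13], 0, p[14], p[15]),
                  phi = .rad2deg(p[16:19]))
}

.modelFromFree <- function(p, idx) {
  params <- .unpackFree(p)
  generateHelixCoordinates(params, buildBasis(params@n), idx)
}

#' Fit the 19-parameter helix model to a backbone segment
#'
#' Least-squares fit (Levenberg-Marquardt, [minpack.lm::nls.lm]) of the
#' four-sub-helix model to the observed N, C-alpha, C, O coordinates of a
#' segment. After convergence the parameters are gauge-normalized so that
#' independent fits of the same coordinates are directly comparable:
#' the axis is oriented from the first to the last residue; the reference
#' point P is placed at the axial foot of the C-alpha sub-helix at the first
#' residue (residue index 0), which fixes the C-alpha axial offset at
#' exactly 0; phases are reported in the deterministic frame of
#' [buildBasis()] and wrapped to [-180, 180).
#'
#' @param segment a [HelixSegment-class] with at least 5 complete residues.
#' @param init optional [HelixParameters-class] starting point; by default a
#'   deterministic closed-form start is derived from the principal axis of
#'   the C-alpha coordinates.
#' @return a [HelixFit-class]. A fit that fails to converge is returned with
#'   `converged = FALSE` and the best parameters found (never silently
#'   accepted); a left-handed solution is flagged via `leftHanded` and
#'   carries `omega < 0`.
#' @examples
#' p <- helixParameters(c(0, 0, 0), c(0, 0, 1), c(1.5, 2.3, 1.7, 2.0),
#'                      5.4, 100, c(-0.9, 0, 1.1, 2.3), c(-27, 0, 27, 20))
#' seg <- helixSegment(generateHelixCoordinates(p, residueIndices = 0:17))
#' fit <- fitHelix(seg)
#' helixOmega(fit)   # 100
#' fitRMSD(fit)      # ~0
#' @export
fitHelix <- function(segment, init = NULL) {
  stopifnot(is(segment, "HelixSegment"))
  coords <- segment@coords
  nres <- dim(coords)[1]
  if (nres < 5) stop("segment too short: need >= 5 complete residues, have ", nres)
  flat <- matrix(aperm(coords, c(2, 1, 3)), ncol = 3)
  ctr <- colMeans(flat)
  cen <- sweep(flat, 2, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  perp <- sqrt(rowSums((cen - (cen %*% ev$vectors[, 1]) %*% t(ev$vectors[, 1]))^2))
  if (max(perp) < 1e-6)
    stop("degenerate segment: all atoms are collinear, no helix axis is defined")
  idx <- seq_len(nres) - 1
  if (is.null(init)) {
    ca <- coords[, "CA", ]
    caCen <- sweep(ca, 2, colMeans(ca))
    axis0 <- eigen(crossprod(caCen) / nres, symmetric = TRUE)$vectors[, 1]
    init <- .deriveParams(coords, colMeans(ca), axis0)$params
  } else {
    validObject(init)
  }
  p0 <- .packFree(init)
  obs <- as.numeric(coords)
  resFun <- function(p) as.numeric(.modelFromFree(p, idx)) - obs
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, gtol = 1e-10,
                                    maxiter = 1024, maxfev = 100000)
  opt <- suppressWarnings(minpack.lm::nls.lm(par = p0, fn = resFun,
                                             control = ctl))
  converged <- opt$info %in% 1:4
  fitted <- .unpackFree(opt$par)
  # gauge normalization from the exact model point cloud
  model0 <- generateHelixCoordinates(fitted, buildBasis(fitted@n), idx)
  canon <- .deriveParams(model0, fitted@P, fitted@n)
  params <- canon$params
  model <- generateHelixCoordinates(params, canon$frame, idx)
  d2 <- apply((model - coords)^2, 1:2, sum)
  perAtom <- sqrt(as.numeric(t(d2)))
  rmsd <- sqrt(mean(d2))
  free <- opt$par
  if (length(free) != 19) stop("internal error: free vector is not length 19")
  new("HelixFit", params = params, segment = segment, rmsd = rmsd,
      converged = converged, nAtoms = 4L * nres, perAtomResiduals = perAtom,
      free = free, leftHanded = params@omega < 0)
}

#' Classify a helix form from its angular turn per residue
#'
#' The ideal angular turns are 120, 100 and 80 deg/residue for 3/10, alpha
#' and pi helices. The nearest ideal value wins, with decision boundaries at
#' the midpoints 110 and 90; exact boundary values resolve toward alpha
#' (the most common form). Values outside [70, 130] are "other".
#'
#' @param omega angular turn per residue, degrees; may be a vector.
#' @return character vector in `c("three_ten", "alpha", "pi", "other")`.
#' @examples
#' classifyHelixForm(c(120, 100, 80, 110, 135))
#' @export
classifyHelixForm <- function(omega) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be positive and finite")
  out <- rep("other", length(omega))
  inr <- omega >= 70 & omega <= 130
  out[inr & omega > 110] <- "three_ten"
  out[inr & omega >= 90 & omega <= 110] <- "alpha"
  out[inr & omega < 90] <- "pi"
  out
}

# Backbone of two consecutive ideal-geometry residues with the given
# dihedrals; returns the two (N, CA, C) triads plus the carbonyl O.
.idealRepeat <- function(phi, psi) {
  g <- .BB_GEOM
  N1 <- c(0, 0, 0)
  Ca1 <- c(g$b_N_CA, 0, 0)
  C1 <- .placeAtom(c(-1, 0.5, 0), N1, Ca1, g$b_CA_C, g$a_N_CA_C, 55)
  N2 <- .placeAtom(N1, Ca1, C1, g$b_C_N, g$a_CA_C_N, psi)
  Ca2 <- .placeAtom(Ca1, C1, N2, g$b_N_CA, g$a_C_N_CA, g$omega_pep)
  C2 <- .placeAtom(C1, N2, Ca2, g$b_CA_C, g$a_N_CA_C, phi)
  list(X = rbind(N1, Ca1, C1), Y = rbind(N2, Ca2, C2))
}

#' Angular turn per residue implied by backbone dihedral angles
#'
#' Maps a backbone dihedral pair (phi, psi) to the helical twist it
#' generates under ideal peptide geometry (standard bond lengths and
#' angles, planar trans peptide). Two consecutive residues are built from
#' the dihedrals and the exact rigid screw carrying one residue's
#' (N, C-alpha, C) triad onto the next is extracted; its signed rotation
#' angle about the advance direction is the angular turn per residue.
#' On the helical ridge this reproduces the classical calibration: dihedral
#' sums phi + psi near -75, -105 and -140 degrees correspond to turns of
#' 120, 100 and 80 deg/residue (3/10, alpha, pi).
#'
#' @param phi,psi backbone dihedrals in degrees, each in [-180, 180);
#'   vectors are mapped elementwise.
#' @return angular turn per residue, deg/residue; positive for right-handed
#'   twist.
#' @examples
#' omegaFromDihedrals(-57, -47)   # ideal alpha, ~100
#' omegaFromDihedrals(-49, -26)   # ideal 3/10, ~120
#' @seealso [idealHelixDihedralSum()] for the inverse along the helical
#'   ridge.
#' @export
omegaFromDihedrals <- function(phi, psi) {
  if (length(phi) != length(psi)) stop("phi and psi must have equal length")
  if (any(!is.finite(c(phi, psi))) || any(abs(c(phi, psi)) > 180))
    stop("dihedrals must be finite angles in [-180, 180]")
  one <- function(f, p) {
    rep_ <- .idealRepeat(f, p)
    cx <- colMeans(rep_$X); cy <- colMeans(rep_$Y)
    H <- t(sweep(rep_$X, 2, cx)) %*% sweep(rep_$Y, 2, cy)
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    tr <- as.numeric(cy - R %*% cx)
    ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
    u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (.norm3(u) < 1e-12) return(0)
    u <- .unit3(u)
    if (sum(u * tr) < 0) ang <- -ang
    .rad2deg(ang)
  }
  mapply(one, phi, psi)
}

#' Dihedral-angle sum on the helical ridge for a given twist
#'
#' Numerically inverts [omegaFromDihedrals()] along the ideal-helix
#' dihedral line to find the backbone dihedral sum phi + psi whose ideal
#' geometry produces a given angular turn per residue. The line is
#' parameterized by the sum with the difference phi - psi held at the
#' ideal alpha-helix value of -10 degrees; across the helical region the
#' twist is nearly a function of the sum alone, so this choice is benign
#' (under 2 degrees of twist variation for differences between -30 and
#' +30).
#'
#' @param omega target angular turn per residue, deg/residue (vectorized).
#' @param diff fixed phi - psi along the line, degrees.
#' @return dihedral sum phi + psi in degrees (about -75, -105, -140 for
#'   omega = 120, 100, 80).
#' @examples
#' idealHelixDihedralSum(100)  # ~ -103
#' @export
idealHelixDihedralSum <- function(omega, diff = -10) {
  vapply(omega, function(w) {
    stats::uniroot(function(s)
      omegaFromDihedrals((s + diff) / 2, (s - diff) / 2) - w,
      interval = c(-175, -30), tol = 1e-10)$root
  }, 0)
}

#' Residues per helical revolution
#'
#' @param omega angular turn per residue, deg/residue (> 0).
#' @return 360 / omega, the number of residues per full turn (3.6 for an
#'   ideal alpha helix).
#' @examples
#' residuesPerRevolution(c(120, 100, 80))  # 3.0 3.6 4.5
#' @export
residuesPerRevolution <- function(omega) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be positive")
  360 / omega
}
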
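#' @include AllClasses.R helix-model.R
NULL

.checkConverged <- function(...) {
  for (f in list(...)) {
    stopifnot(is(f, "HelixFit"))
    if (!f@converged)
      stop("fit of segment '", f@segment@label, "' (",
           f@segment@structureId, ") did not converge")
  }
}

# axial extent (z range about P along n) of a fit's model CA atoms
.axialExtent <- function(fit) {
  p <- fit@params
  idx <- seq_along(fit@segment@resno) - 1
  rise <- p@s * p@omega / 360
  range(idx * rise)
}

#' Angle and distance between two fitted helix axes
#'
#' The interhelix angle is measured between the two N-to-C oriented axes in
#' [0, 180) (fold to [0, 90] yourself if you want the crystallographic
#' crossing-angle convention). The distance is the length of the common
#' perpendicular between the two axis lines; when the perpendicular feet
#' fall outside either fitted segment's axial extent, the distance between
#' the axis segments is reported instead and `clamped` is set.
#'
#' @param fitA,fitB converged [HelixFit-class] objects.
#' @return list with `angle` (degrees), `distance` (Angstrom) and `clamped`
#'   (logical).
#' @export
interhelixGeometry <- function(fitA, fitB) {
  .checkConverged(fitA, fitB)
  n1 <- fitA@params@n; n2 <- fitB@params@n
  P1 <- fitA@params@P; P2 <- fitB@params@P
  angle <- .rad2deg(acos(pmin(1, pmax(-1, sum(n1 * n2)))))
  if (angle >= 180) angle <- 0
  d <- P2 - P1
  extA <- .axialExtent(fitA); extB <- .axialExtent(fitB)
  if (angle < 0.1 || angle > 179.9) {
    # parallel axes: point-to-line distance
    perp <- d - sum(d * n1) * n1
    dist <- .norm3(perp)
    clamped <- FALSE
  } else {
    # common perpendicular between infinite lines P1 + t1 n1, P2 + t2 n2
    b <- sum(n1 * n2)
    t1 <- (sum(d * n1) - b * sum(d * n2)) / (1 - b^2)
    t2 <- (b * sum(d * n1) - sum(d * n2)) / (1 - b^2)
    dist <- .norm3((P1 + t1 * n1) - (P2 + t2 * n2))
    clamped <- t1 < extA[1] || t1 > extA[2] || t2 < extB[1] || t2 > extB[2]
    if (clamped) dist <- .segmentDistance(P1, n1, extA, P2, n2, extB)
  }
  list(angle = angle, distance = dist, clamped = clamped)
}

# minimum distance between two finite 3-D segments (clamped iteration on
# the closed-form line solution; exact for this convex problem)
.segmentDistance <- function(P1, n1, ext1, P2, n2, ext2) {
  f <- function(t) .norm3((P1 + t[1] * n1) - (P2 + t[2] * n2))
  opt <- stats::optim(c(mean(ext1), mean(ext2)), f, method = "L-BFGS-B",
                      lower = c(ext1[1], ext2[1]), upper = c(ext1[2], ext2[2]))
  opt$value
}

#' Torsional position of a fitted helix
#'
#' The circular mean of the four sub-helix phases; its change between two
#' states of a structure is a torsion (axial rotation) of the helix.
#'
#' @param fit a converged [HelixFit-class].
#' @return degrees in [-180, 180).
#' @export
torsionalPosition <- function(fit) {
  .checkConverged(fit)
  .circMean(fit@params@phi)
}

# phases of a fit's sub-helices at residue index 0, measured about its own
# axis but in an externally supplied basis frame, after an optional rigid
# transform of the whole helix
.phasesInFrame <- function(fit, frame, transform = NULL) {
  p <- fit@params
  selfFrame <- buildBasis(p@n)
  vapply(.ATOM_TYPES, function(A) {
    x0 <- p@P + p@t[[A]] * p@n +
      p@radii[[A]] * cos(.deg2rad(p@phi[[A]])) * selfFrame$a +
      p@radii[[A]] * sin(.deg2rad(p@phi[[A]])) * selfFrame$b
    P <- p@P
    if (!is.null(transform)) {
      x0 <- applyTransform(x0, transform)
      P <- applyTransform(P, transform)
    }
    v <- x0 - P
    .rad2deg(atan2(sum(v * frame$b), sum(v * frame$a)))
  }, 0)
}

#' Motion components of one helix between two functional states
#'
#' Quantifies how a named helical segment moves between two structures:
#' `deltaPhase` is the torsional rotation about the axis, `sliding` the
#' longitudinal (piston-like) displacement of the reference point along the
#' state-1 axis (positive toward the C-terminus), `deltaOmega` the
#' winding change. The caller supplies the rigid transform that superposes
#' structure 2 onto structure 1 (typically [kabschTransform()] on a
#' reference C-alpha selection); phases of both states are recomputed in
#' the common basis frame built from the state-1 axis, which makes the
#' phase change well defined across structures.
#'
#' Relative two-helix readouts are differences of per-helix components: the
#' gear-like relative torsion of helices A and B is
#' `deltaPhase_A - deltaPhase_B`.
#'
#' @param fitState1,fitState2 converged [HelixFit-class] objects of the
#'   same named segment in two structures.
#' @param superposition rigid transform (list with `R`, `t`) aligning
#'   structure 2 onto structure 1; defaults to the identity for structures
#'   already in a common frame.
#' @return list with `deltaPhase` (degrees, wrapped to [-180, 180)),
#'   `sliding` (Angstrom), `deltaOmega` (deg/residue) and `angleChange`
#'   (degrees between the two axis directions after superposition).
#' @export
stateMotion <- function(fitState1, fitState2,
                        superposition = list(R = diag(3), t = c(0, 0, 0))) {
  .checkConverged(fitState1, fitState2)
  if (!identical(fitState1@segment@label, fitState2@segment@label))
    stop("segment label mismatch: '", fitState1@segment@label, "' vs '",
         fitState2@segment@label, "'")
  frame1 <- buildBasis(fitState1@params@n)
  ph1 <- .phasesInFrame(fitState1, frame1)
  ph2 <- .phasesInFrame(fitState2, frame1, transform = superposition)
  deltaPhase <- .circMean(ph2 - ph1)
  P2 <- applyTransform(fitState2@params@P, superposition)
  n2 <- as.numeric(superposition$R %*% fitState2@params@n)
  sliding <- sum((P2 - fitState1@params@P) * fitState1@params@n)
  ang <- .rad2deg(acos(pmin(1, pmax(-1, sum(n2 * fitState1@params@n)))))
  list(deltaPhase = deltaPhase, sliding = sliding,
       deltaOmega = fitState2@params@omega - fitState1@params@omega,
       angleChange = ang)
}

#' Within-structure relative phase of two helices
#'
#' Phase of helix A minus phase of helix B (circular means of the sub-helix
#' phases, each in its own deterministic frame), wrapped to [-180, 180).
#' Its change between states equals the difference of the per-helix
#' `deltaPhase` components.
#'
#' @param fitA,fitB converged [HelixFit-class] objects from one structure.
#' @return degrees in [-180, 180).
#' @export
relativePhase <- function(fitA, fitB) {
  .checkConverged(fitA, fitB)
  .wrapAngle(torsionalPosition(fitA) - torsionalPosition(fitB))
}

#' Differential winding between two helix segments
#'
#' Difference in angular turn per residue, first minus second; typically
#' applied to two segments of the same helix, where a nonzero value means
#' the helix is wound to different tightness along its length.
#'
#' @param fitSeg1,fitSeg2 converged [HelixFit-class] objects.
#' @return deg/residue, signed (swapping the arguments negates the value).
#' @export
differentialWinding <- function(fitSeg1, fitSeg2) {
  .checkConverged(fitSeg1, fitSeg2)
  fitSeg1@params@omega - fitSeg2@params@omega
}
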
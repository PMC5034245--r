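#' @import methods
NULL

.ATOM_TYPES <- c("N", "CA", "C", "O")

#' HelixParameters: the 19-parameter model of a straight helix
#'
#' A straight protein helix is described as the superposition of four
#' sub-helices, one per backbone atom type (N, C-alpha, C, O), sharing one
#' axis, one pitch and one angular turn per residue, but each with its own
#' radius, axial offset and phase. The C-alpha axial offset is fixed at zero
#' and is not a free parameter, leaving 19 free scalars: reference point (3),
#' axis direction (2 independent direction-cosine degrees of freedom), four
#' radii, pitch, angular turn per residue, three axial offsets and four
#' phases.
#'
#' @slot P numeric(3), reference point on the axis, in Angstrom. Gauge
#'   convention: the axial foot of the C-alpha sub-helix at the segment's
#'   first residue (residue index 0), which is what fixes the C-alpha axial
#'   offset at exactly zero.
#' @slot n numeric(3), unit axis direction cosines, oriented from the helix
#'   N-terminus towards the C-terminus.
#' @slot radii numeric(4), sub-helix radii in Angstrom, named
#'   `N`, `CA`, `C`, `O`.
#' @slot s numeric(1), pitch in Angstrom per full 360-degree revolution.
#' @slot omega numeric(1), angular turn per residue in degrees; positive for
#'   right-handed helices (the overwhelmingly common case for protein
#'   helices), negative values flag a left-handed solution.
#' @slot t numeric(4), axial offsets of the sub-helices relative to the
#'   C-alpha sub-helix, Angstrom; `t["CA"]` is identically 0.
#' @slot phi numeric(4), sub-helix phases in degrees, reported in the
#'   deterministic basis frame of [buildBasis()] with residue index 0 at the
#'   segment's first residue, wrapped to [-180, 180).
#' @seealso [fitHelix()], [generateHelixCoordinates()]
#' @export
setClass("HelixParameters",
  representation(P = "numeric", n = "numeric", radii = "numeric",
                 s = "numeric", omega = "numeric", t = "numeric",
                 phi = "numeric"))

setValidity("HelixParameters", function(object) {
  msg <- character()
  if (length(object@P) != 3) msg <- c(msg, "P must be a 3-vector")
  if (length(object@n) != 3) msg <- c(msg, "n must be a 3-vector")
  else if (abs(.norm3(object@n) - 1) > 1e-9)
    msg <- c(msg, "n must be a unit vector (|n| = 1 within 1e-9)")
  if (length(object@radii) != 4 || !identical(names(object@radii), .ATOM_TYPES))
    msg <- c(msg, "radii must be named N, CA, C, O")
  else if (any(object@radii <= 0)) msg <- c(msg, "all radii must be > 0")
  if (length(object@omega) != 1 || object@omega == 0 || abs(object@omega) >= 180)
    msg <- c(msg, "omega must be nonzero with |omega| < 180 deg/residue")
  if (length(object@s) != 1 || !is.finite(object@s) ||
      object@s * object@omega[1] <= 0)
    msg <- c(msg, "pitch s must be nonzero with the sign of omega (s > 0 for right-handed helices)")
  if (length(object@t) != 4 || !identical(names(object@t), .ATOM_TYPES))
    msg <- c(msg, "t must be named N, CA, C, O")
  else if (object@t[["CA"]] != 0)
    msg <- c(msg, "t[CA] is the axial reference and must be identically 0")
  if (length(object@phi) != 4 || !identical(names(object@phi), .ATOM_TYPES))
    msg <- c(msg, "phi must be named N, CA, C, O")
  if (length(msg)) msg else TRUE
})

#' Construct a HelixParameters object
#'
#' @param P reference point (3-vector, Angstrom).
#' @param n axis direction (unit 3-vector, N- to C-terminus).
#' @param radii sub-helix radii, Angstrom; length-4, in N, CA, C, O order
#'   (names are attached if absent).
#' @param s pitch, Angstrom per revolution.
#' @param omega angular turn per residue, degrees.
#' @param t axial offsets relative to C-alpha, Angstrom; `t[CA]` must be 0.
#' @param phi sub-helix phases, degrees.
#' @return a validated [HelixParameters-class] object.
#' @examples
#' p <- helixParameters(P = c(0, 0, 0), n = c(0, 0, 1),
#'                      radii = c(1.5, 2.3, 1.7, 2.0), s = 5.4, omega = 100,
#'                      t = c(-0.9, 0, 1.1, 2.3),
#'                      phi = c(-27, 0, 27, 20))
#' helixDiameter(p)
#' @export
helixParameters <- function(P, n, radii, s, omega, t, phi) {
  nm <- function(x) { x <- as.numeric(x); names(x) <- .ATOM_TYPES; x }
  new("HelixParameters", P = as.numeric(P), n = as.numeric(n),
      radii = nm(radii), s = as.numeric(s), omega = as.numeric(omega),
      t = nm(t), phi = nm(.wrapAngle(phi)))
}

#' HelixSegment: extracted backbone coordinates of one helical segment
#'
#' Holds, for a named chain / residue range of one structure, the coordinates
#' of the four backbone atoms N, C-alpha, C and O of every retained residue.
#' Residues missing any of the four atoms are dropped (with a warning) before
#' a segment is built, so every row of the coordinate array is complete.
#'
#' @slot structureId text identifier (e.g. PDB code).
#' @slot chainId chain identifier.
#' @slot label segment name (e.g. "TM5c").
#' @slot resno integer author residue numbers, strictly increasing in
#'   sequence order.
#' @slot insert insertion codes ("" when absent), parallel to `resno`.
#' @slot coords numeric array `[residue, atom, xyz]` with atom dimension
#'   named N, CA, C, O; Angstrom.
#' @export
setClass("HelixSegment",
  representation(structureId = "character", chainId = "character",
                 label = "character", resno = "integer",
                 insert = "character", coords = "array"))

setValidity("HelixSegment", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 4 || d[3] != 3)
    msg <- c(msg, "coords must be an [nres, 4, 3] array")
  else {
    if (!identical(dimnames(object@coords)[[2]], .ATOM_TYPES))
      msg <- c(msg, "coords atom dimension must be named N, CA, C, O")
    if (d[1] < 1) msg <- c(msg, "segment must contain at least one residue")
    if (d[1] != length(object@resno))
      msg <- c(msg, "resno length must match the residue dimension")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coords must be finite (incomplete residues are dropped before construction)")
  }
  if (length(object@resno) > 1) {
    key <- order(object@resno, object@insert)
    if (!identical(key, seq_along(object@resno)))
      msg <- c(msg, "residues must be in increasing author order")
    if (anyDuplicated(paste(object@resno, object@insert)))
      msg <- c(msg, "duplicate residue identifiers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HelixSegment from coordinate matrices
#'
#' @param coords array `[nres, 4, 3]` (atoms N, CA, C, O) or a list with
#'   elements `N`, `CA`, `C`, `O`, each an nres x 3 matrix.
#' @param resno author residue numbers (defaults to `1:nres`).
#' @param insert insertion codes (defaults to `""`).
#' @param structureId,chainId,label identifying metadata.
#' @return a [HelixSegment-class] object.
#' @export
helixSegment <- function(coords, resno = NULL, insert = NULL,
                         structureId = "synthetic", chainId = "A",
                         label = "helix") {
  if (is.list(coords)) {
    nres <- nrow(coords[[1]])
    arr <- array(NA_real_, c(nres, 4, 3),
                 dimnames = list(NULL, .ATOM_TYPES, c("x", "y", "z")))
    for (a in .ATOM_TYPES) arr[, a, ] <- as.matrix(coords[[a]])
    coords <- arr
  }
  nres <- dim(coords)[1]
  if (is.null(resno)) resno <- seq_len(nres)
  if (is.null(insert)) insert <- rep("", nres)
  new("HelixSegment", structureId = structureId, chainId = chainId,
      label = label, resno = as.integer(resno), insert = insert,
      coords = coords)
}

#' HelixFit: a converged helix parameterization with fit diagnostics
#'
#' @slot params the gauge-normalized [HelixParameters-class].
#' @slot segment the fitted [HelixSegment-class].
#' @slot rmsd root-mean-square deviation between observed and model atoms,
#'   Angstrom.
#' @slot converged logical convergence flag from the optimizer.
#' @slot nAtoms number of atoms entering the fit.
#' @slot perAtomResiduals per-atom observed-model distances, Angstrom.
#' @slot free the converged 19-entry free-parameter vector as seen by the
#'   optimizer (named; the C-alpha axial offset is structurally excluded).
#' @slot leftHanded TRUE when the best solution has negative twist.
#' @export
setClass("HelixFit",
  representation(params = "HelixParameters", segment = "HelixSegment",
                 rmsd = "numeric", converged = "logical", nAtoms = "integer",
                 perAtomResiduals = "numeric", free = "numeric",
                 leftHanded = "logical"))

setValidity("HelixFit", function(object) {
  msg <- character()
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (length(object@free) != 19)
    msg <- c(msg, "free-parameter vector must have exactly 19 entries")
  if ("t_CA" %in% names(object@free))
    msg <- c(msg, "t_CA must not appear among free parameters")
  if (length(msg)) msg else TRUE
})

#' SpiralDiagram: observed and fitted per-residue phases for plotting
#'
#' @slot data data.frame with columns `resno`, `observedPhase`,
#'   `fittedPhase` (degrees in [0, 360), origin at the fitted phase of the
#'   first residue), `radius` (unitless plotting radius, growing linearly
#'   with residue index) and `colorIndex` (0-3 cycling black, red, green,
#'   blue).
#' @slot label segment label.
#' @slot omega fitted angular turn per residue, degrees.
#' @export
setClass("SpiralDiagram",
  representation(data = "data.frame", label = "character", omega = "numeric"))

setValidity("SpiralDiagram", function(object) {
  need <- c("resno", "observedPhase", "fittedPhase", "radius", "colorIndex")
  msg <- character()
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("data must contain columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@data) < 1) msg <- c(msg, "diagram must be non-empty")
    else if (abs(object@data$fittedPhase[1]) > 1e-6)
      msg <- c(msg, "first residue's fitted phase must be 0 (fixed horizontal axis)")
    ph <- c(object@data$observedPhase, object@data$fittedPhase)
    if (any(ph < 0 | ph >= 360)) msg <- c(msg, "phases must be wrapped to [0, 360)")
  }
  if (length(msg)) msg else TRUE
})
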
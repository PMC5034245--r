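#' @include AllClasses.R helix-model.R
NULL

# Canonical sub-helix constants per helix form, derived once from ideal
# backbone covalent geometry (standard bond lengths/angles, planar trans
# peptide) at the backbone dihedrals whose exact screw gives the form's
# ideal angular turn (120, 100, 80 deg/residue). Radii and pitch in
# Angstrom, phases in degrees relative to the C-alpha sub-helix. These are
# generator inputs for testing, not measurements.
.FORM_CONSTANTS <- list(
  three_ten = list(omega = 120, s = 5.9554,
                   radii = c(N = 1.0626, CA = 1.8734, C = 1.2377, O = 1.6799),
                   t = c(N = -1.0513, CA = 0, C = 1.1931, O = 2.3233),
                   phi = c(N = -24.661, CA = 0, C = 26.793, O = 18.587)),
  alpha = list(omega = 100, s = 5.6744,
               radii = c(N = 1.5333, CA = 2.2597, C = 1.6479, O = 1.9062),
               t = c(N = -0.9247, CA = 0, C = 1.0747, O = 2.2609),
               phi = c(N = -26.777, CA = 0, C = 26.737, O = 20.141)),
  pi = list(omega = 80, s = 3.3555,
            radii = c(N = 2.3075, CA = 2.9015, C = 2.2720, O = 2.2270),
            t = c(N = -0.6458, CA = 0, C = 0.8032, O = 2.0329),
            phi = c(N = -26.006, CA = 0, C = 25.498, O = 24.628)))

#' Canonical helix parameters for an ideal helix form
#'
#' @param form `"three_ten"`, `"alpha"` or `"pi"`.
#' @param P,n axis placement (default: origin, +z).
#' @param omega,s overrides for angular turn (deg/residue) and pitch
#'   (Angstrom/revolution); by default the form's canonical values. When
#'   only `omega` is overridden the pitch is rescaled to preserve the
#'   form's axial rise per residue.
#' @param phiCA phase of the C-alpha sub-helix, degrees (the other three
#'   phases keep their canonical offsets relative to it).
#' @return a [HelixParameters-class].
#' @export
idealHelixParameters <- function(form = c("alpha", "three_ten", "pi"),
                                 P = c(0, 0, 0), n = c(0, 0, 1),
                                 omega = NULL, s = NULL, phiCA = 0) {
  form <- match.arg(form)
  k <- .FORM_CONSTANTS[[form]]
  if (is.null(omega)) omega <- k$omega
  if (is.null(s)) s <- k$s * k$omega / omega   # keep the canonical rise
  helixParameters(P = P, n = .unit3(n), radii = k$radii, s = s,
                  omega = omega, t = k$t, phi = k$phi + phiCA)
}

.writeBackbonePDB <- function(file, coordsList, append = FALSE) {
  # coordsList: list of list(coords = [nres,4,3], resno, chain)
  xyz <- c(); resno <- c(); elety <- c(); chain <- c()
  for (h in coordsList) {
    nres <- dim(h$coords)[1]
    for (j in seq_len(nres)) {
      for (A in .ATOM_TYPES) {
        xyz <- c(xyz, h$coords[j, A, ])
        resno <- c(resno, h$resno[j])
        elety <- c(elety, A)
        chain <- c(chain, h$chain)
      }
    }
  }
  n <- length(elety)
  bio3d::write.pdb(pdb = NULL, file = file, xyz = round(xyz, 3),
                   resno = resno, resid = rep("ALA", n),
                   eleno = seq_len(n), elety = elety, chain = chain,
                   o = rep(1, n), b = rep(0, n))
  invisible(file)
}

.applyPerturbation <- function(coords, pert, params) {
  type <- pert$type
  mag <- pert$magnitude
  n <- params@n
  if (is.null(type) || is.null(mag)) stop("perturbation needs 'type' and 'magnitude'")
  nres <- dim(coords)[1]
  rows <- if (!is.null(pert$target)) {
    which(seq_len(nres) >= pert$target[1] & seq_len(nres) <= pert$target[2])
  } else seq_len(nres)
  flatApply <- function(coords, rows, f) {
    for (A in .ATOM_TYPES) coords[rows, A, ] <- f(coords[rows, A, , drop = TRUE])
    coords
  }
  asMat <- function(x) if (is.null(dim(x))) matrix(x, 1) else x
  switch(type,
    axial_shift = flatApply(coords, rows, function(x)
      sweep(asMat(x), 2, mag * n, "+")),
    axis_rotation = {
      R <- .rotationAboutAxis(n, mag)
      flatApply(coords, rows, function(x) {
        v <- sweep(asMat(x), 2, params@P)
        sweep(v %*% t(R), 2, params@P, "+")
      })
    },
    rigid_move = {
      R <- .rotationAboutAxis(c(1, 2, 3), mag)
      tr <- c(3.1, -2.2, 1.3)
      flatApply(coords, rows, function(x)
        sweep(asMat(x) %*% t(R), 2, tr, "+"))
    },
    kink = {
      at <- if (is.null(pert$at)) floor(nres / 2) else pert$at
      pivot <- coords[at, "CA", ]
      axis <- buildBasis(n)$a
      R <- .rotationAboutAxis(axis, mag)
      bendRows <- intersect(rows, (at + 1):nres)
      flatApply(coords, bendRows, function(x) {
        v <- sweep(asMat(x), 2, pivot)
        sweep(v %*% t(R), 2, pivot, "+")
      })
    },
    delta_omega = stop("delta_omega is applied at generation time; pass it via 'omega' or bundle programming"),
    stop("unknown perturbation type: '", type, "'"))
}

#' Generate a synthetic helix fixture as a PDB file with ground truth
#'
#' Places backbone N, C-alpha, C, O atoms with the four-sub-helix forward
#' model using canonical constants for the chosen form, optionally applies
#' geometric perturbations (in listed order) and per-coordinate Gaussian
#' noise, writes a PDB file, and records the generating parameters as JSON
#' ground truth next to it. Same seed, same arguments: byte-identical
#' output.
#'
#' @param file output PDB path; ground truth goes to `paste0(file, ".json")`.
#' @param form helix form, see [idealHelixParameters()].
#' @param nResidues number of residues (>= 5).
#' @param omega,s overrides of angular turn and pitch.
#' @param noiseSigma standard deviation of isotropic Gaussian coordinate
#'   noise, Angstrom.
#' @param perturbations list of perturbation records, each a list with
#'   `type` (`"axial_shift"`, `"axis_rotation"`, `"rigid_move"`, `"kink"`),
#'   `magnitude` (Angstrom or degrees as appropriate), optional `target`
#'   residue-index range `c(first, last)` and, for kinks, the split residue
#'   `at`.
#' @param seed integer RNG seed (default 1).
#' @param chain,startRes,structureId PDB bookkeeping.
#' @param P,n,phiCA helix placement, see [idealHelixParameters()].
#' @return invisibly, a list with `file`, `truthFile`, the generating
#'   [HelixParameters-class] in `params`, and the [HelixSegment-class] of
#'   the written coordinates in `segment`.
#' @export
makeFixture <- function(file, form = "alpha", nResidues = 18, omega = NULL,
                        s = NULL, noiseSigma = 0, perturbations = list(),
                        seed = 1L, chain = "A", startRes = 1L,
                        structureId = "fixture", P = c(0, 0, 0),
                        n = c(0, 0, 1), phiCA = 0) {
  if (nResidues < 5) stop("nResidues must be >= 5")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  params <- idealHelixParameters(form, P = P, n = n, omega = omega, s = s,
                                 phiCA = phiCA)
  coords <- generateHelixCoordinates(params, residueIndices = 0:(nResidues - 1))
  for (pert in perturbations) coords <- .applyPerturbation(coords, pert, params)
  if (noiseSigma > 0) {
    set.seed(as.integer(seed))
    coords <- coords + array(stats::rnorm(length(coords), 0, noiseSigma),
                             dim(coords))
  }
  resno <- seq(startRes, length.out = nResidues)
  .writeBackbonePDB(file, list(list(coords = coords, resno = resno,
                                    chain = chain)))
  truthFile <- paste0(file, ".json")
  truth <- list(form = form, nResidues = nResidues,
                omega = params@omega, s = params@s,
                radii = as.list(params@radii), t = as.list(params@t),
                phi = as.list(params@phi), P = params@P, n = params@n,
                noiseSigma = noiseSigma, seed = seed,
                perturbations = perturbations)
  jsonlite::write_json(truth, truthFile, auto_unbox = TRUE, digits = NA)
  seg <- helixSegment(coords, resno = resno, structureId = structureId,
                      chainId = chain, label = form)
  invisible(list(file = file, truthFile = truthFile, params = params,
                 segment = seg))
}

#' Generate a two-state seven-helix bundle with programmed motions
#'
#' Builds a rhodopsin-like bundle of seven alpha helices arranged on a ring
#' (all chains 'A', helix k occupying residues (k-1)*30+1 onward, slight
#' deterministic outward tilts), then a second state in which named helices
#' carry programmed conformational changes: winding change `deltaOmega`
#' (deg/residue), torsion `axisRotation` (degrees about the helix's own
#' axis), longitudinal `sliding` (Angstrom along the axis, positive toward
#' the C-terminus) and `tilt` (degrees about a perpendicular axis through
#' the helix midpoint). State 2 as a whole is additionally moved by a rigid
#' transform (when `globalMove` is TRUE) so that cross-state comparisons
#' must superpose first, as with real structures. Both states are written
#' as PDB files together with a JSON ground-truth motion record and a
#' segment config naming TM1-TM7.
#'
#' @param dir output directory (created if needed).
#' @param programmed named list, e.g.
#'   `list(TM5 = list(deltaOmega = -3), TM6 = list(axisRotation = 15))`;
#'   names must be among TM1-TM7.
#' @param nResidues residues per helix.
#' @param ringRadius bundle ring radius, Angstrom.
#' @param noiseSigma Gaussian coordinate noise, Angstrom (applied to both
#'   states with seeds derived from `seed`).
#' @param seed integer RNG seed.
#' @param globalMove rigid-move state 2 before writing (default TRUE).
#' @return list with `state1`, `state2` (PDB paths), `truthFile`,
#'   `segmentConfig` (YAML path) and `truth` (the ground-truth list).
#' @export
makeTwoStateBundle <- function(dir, programmed = list(),
                               nResidues = 18, ringRadius = 16,
                               noiseSigma = 0, seed = 1L, globalMove = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  helices <- paste0("TM", 1:7)
  bad <- setdiff(names(programmed), helices)
  if (length(bad)) stop("programmed motions name unknown helices: ",
                        paste(bad, collapse = ", "))
  buildState <- function(state) {
    out <- list()
    for (k in 1:7) {
      nm <- helices[k]
      ang <- 2 * pi * (k - 1) / 7
      radial <- c(cos(ang), sin(ang), 0)
      Pk <- ringRadius * radial
      # small deterministic outward tilt, alternating magnitude
      nk <- .unit3(c(0, 0, 1) + (0.04 + 0.02 * (k %% 3)) * radial)
      prog <- if (state == 2) programmed[[nm]] else NULL
      om <- 100 + if (!is.null(prog$deltaOmega)) prog$deltaOmega else 0
      params <- idealHelixParameters("alpha", P = Pk, n = nk, omega = om,
                                     phiCA = 40 * k)
      coords <- generateHelixCoordinates(params,
                                         residueIndices = 0:(nResidues - 1))
      if (!is.null(prog$axisRotation))
        coords <- .applyPerturbation(coords,
          list(type = "axis_rotation", magnitude = prog$axisRotation), params)
      if (!is.null(prog$sliding))
        coords <- .applyPerturbation(coords,
          list(type = "axial_shift", magnitude = prog$sliding), params)
      if (!is.null(prog$tilt)) {
        mid <- coords[floor(nResidues / 2), "CA", ]
        R <- .rotationAboutAxis(buildBasis(params@n)$a, prog$tilt)
        for (A in .ATOM_TYPES) {
          v <- sweep(coords[, A, ], 2, mid)
          coords[, A, ] <- sweep(v %*% t(R), 2, mid, "+")
        }
      }
      out[[nm]] <- list(coords = coords, resno = seq((k - 1) * 30 + 1,
                                                     length.out = nResidues),
                        chain = "A")
    }
    out
  }
  st1 <- buildState(1)
  st2 <- buildState(2)
  if (globalMove) {
    R <- .rotationAboutAxis(c(1, 1, 0), 10)
    tr <- c(4, -3, 2)
    for (nm in helices)
      for (A in .ATOM_TYPES)
        st2[[nm]]$coords[, A, ] <-
          sweep(st2[[nm]]$coords[, A, ] %*% t(R), 2, tr, "+")
  }
  if (noiseSigma > 0) {
    set.seed(as.integer(seed))
    for (nm in helices) {
      st1[[nm]]$coords <- st1[[nm]]$coords +
        array(stats::rnorm(length(st1[[nm]]$coords), 0, noiseSigma),
              dim(st1[[nm]]$coords))
      st2[[nm]]$coords <- st2[[nm]]$coords +
        array(stats::rnorm(length(st2[[nm]]$coords), 0, noiseSigma),
              dim(st2[[nm]]$coords))
    }
  }
  f1 <- file.path(dir, "state1.pdb"); f2 <- file.path(dir, "state2.pdb")
  .writeBackbonePDB(f1, st1)
  .writeBackbonePDB(f2, st2)
  truth <- list(
    helices = lapply(seq_along(helices), function(k) {
      nm <- helices[k]
      prog <- programmed[[nm]]
      list(name = nm, startRes = (k - 1) * 30 + 1,
           endRes = (k - 1) * 30 + nResidues,
           deltaOmega = if (!is.null(prog$deltaOmega)) prog$deltaOmega else 0,
           axisRotation = if (!is.null(prog$axisRotation)) prog$axisRotation else 0,
           sliding = if (!is.null(prog$sliding)) prog$sliding else 0,
           tilt = if (!is.null(prog$tilt)) prog$tilt else 0)
    }),
    noiseSigma = noiseSigma, seed = seed, globalMove = globalMove)
  truthFile <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truthFile, auto_unbox = TRUE, digits = NA)
  cfgFile <- file.path(dir, "segments.yaml")
  cfg <- list(segments = lapply(seq_along(helices), function(k)
    list(name = helices[k], chain = "A", start = (k - 1) * 30 + 1,
         end = (k - 1) * 30 + nResidues)))
  yaml::write_yaml(cfg, cfgFile)
  list(state1 = f1, state2 = f2, truthFile = truthFile,
       segmentConfig = cfgFile, truth = truth)
}
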
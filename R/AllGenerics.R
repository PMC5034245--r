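#' @include AllClasses.R
NULL

#' Accessors for helix parameterizations
#'
#' Getter generics shared by [HelixParameters-class] and
#' [HelixFit-class] objects; a `HelixFit` delegates to its embedded
#' parameters.
#'
#' @param object a `HelixParameters` or `HelixFit`.
#' @return `helixOmega`: angular turn per residue (deg/residue);
#'   `helixPitch`: pitch (Angstrom/revolution); `helixRadii`: named
#'   sub-helix radii (Angstrom); `helixPhases`: named sub-helix phases
#'   (degrees); `axialOffsets`: named axial offsets relative to C-alpha
#'   (Angstrom); `axisDirection`: unit axis vector; `referencePoint`:
#'   reference point on the axis (Angstrom); `helixDiameter`: twice the mean
#'   sub-helix radius (Angstrom); `meanPhase`: circular mean of the four
#'   phases (degrees).
#' @name helix-accessors
NULL

#' @rdname helix-accessors
#' @export
setGeneric("helixOmega", function(object) standardGeneric("helixOmega"))
#' @rdname helix-accessors
#' @export
setGeneric("helixPitch", function(object) standardGeneric("helixPitch"))
#' @rdname helix-accessors
#' @export
setGeneric("helixRadii", function(object) standardGeneric("helixRadii"))
#' @rdname helix-accessors
#' @export
setGeneric("helixPhases", function(object) standardGeneric("helixPhases"))
#' @rdname helix-accessors
#' @export
setGeneric("axialOffsets", function(object) standardGeneric("axialOffsets"))
#' @rdname helix-accessors
#' @export
setGeneric("axisDirection", function(object) standardGeneric("axisDirection"))
#' @rdname helix-accessors
#' @export
setGeneric("referencePoint", function(object) standardGeneric("referencePoint"))
#' @rdname helix-accessors
#' @export
setGeneric("helixDiameter", function(object) standardGeneric("helixDiameter"))
#' @rdname helix-accessors
#' @export
setGeneric("meanPhase", function(object) standardGeneric("meanPhase"))

#' @rdname helix-accessors
setMethod("helixOmega", "HelixParameters", function(object) object@omega)
#' @rdname helix-accessors
setMethod("helixPitch", "HelixParameters", function(object) object@s)
#' @rdname helix-accessors
setMethod("helixRadii", "HelixParameters", function(object) object@radii)
#' @rdname helix-accessors
setMethod("helixPhases", "HelixParameters", function(object) object@phi)
#' @rdname helix-accessors
setMethod("axialOffsets", "HelixParameters", function(object) object@t)
#' @rdname helix-accessors
setMethod("axisDirection", "HelixParameters", function(object) object@n)
#' @rdname helix-accessors
setMethod("referencePoint", "HelixParameters", function(object) object@P)
#' @rdname helix-accessors
setMethod("helixDiameter", "HelixParameters",
          function(object) 2 * mean(object@radii))
#' @rdname helix-accessors
setMethod("meanPhase", "HelixParameters",
          function(object) .circMean(object@phi))

for (g in c("helixOmega", "helixPitch", "helixRadii", "helixPhases",
            "axialOffsets", "axisDirection", "referencePoint",
            "helixDiameter", "meanPhase")) {
  local({
    gg <- g
    setMethod(gg, "HelixFit", function(object) {
      do.call(gg, list(object@params))
    })
  })
}

#' Fit diagnostics accessors
#'
#' @param object a [HelixFit-class].
#' @return `fitRMSD`: Angstrom; `isConverged`: logical; `helixParams`: the
#'   embedded [HelixParameters-class].
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("fitRMSD", function(object) standardGeneric("fitRMSD"))
#' @rdname fit-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname fit-accessors
#' @export
setGeneric("helixParams", function(object) standardGeneric("helixParams"))

#' @rdname fit-accessors
setMethod("fitRMSD", "HelixFit", function(object) object@rmsd)
#' @rdname fit-accessors
setMethod("isConverged", "HelixFit", function(object) object@converged)
#' @rdname fit-accessors
setMethod("helixParams", "HelixFit", function(object) object@params)

setMethod("show", "HelixParameters", function(object) {
  cat("HelixParameters (4 sub-helices, 19 free parameters)\n")
  cat(sprintf("  axis n: (%.4f, %.4f, %.4f)   P: (%.2f, %.2f, %.2f) A\n",
              object@n[1], object@n[2], object@n[3],
              object@P[1], object@P[2], object@P[3]))
  cat(sprintf("  omega: %.3f deg/residue (%.2f residues/turn)   pitch s: %.3f A\n",
              object@omega, 360 / abs(object@omega), object@s))
  cat(sprintf("  radii (A):   N %.3f  CA %.3f  C %.3f  O %.3f   diameter %.3f\n",
              object@radii[1], object@radii[2], object@radii[3],
              object@radii[4], 2 * mean(object@radii)))
  cat(sprintf("  t (A):       N %+.3f CA %+.3f C %+.3f O %+.3f\n",
              object@t[1], object@t[2], object@t[3], object@t[4]))
  cat(sprintf("  phi (deg):   N %+.1f CA %+.1f C %+.1f O %+.1f   mean %+.1f\n",
              object@phi[1], object@phi[2], object@phi[3], object@phi[4],
              .circMean(object@phi)))
  invisible(object)
})

setMethod("show", "HelixSegment", function(object) {
  cat(sprintf("HelixSegment '%s' (%s, chain %s): %d residues %s-%s\n",
              object@label, object@structureId, object@chainId,
              length(object@resno), object@resno[1],
              object@resno[length(object@resno)]))
  invisible(object)
})

setMethod("show", "HelixFit", function(object) {
  cat(sprintf("HelixFit of '%s' (%s/%s): %s, rmsd %.4f A over %d atoms\n",
              object@segment@label, object@segment@structureId,
              object@segment@chainId,
              if (object@converged) "converged" else "NOT converged",
              object@rmsd, object@nAtoms))
  if (object@leftHanded) cat("  ! left-handed solution (omega < 0)\n")
  show(object@params)
  invisible(object)
})

setMethod("show", "SpiralDiagram", function(object) {
  cat(sprintf("SpiralDiagram '%s': %d residues, omega %.2f deg/residue\n",
              object@label, nrow(object@data), object@omega))
  invisible(object)
})
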
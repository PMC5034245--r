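#' @include AllClasses.R helix-model.R
NULL

#' Build spiral (wenxiang) diagram data for a fitted segment
#'
#' Each residue is represented by the average position of its N, C-alpha,
#' C and O atoms. The observed phase of residue i is the azimuth, in the
#' fit's basis frame, of that average point projected onto the plane normal
#' to the axis; the fitted phase is the azimuth of the model's average
#' point, which advances by exactly omega per residue. Both series are
#' offset so that the fitted phase of the first residue is 0 — the first
#' residue starts on the fixed horizontal axis — and wrapped to [0, 360).
#' The plotting radius grows linearly with residue index (inner to outer)
#' and colors cycle black, red, green, blue.
#'
#' @param segment the [HelixSegment-class] that was fitted.
#' @param fit the converged [HelixFit-class] of that segment.
#' @return a [SpiralDiagram-class].
#' @export
makeSpiral <- function(segment, fit) {
  stopifnot(is(segment, "HelixSegment"), is(fit, "HelixFit"))
  if (!fit@converged) stop("spiral diagram requires a converged fit")
  p <- fit@params
  frame <- buildBasis(p@n)
  idx <- seq_along(segment@resno) - 1
  model <- generateHelixCoordinates(p, frame, idx)
  azim <- function(arr) {
    avg <- apply(arr, c(1, 3), mean)          # residue-average of N,CA,C,O
    v <- sweep(avg, 2, p@P)
    .rad2deg(atan2(v %*% frame$b, v %*% frame$a))[, 1]
  }
  zObs <- azim(segment@coords)
  zFit <- azim(model)
  origin <- zFit[1]
  data <- data.frame(
    resno = segment@resno,
    observedPhase = .wrapAngle(zObs - origin, lower = 0),
    fittedPhase = .wrapAngle(zFit - origin, lower = 0),
    radius = 1 + idx * 0.35,
    colorIndex = idx %% 4L)
  data$fittedPhase[1] <- 0
  new("SpiralDiagram", data = data, label = segment@label, omega = p@omega)
}

.SPIRAL_COLORS <- c("black", "red", "green", "blue")

#' Render a spiral diagram as SVG
#'
#' Writes a deterministic vector image: solid dots for observed residue
#' phases, open circles for fitted phases (their superposition indicates
#' the goodness of fit), the first residue on the +x axis, residue colors
#' cycling black, red, green, blue, and a faint archimedean guide spiral.
#' Identical inputs produce byte-identical files.
#'
#' @param diagram a [SpiralDiagram-class].
#' @param path output `.svg` path.
#' @return `path`, invisibly.
#' @export
renderSpiral <- function(diagram, path) {
  stopifnot(is(diagram, "SpiralDiagram"))
  d <- diagram@data
  if (nrow(d) == 0) stop("empty diagram")
  dirp <- dirname(path)
  if (!dir.exists(dirp)) stop("directory does not exist: '", dirp, "'")
  size <- 480
  cx <- size / 2
  scale <- (size / 2 - 40) / max(d$radius)
  px <- function(r, phaseDeg) {
    th <- .deg2rad(phaseDeg)
    c(cx + scale * r * cos(th), cx - scale * r * sin(th))
  }
  num <- function(x) sprintf("%.3f", x)
  ln <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                  size, size, size, size),
          sprintf('<line x1="%s" y1="%s" x2="%d" y2="%s" stroke="gray" stroke-width="0.5"/>',
                  num(cx), num(cx), size, num(cx)))
  # guide spiral through the residue slots (20 steps per residue)
  n <- nrow(d)
  if (n > 1) {
    tt <- seq(0, n - 1, by = 0.05)
    rr <- 1 + tt * 0.35
    ph <- tt * diagram@omega
    pts <- t(vapply(seq_along(tt), function(k) px(rr[k], ph[k]), c(0, 0)))
    ln <- c(ln, sprintf('<polyline fill="none" stroke="#cccccc" stroke-width="0.6" points="%s"/>',
                        paste(sprintf("%.2f,%.2f", pts[, 1], pts[, 2]),
                              collapse = " ")))
  }
  for (i in seq_len(n)) {
    col <- .SPIRAL_COLORS[d$colorIndex[i] + 1]
    po <- px(d$radius[i], d$observedPhase[i])
    pf <- px(d$radius[i], d$fittedPhase[i])
    ln <- c(ln,
      sprintf('<circle class="observed" cx="%s" cy="%s" r="4" fill="%s"/>',
              num(po[1]), num(po[2]), col),
      sprintf('<circle class="fitted" cx="%s" cy="%s" r="6" fill="none" stroke="%s" stroke-width="1.2"/>',
              num(pf[1]), num(pf[2]), col),
      sprintf('<text x="%s" y="%s" font-size="8" fill="%s">%d</text>',
              num(po[1] + 6), num(po[2] - 6), col, d$resno[i]))
  }
  ln <- c(ln, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(ln, con, sep = "\n")
  invisible(path)
}

#' Write spiral diagram data as TSV
#'
#' @param diagram a [SpiralDiagram-class].
#' @param path output file path.
#' @return the data.frame written, invisibly.
#' @export
writeSpiralTable <- function(diagram, path) {
  stopifnot(is(diagram, "SpiralDiagram"))
  utils::write.table(diagram@data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(diagram@data)
}
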
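#' @import methods
NULL

#' SigmaField: microvillar principal axes on a hexagonal lattice
#'
#' Container for per-ommatidium microvillar principal axes Sigma on an axial
#' hexagonal lattice. Sigma is an axial angle: it is defined modulo 90 degrees
#' (the angle of eye rotation at which depolarized eyeshine is minimal) and is
#' stored in [0, 90). Cells outside the illuminated patch, or failing quality
#' control, carry \code{measured = FALSE} and \code{NA} Sigma.
#'
#' @slot coords data.frame with integer columns \code{q}, \code{r} (axial
#'   coordinates), one row per lattice cell.
#' @slot sigma numeric, principal axis in degrees, \code{NA} where unmeasured.
#' @slot measured logical, whether the cell carries a measured Sigma.
#' @slot metadata list of free-form patch metadata (e.g. \code{patch_id},
#'   \code{sex}, \code{elevation_deg}, \code{azimuth_deg}).
#'
#' @seealso [generateSigmaField()], [estimatePatch()], [patchMetrics()]
#' @export
setClass("SigmaField",
  representation(
    coords = "data.frame",
    sigma = "numeric",
    measured = "logical",
    metadata = "list"
  )
)

setValidity("SigmaField", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (!all(c("q", "r") %in% names(object@coords)))
    msg <- c(msg, "coords must have columns 'q' and 'r'")
  if (length(object@sigma) != n || length(object@measured) != n)
    msg <- c(msg, "sigma and measured must match nrow(coords)")
  if (n > 0 && anyDuplicated(object@coords[, c("q", "r")]))
    msg <- c(msg, "duplicated lattice coordinates")
  meas <- object@measured
  s <- object@sigma[meas]
  if (any(!is.finite(s)))
    msg <- c(msg, "measured cells must have finite sigma")
  else if (any(s < 0 | s >= 90))
    msg <- c(msg, "sigma must lie in [0, 90)")
  if (any(!is.na(object@sigma[!meas])))
    msg <- c(msg, "unmeasured cells must have NA sigma")
  if (length(msg)) msg else TRUE
})

#' Construct a SigmaField
#'
#' @param q,r Integer axial coordinates, one entry per lattice cell.
#' @param sigma Principal axis in degrees, in [0, 90); \code{NA} where the
#'   cell was not measured.
#' @param measured Logical; defaults to \code{!is.na(sigma)}.
#' @param metadata Optional list of patch metadata.
#' @return A [SigmaField-class] object.
#' @export
#' @examples
#' f <- SigmaField(q = c(0, 1), r = c(0, 0), sigma = c(10, 40))
#' sigmaValues(f)
SigmaField <- function(q, r, sigma, measured = !is.na(sigma),
                       metadata = list()) {
  new("SigmaField",
    coords = data.frame(q = as.integer(q), r = as.integer(r)),
    sigma = as.numeric(sigma), measured = as.logical(measured),
    metadata = metadata
  )
}

setMethod("show", "SigmaField", function(object) {
  n <- nrow(object@coords)
  nm <- sum(object@measured)
  cat("SigmaField with", n, "lattice cells (", nm, "measured )\n")
  if (nm > 0) {
    s <- object@sigma[object@measured]
    cat(sprintf("  sigma range: [%.2f, %.2f] deg\n", min(s), max(s)))
  }
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  invisible(NULL)
})

#' EyeshineStack: depolarized eyeshine images over eye roll angles
#'
#' Ordered image frames of a patch of depolarized eyeshine spots, one frame
#' per eye roll angle theta, per colour channel. Frames are stored as
#' height x width x n_frames numeric arrays (counts), one array per channel.
#'
#' @slot thetas numeric, strictly increasing roll angles in degrees.
#' @slot frames named list of 3-D arrays, one per channel.
#' @slot channels character, channel names (subset of R, G, B, mono).
#' @slot spacing numeric, lattice spot spacing in pixels.
#' @slot centers data.frame of spot centres (\code{q}, \code{r}, \code{x},
#'   \code{y}) in pixel coordinates.
#' @seealso [renderEyeshineStack()], [extractIntensitySeries()]
#' @export
setClass("EyeshineStack",
  representation(
    thetas = "numeric",
    frames = "list",
    channels = "character",
    spacing = "numeric",
    centers = "data.frame"
  )
)

setValidity("EyeshineStack", function(object) {
  msg <- character()
  nt <- length(object@thetas)
  if (nt < 1) msg <- c(msg, "at least one frame required")
  if (is.unsorted(object@thetas, strictly = TRUE))
    msg <- c(msg, "thetas must be strictly increasing")
  if (!setequal(names(object@frames), object@channels))
    msg <- c(msg, "frames must be named by channels")
  for (ch in object@channels) {
    a <- object@frames[[ch]]
    if (length(dim(a)) != 3 || dim(a)[3] != nt)
      msg <- c(msg, sprintf("channel %s must be h x w x %d", ch, nt))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EyeshineStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf(
    "EyeshineStack: %d frames of %d x %d px, channels %s\n",
    length(object@thetas), d[1], d[2],
    paste(object@channels, collapse = "/")
  ))
  cat(sprintf(
    "  theta: %g..%g deg, %d spots, spacing %g px\n",
    min(object@thetas), max(object@thetas),
    nrow(object@centers), object@spacing
  ))
  invisible(NULL)
})

#' HexROIGrid: circular regions of interest on a hexagonal grid
#'
#' A grid of equal-radius circular ROIs, one per lattice coordinate, used to
#' profile per-ommatidium intensity through an image stack.
#'
#' @slot centers data.frame with columns \code{q}, \code{r}, \code{x},
#'   \code{y}, \code{label}.
#' @slot radius numeric, ROI radius in pixels.
#' @slot imageDim integer length-2, (height, width) of the target images.
#' @seealso [buildRoiGrid()], [roiGridForStack()]
#' @export
setClass("HexROIGrid",
  representation(
    centers = "data.frame",
    radius = "numeric",
    imageDim = "integer"
  )
)

setValidity("HexROIGrid", function(object) {
  msg <- character()
  cc <- object@centers
  if (!all(c("q", "r", "x", "y") %in% names(cc)))
    msg <- c(msg, "centers must have columns q, r, x, y")
  if (object@radius <= 0) msg <- c(msg, "radius must be positive")
  if (nrow(cc) > 1) {
    d2 <- stats::dist(cc[, c("x", "y")])
    if (min(d2) < 2 * object@radius - 1e-9)
      msg <- c(msg, "ROI circles overlap: radius too large for spacing")
  }
  if (length(object@imageDim) == 2) {
    r <- object@radius
    bad <- cc$x < r | cc$y < r |
      cc$x > object@imageDim[2] + 1 - r | cc$y > object@imageDim[1] + 1 - r
    if (any(bad))
      msg <- c(msg, paste(
        "ROI centers out of image bounds at:",
        paste(sprintf("(%d,%d)", cc$q[bad], cc$r[bad]), collapse = " ")
      ))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HexROIGrid", function(object) {
  cat(sprintf(
    "HexROIGrid: %d circular ROIs of radius %g px on a %d x %d image\n",
    nrow(object@centers), object@radius,
    object@imageDim[1], object@imageDim[2]
  ))
  invisible(NULL)
})
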
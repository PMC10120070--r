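#' Build a hexagonal grid of circular ROIs
#'
#' Lays circular regions of interest on a pointy-top hexagonal lattice over
#' a reference image, one ROI per lattice coordinate. ROIs must be pairwise
#' non-overlapping (\code{radius < spacing / 2}) and fully inside the image.
#'
#' @param image_dim Integer length-2 (height, width) of the target images,
#'   or a matrix whose dimensions are used.
#' @param spacing Centre-to-centre lattice spacing, pixels.
#' @param radius ROI radius, pixels; must satisfy \code{radius < spacing/2}.
#' @param origin Pixel position (x, y) of lattice cell (0, 0).
#' @param n_rows,n_cols Lattice extent.
#' @return A [HexROIGrid-class].
#' @export
#' @examples
#' g <- buildRoiGrid(c(100, 100), spacing = 20, radius = 8,
#'                   origin = c(21, 21), n_rows = 3, n_cols = 3)
#' nrow(roiCenters(g))
buildRoiGrid <- function(image_dim, spacing, radius, origin,
                         n_rows, n_cols) {
  if (is.matrix(image_dim)) image_dim <- dim(image_dim)
  stopifnot(length(image_dim) == 2, n_rows >= 1, n_cols >= 1)
  if (radius >= spacing / 2)
    stop("radius must be < spacing / 2 (ROIs would overlap)")
  cc <- rhombicCoords(n_rows, n_cols)
  pos <- hexAxialToPixel(cc$q, cc$r, spacing, origin)
  pos$label <- hexColRowLabel(pos$q, pos$r)
  new("HexROIGrid",
    centers = pos, radius = as.numeric(radius),
    imageDim = as.integer(image_dim)
  )
}

#' ROI grid matching a rendered eyeshine stack
#'
#' Convenience constructor placing one ROI at every rendered spot centre of
#' an [EyeshineStack-class].
#'
#' @param stack An [EyeshineStack-class].
#' @param radius ROI radius in pixels (must be below half the spot spacing).
#' @return A [HexROIGrid-class].
#' @export
roiGridForStack <- function(stack, radius) {
  stopifnot(is(stack, "EyeshineStack"))
  if (radius >= stack@spacing / 2)
    stop("radius must be < spacing / 2 (ROIs would overlap)")
  pos <- stack@centers
  pos$label <- hexColRowLabel(pos$q, pos$r)
  d <- dim(stack@frames[[1]])
  new("HexROIGrid",
    centers = pos, radius = as.numeric(radius),
    imageDim = as.integer(d[1:2])
  )
}

#' Extract per-ommatidium intensity-versus-theta series
#'
#' For every ROI of the grid and every frame of the (registered) stack,
#' computes the arithmetic mean intensity over the pixels whose centres lie
#' within the ROI circle. Returns one series per lattice coordinate in long
#' format.
#'
#' @param stack An [EyeshineStack-class] (frames assumed registered).
#' @param grid A [HexROIGrid-class].
#' @param channel Channel to profile (must be present in the stack).
#' @return data.frame with columns \code{q}, \code{r}, \code{label},
#'   \code{channel}, \code{theta_deg}, \code{intensity}, ordered by
#'   coordinate then theta.
#' @export
#' @examples
#' f <- generateSigmaField(3, 3, seed = 1)
#' st <- renderEyeshineStack(f)
#' ser <- extractIntensitySeries(st, roiGridForStack(st, 8), "R")
#' head(ser)
extractIntensitySeries <- function(stack, grid, channel = "R") {
  stopifnot(is(stack, "EyeshineStack"), is(grid, "HexROIGrid"))
  a <- frameData(stack, channel)  # errors if channel absent
  h <- dim(a)[1]; w <- dim(a)[2]; nt <- dim(a)[3]
  if (any(grid@imageDim != c(h, w)))
    stop("grid was built for a different image size")
  cc <- roiCenters(grid)
  if (is.null(cc$label)) cc$label <- hexColRowLabel(cc$q, cc$r)
  flat <- matrix(a, nrow = h * w, ncol = nt)
  out <- vector("list", nrow(cc))
  for (i in seq_len(nrow(cc))) {
    xs <- max(1L, floor(cc$x[i] - grid@radius)):
      min(w, ceiling(cc$x[i] + grid@radius))
    ys <- max(1L, floor(cc$y[i] - grid@radius)):
      min(h, ceiling(cc$y[i] + grid@radius))
    gx <- expand.grid(y = ys, x = xs)
    keep <- (gx$x - cc$x[i])^2 + (gx$y - cc$y[i])^2 <= grid@radius^2
    idx <- (gx$x[keep] - 1L) * h + gx$y[keep]
    vals <- colMeans(flat[idx, , drop = FALSE])
    out[[i]] <- data.frame(
      q = cc$q[i], r = cc$r[i], label = cc$label[i], channel = channel,
      theta_deg = stack@thetas, intensity = vals
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
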
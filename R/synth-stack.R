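#' Optical parameters for synthetic eyeshine rendering
#'
#' Bundles the parameters of the phenomenological eyeshine intensity model
#' used by [renderEyeshineStack()]. At the centre of a rendered spot the
#' noiseless intensity is
#' \deqn{I(\theta) = background + baseline + amplitude \cdot
#'       \sin^2(2(\theta - \Sigma)),}
#' which has period 90 degrees in the roll angle theta, minima at
#' \eqn{\theta = \Sigma} (mod 90) and maxima halfway between successive
#' minima. Spots are compact-support Gaussian profiles (truncated at half
#' the lattice spacing) so that neighbouring spots never overlap and each
#' ROI therefore carries a pure DC + 4-theta-harmonic signal.
#'
#' @param baseline Minimum spot intensity above background, counts.
#' @param amplitude Modulation amplitude, counts.
#' @param spot_sigma Gaussian spot radius parameter, pixels.
#' @param noise_sd Additive Gaussian pixel noise sd, counts.
#' @param background Uniform image background, counts.
#' @param spacing Lattice spot spacing, pixels.
#' @param beam_half_angle Half-angle of the illumination cone, degrees (the
#'   default corresponds to a 21-degree cone; recorded as acquisition
#'   metadata, not used by the renderer).
#' @param saturation Detector saturation level, counts.
#' @param channel_gain Named numeric, per-channel scaling of the modulation
#'   amplitude. Depolarized eyeshine is predominantly red, so G and B are
#'   rendered at reduced amplitude by default.
#' @return Named list of optics parameters.
#' @export
opticsParams <- function(baseline = 40, amplitude = 120, spot_sigma = 3,
                         noise_sd = 0, background = 5, spacing = 20,
                         beam_half_angle = 10.5, saturation = 255,
                         channel_gain = c(R = 1, G = 0.4, B = 0.25)) {
  p <- list(
    baseline = baseline, amplitude = amplitude, spot_sigma = spot_sigma,
    noise_sd = noise_sd, background = background, spacing = spacing,
    beam_half_angle = beam_half_angle, saturation = saturation,
    channel_gain = channel_gain
  )
  num <- c("baseline", "amplitude", "spot_sigma", "noise_sd", "background",
    "spacing", "beam_half_angle", "saturation")
  for (nm in num)
    if (!is.numeric(p[[nm]]) || any(p[[nm]] < 0))
      stop("optics parameter '", nm, "' must be non-negative")
  if (p$background + p$baseline + p$amplitude + 4 * p$noise_sd > p$saturation)
    stop("baseline + amplitude + noise exceed saturation for this bit depth")
  p
}

#' Phenomenological depolarized-eyeshine intensity model
#'
#' Noiseless spot-centre intensity as a function of eye roll angle theta for
#' an ommatidium with principal axis \code{sigma}:
#' \code{baseline + amplitude * sin(2 * (theta - sigma))^2} (degrees).
#' The curve has period 90 degrees, minima at \code{theta = sigma} (mod 90)
#' and maxima at \code{theta = sigma + 45} (mod 90).
#'
#' @param theta Roll angles, degrees (vectorised).
#' @param sigma Principal axis, degrees.
#' @param baseline Intensity at the minimum.
#' @param amplitude Peak-to-trough modulation.
#' @return Numeric vector of intensities.
#' @export
#' @examples
#' eyeshineModel(c(27, 72, 117), sigma = 27, baseline = 40, amplitude = 120)
eyeshineModel <- function(theta, sigma, baseline = 40, amplitude = 120) {
  baseline + amplitude * sin(2 * (theta - sigma) * pi / 180)^2
}

#' Render a synthetic depolarized-eyeshine image stack
#'
#' Renders one image per roll angle theta of a patch of eyeshine spots, one
#' spot per measured ommatidium of \code{field}, following the intensity
#' model of [eyeshineModel()] plus optional Gaussian pixel noise. Cells with
#' \code{isMeasured(field) == FALSE} (outside the illumination cone) are not
#' rendered and their position shows only background.
#'
#' @param field A [SigmaField-class].
#' @param thetas Roll angles in degrees, strictly increasing. The default is
#'   the standard acquisition of 0 to 180 degrees in 5-degree steps
#'   (37 frames).
#' @param optics Parameter list from [opticsParams()].
#' @param seed Integer seed for the pixel noise (deterministic per seed).
#' @return An [EyeshineStack-class] with channels R, G and B.
#' @export
#' @examples
#' f <- generateSigmaField(3, 3, seed = 1)
#' st <- renderEyeshineStack(f, optics = opticsParams(noise_sd = 0))
#' length(rollAngles(st))
renderEyeshineStack <- function(field, thetas = seq(0, 180, by = 5),
                                optics = opticsParams(), seed = 1L) {
  stopifnot(is(field, "SigmaField"))
  if (nrow(latticeCoords(field)) == 0) stop("field is empty")
  if (length(thetas) == 0) stop("thetas is empty")
  if (is.unsorted(thetas, strictly = TRUE))
    stop("thetas must be strictly increasing")
  if (optics$spacing < 3 * optics$spot_sigma)
    warning("spot spacing < 3 * spot_sigma: spots may overlap")

  cc <- latticeCoords(field)
  margin <- optics$spacing
  pos <- hexAxialToPixel(cc$q, cc$r, optics$spacing,
    origin = c(margin + 1, margin + 1))
  w <- ceiling(max(pos$x) + margin)
  h <- ceiling(max(pos$y) + margin)
  nt <- length(thetas)
  cutoff <- optics$spacing / 2  # compact support: spots never overlap
  sig2 <- 2 * optics$spot_sigma^2

  ## Per-spot Gaussian footprint (pixel index + weight), computed once.
  meas <- isMeasured(field)
  foot <- vector("list", nrow(cc))
  for (i in which(meas)) {
    xs <- max(1L, floor(pos$x[i] - cutoff)):min(w, ceiling(pos$x[i] + cutoff))
    ys <- max(1L, floor(pos$y[i] - cutoff)):min(h, ceiling(pos$y[i] + cutoff))
    gx <- expand.grid(y = ys, x = xs)
    d2 <- (gx$x - pos$x[i])^2 + (gx$y - pos$y[i])^2
    keep <- d2 <= cutoff^2
    foot[[i]] <- list(
      idx = (gx$x[keep] - 1L) * h + gx$y[keep],  # linear index into h x w
      wgt = exp(-d2[keep] / sig2)
    )
  }

  frames <- withSeed(seed, {
    out <- list()
    for (ch in names(optics$channel_gain)) {
      gain <- optics$channel_gain[[ch]]
      a <- array(optics$background, dim = c(h, w, nt))
      for (k in seq_len(nt)) {
        frame <- a[, , k]
        for (i in which(meas)) {
          bright <- optics$baseline + gain * optics$amplitude *
            sin(2 * (thetas[k] - sigmaValues(field)[i]) * pi / 180)^2
          frame[foot[[i]]$idx] <- frame[foot[[i]]$idx] +
            bright * foot[[i]]$wgt
        }
        a[, , k] <- frame
      }
      if (max(a) > optics$saturation)
        stop("rendered intensity exceeds saturation")
      if (optics$noise_sd > 0) {
        a <- a + array(stats::rnorm(length(a), 0, optics$noise_sd), dim(a))
        a <- pmin(pmax(a, 0), optics$saturation)  # detector clipping
      }
      out[[ch]] <- a
    }
    out
  })

  new("EyeshineStack",
    thetas = as.numeric(thetas), frames = frames,
    channels = names(optics$channel_gain), spacing = optics$spacing,
    centers = pos
  )
}
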
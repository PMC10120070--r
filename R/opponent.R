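## Two-channel polarization-opponent model and second-order pairwise
## summation.

#' Photoreceptor response to partially polarized light
#'
#' Classical two-mechanism (Malus-law) response of a photoreceptor with
#' microvillar axis \code{axis} and polarization sensitivity \code{ps} to a
#' stimulus of intensity \code{intensity}, degree of polarization
#' \code{dop} and angle of polarization \code{aop}:
#' \deqn{R = I\left[(1-d)\frac{PS+1}{2} +
#'   d\left(PS \cos^2(\phi-\alpha) + \sin^2(\phi-\alpha)\right)\right].}
#' Unpolarized light (d = 0) drives the receptor at the average of its
#' parallel and perpendicular sensitivities.
#'
#' @param dop Degree of polarization in [0, 1].
#' @param aop Angle of polarization, degrees (vectorised).
#' @param axis Microvillar axis, degrees (mod 180).
#' @param ps Polarization sensitivity, >= 1 (default 10).
#' @param intensity Stimulus intensity, > 0.
#' @return Receptor response (same units as intensity), always positive.
#' @export
#' @examples
#' receptorResponse(dop = 1, aop = 0, axis = 0, ps = 10)  # I * PS
receptorResponse <- function(dop, aop, axis, ps = 10, intensity = 1) {
  if (any(dop < 0 | dop > 1)) stop("dop must lie in [0, 1]")
  if (any(ps < 1)) stop("polarization sensitivity must be >= 1")
  if (any(intensity <= 0)) stop("intensity must be > 0")
  rel <- (aop - axis) * pi / 180
  intensity * ((1 - dop) * (ps + 1) / 2 +
    dop * (ps * cos(rel)^2 + sin(rel)^2))
}

#' First-order polarization-opponent response
#'
#' Normalised difference between the two orthogonal receptor channels of an
#' ommatidium (microvillar axes \code{axis} and \code{axis + 90}):
#' \deqn{O = \frac{R_\parallel - R_\perp}{R_\parallel + R_\perp}
#'   = d\,\frac{PS-1}{PS+1}\,\cos 2(\phi-\alpha).}
#' The response is independent of stimulus intensity, bounded by
#' \code{dop * (ps - 1) / (ps + 1)} in magnitude, and vanishes when the
#' angle of polarization is at 45 degrees to the microvilli — the
#' polarization-blind angle of a single opponent unit.
#'
#' @inheritParams receptorResponse
#' @return Opponent response, dimensionless in [-1, 1] (vectorised over
#'   \code{aop}).
#' @export
#' @examples
#' opponentResponse(dop = 1, aop = 45, axis = 0, ps = 10)  # 0: blind
opponentResponse <- function(dop, aop, axis, ps = 10, intensity = 1) {
  rp <- receptorResponse(dop, aop, axis, ps, intensity)
  rq <- receptorResponse(dop, aop, axis + 90, ps, intensity)
  (rp - rq) / (rp + rq)
}

#' Polarization state-space locus of an ommatidial pair
#'
#' Plots (numerically) the opponent response of one ommatidium against that
#' of its neighbour while the stimulus angle of polarization sweeps its full
#' range. Aligned pairs collapse onto the identity line; as the axial
#' difference between the two axes grows, the locus opens and samples an
#' increasing extent of the polarization state space.
#'
#' @param axis1,axis2 Principal axes of the two ommatidia, degrees.
#' @param ps Polarization sensitivity (default 10).
#' @param dop Degree of polarization (default 1).
#' @param phi Angle-of-polarization grid, degrees, spanning [-90, 90).
#' @return data.frame with columns \code{phi}, \code{o1}, \code{o2};
#'   attributes \code{delta_sigma}, \code{dop}, \code{ps}.
#' @export
stateSpaceLocus <- function(axis1, axis2, ps = 10, dop = 1,
                            phi = seq(-90, 89.5, by = 0.5)) {
  if (min(phi) > -90 || max(phi) < 89) ## must span the axial range
    stop("phi grid must span [-90, 90)")
  out <- data.frame(
    phi = phi,
    o1 = opponentResponse(dop, phi, axis1, ps),
    o2 = opponentResponse(dop, phi, axis2, ps)
  )
  attr(out, "delta_sigma") <- deltaSigma(axis1, axis2)
  attr(out, "dop") <- dop
  attr(out, "ps") <- ps
  out
}

#' Second-order summed response of an ommatidial pair
#'
#' Response of a second-order neuron summing the rectified first-order
#' opponent outputs of two adjacent ommatidia:
#' \code{S = |O(aop; axis1)| + |O(aop; axis2)|}. A signed sum of two cosine
#' opponents is itself a cosine and stays polarization blind at some angle;
#' rectification is the minimal nonlinearity that makes the pair's response
#' robust (never blind) once the axes differ enough. Set
#' \code{rectified = FALSE} for the signed-sum variant, for comparison.
#'
#' @inheritParams receptorResponse
#' @param axis1,axis2 Principal axes of the two ommatidia, degrees.
#' @param rectified Sum absolute opponent outputs (default) or signed ones.
#' @return Summed response (vectorised over \code{aop}); non-negative and
#'   90-degree periodic in \code{aop} when rectified.
#' @export
secondOrderResponse <- function(dop, aop, axis1, axis2, ps = 10,
                                rectified = TRUE) {
  o1 <- opponentResponse(dop, aop, axis1, ps)
  o2 <- opponentResponse(dop, aop, axis2, ps)
  if (rectified) abs(o1) + abs(o2) else o1 + o2
}

#' Robustness of a second-order polarization detector
#'
#' Worst-case (minimum over all angles of polarization) response of the
#' rectified second-order sum of an ommatidial pair. Aligned pairs are
#' blind at some angle (robustness 0); the robustness grows with the axial
#' difference of the pair, and pairs misaligned by 20 degrees or more
#' retain a substantial response at every angle of polarization.
#'
#' @param axis1,axis2 Principal axes of the two ommatidia, degrees.
#' @param ps Polarization sensitivity (default 10).
#' @param dop Degree of polarization (default 1).
#' @param phi_step Grid resolution of the exhaustive scan, degrees
#'   (default 0.1; must be <= 0.1).
#' @return Minimum summed response over the angle-of-polarization grid.
#' @export
#' @examples
#' polRobustness(0, 0)    # 0: an aligned pair stays blind
#' polRobustness(0, 45)   # (ps-1)/(ps+1) at the orthogonal extreme
polRobustness <- function(axis1, axis2, ps = 10, dop = 1, phi_step = 0.1) {
  if (phi_step > 0.1 + 1e-12) stop("phi_step must be <= 0.1 degrees")
  phi <- seq(-90, 90, by = phi_step)
  min(secondOrderResponse(dop, phi, axis1, axis2, ps))
}
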
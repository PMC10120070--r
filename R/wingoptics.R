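## Wing polarization and colour photometry: degree of polarization from
## image pairs, angular-contrast sweeps with polynomial trends, spectral
## peaks, quantum catches and tetrahedral colour-space summaries.

#' Degree of polarization from channel totals
#'
#' \code{DoP = |I_H - I_V| / (I_H + I_V)}, where \code{I_H} and \code{I_V}
#' are the total intensities of the horizontal-polarized (perpendicular to
#' the plane of incidence) and vertical-polarized (parallel) images.
#'
#' @param i_h_total,i_v_total Non-negative channel totals.
#' @return DoP in [0, 1].
#' @export
#' @examples
#' computeDop(2, 1)  # 1/3
computeDop <- function(i_h_total, i_v_total) {
  if (any(i_h_total < 0) || any(i_v_total < 0))
    stop("intensities must be non-negative")
  tot <- i_h_total + i_v_total
  if (any(tot == 0)) stop("both channel totals are zero")
  abs(i_h_total - i_v_total) / tot
}

#' Degree of polarization of a polarization image pair
#'
#' Sums each image over the (optional) wing mask and computes the DoP of
#' the totals, together with the dominant polarization channel.
#'
#' @param i_h,i_v Numeric matrices of equal shape: horizontal- and
#'   vertical-polarized intensity images.
#' @param mask Optional logical matrix selecting wing pixels.
#' @return List with \code{dop}, \code{dominant} (\code{"H"} or \code{"V"}),
#'   \code{i_h_total}, \code{i_v_total}.
#' @export
imagePairDop <- function(i_h, i_v, mask = NULL) {
  if (!all(dim(i_h) == dim(i_v))) stop("images must have the same shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(i_h), ncol(i_h))
  if (!all(dim(mask) == dim(i_h))) stop("mask must match image shape")
  if (!any(mask)) stop("empty mask: no wing pixels selected")
  th <- sum(i_h[mask]); tv <- sum(i_v[mask])
  list(
    dop = computeDop(th, tv),
    dominant = if (th >= tv) "H" else "V",
    i_h_total = th, i_v_total = tv
  )
}

#' DoP sweep over viewing geometries
#'
#' Computes the DoP of one polarization image pair per viewing geometry and
#' tabulates it against the angular contrast, defined as the sum of the
#' incident angle theta and the detection angle phi.
#'
#' @param pairs List of entries, each a list with images \code{i_h},
#'   \code{i_v}, optional \code{mask}, angles \code{theta_inc} and
#'   \code{phi_det} (degrees), and optionally a precomputed
#'   \code{angular_contrast} that is checked against
#'   \code{theta_inc + phi_det}.
#' @return data.frame with columns \code{theta_inc}, \code{phi_det},
#'   \code{angular_contrast}, \code{dop}, \code{dominant}.
#' @export
dopSweep <- function(pairs) {
  if (!length(pairs)) stop("need at least one geometry")
  rows <- lapply(pairs, function(p) {
    ac <- p$theta_inc + p$phi_det
    if (!is.null(p$angular_contrast) &&
        abs(p$angular_contrast - ac) > 1e-9)
      stop(sprintf(
        "inconsistent angular contrast: %g != theta (%g) + phi (%g)",
        p$angular_contrast, p$theta_inc, p$phi_det
      ))
    d <- imagePairDop(p$i_h, p$i_v, p$mask)
    data.frame(
      theta_inc = p$theta_inc, phi_det = p$phi_det,
      angular_contrast = ac, dop = d$dop, dominant = d$dominant
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Polynomial trend of DoP versus angular contrast
#'
#' Ordinary least squares fit of DoP on an orthogonal polynomial of the
#' angular contrast (order 2 or 3), as used to summarise the non-linear
#' dependence of wing DoP on viewing obliquity.
#'
#' @param sweep data.frame with columns \code{angular_contrast} and
#'   \code{dop} (e.g. from [dopSweep()]).
#' @param order Polynomial order, 2 or 3.
#' @return List with \code{order}, \code{coefficients} (orthogonal basis),
#'   \code{residual_sd}, \code{r_squared} and the fitted \code{model}.
#' @export
fitDopTrend <- function(sweep, order = 2) {
  if (!order %in% c(2, 3)) stop("order must be 2 or 3")
  if (nrow(sweep) < order + 2)
    stop("need at least order + 2 rows to fit the trend")
  if (length(unique(sweep$angular_contrast)) <= order)
    stop("rank-deficient design: too few distinct contrast values")
  fit <- stats::lm(dop ~ poly(angular_contrast, degree = order),
    data = sweep)
  ## summary.lm warns on exact fits; residual_sd = 0 is a valid outcome here
  sm <- suppressWarnings(summary(fit))
  list(
    order = order,
    coefficients = stats::coef(fit),
    residual_sd = sm$sigma,
    r_squared = sm$r.squared,
    model = fit
  )
}

#' Wavelength of maximum reflectance
#'
#' Global maximum of a reflectance spectrum on its sampled grid. Ties are
#' resolved towards the smallest wavelength and flagged; a peak on the grid
#' boundary is flagged as such.
#'
#' @param spec data.frame with columns \code{wavelength_nm},
#'   \code{reflectance} (strictly increasing wavelengths).
#' @return List with \code{peak_nm}, \code{reflectance} (peak height),
#'   \code{tie} and \code{boundary} flags.
#' @export
#' @examples
#' spectralPeak(forewingTemplate("male"))$peak_nm  # 545
spectralPeak <- function(spec) {
  stopifnot(all(c("wavelength_nm", "reflectance") %in% names(spec)))
  if (is.unsorted(spec$wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  r <- spec$reflectance
  if (diff(range(r)) == 0) stop("constant spectrum has no peak")
  top <- which(r == max(r))
  i <- top[1]
  list(
    peak_nm = spec$wavelength_nm[i],
    reflectance = r[i],
    tie = length(top) > 1,
    boundary = i == 1 || i == length(r)
  )
}

#' Quantum catches of the four photoreceptor classes
#'
#' Photoreceptor quantum catches of a reflectance spectrum under an ideal
#' (flat) illuminant and background:
#' \eqn{Q_i = \sum_\lambda R(\lambda) S_i(\lambda) \Delta\lambda} for the
#' u, s, m, l receptor classes. Sensitivities are linearly interpolated
#' onto the reflectance grid (zero outside their support) before
#' integration, and spectra outside 350-700 nm are truncated.
#'
#' @param spec data.frame with columns \code{wavelength_nm},
#'   \code{reflectance}.
#' @param sensitivities data.frame with columns \code{wavelength_nm},
#'   \code{u}, \code{s}, \code{m}, \code{l} (e.g. from
#'   [generateSensitivityTemplates()]).
#' @param range_nm Truncation range, nm (default 350-700).
#' @return List of class fields: \code{catch} (named u/s/m/l absolute
#'   catches), \code{relative} (normalised to sum 1) and \code{xyz}
#'   (Cartesian tetrahedral coordinates, see [tetraCoordinates()]).
#' @export
quantumCatches <- function(spec, sensitivities, range_nm = c(350, 700)) {
  stopifnot(all(c("wavelength_nm", "reflectance") %in% names(spec)))
  cls <- c("u", "s", "m", "l")
  stopifnot(all(c("wavelength_nm", cls) %in% names(sensitivities)))
  keep <- spec$wavelength_nm >= range_nm[1] &
    spec$wavelength_nm <= range_nm[2]
  wl <- spec$wavelength_nm[keep]
  refl <- spec$reflectance[keep]
  if (length(wl) < 2) stop("too few wavelengths after truncation")
  dl <- stats::median(diff(wl))
  catch <- vapply(cls, function(k) {
    s <- stats::approx(sensitivities$wavelength_nm, sensitivities[[k]],
      xout = wl, yleft = 0, yright = 0)$y
    sum(refl * s) * dl
  }, numeric(1))
  if (sum(catch) <= 0) stop("all quantum catches are zero")
  rel <- catch / sum(catch)
  list(catch = catch, relative = rel, xyz = tetraCoordinates(rel))
}

#' Cartesian coordinates in tetrahedral colour space
#'
#' Maps relative quantum catches (u, s, m, l summing to 1) to Cartesian
#' coordinates of a regular tetrahedron with the achromatic point at the
#' origin and unit centre-to-vertex distance 0.75:
#' \deqn{x = \sqrt{3/2}\,\frac{1 - 2s - m - u}{2}, \quad
#'       y = \frac{-1 + 3m + u}{2\sqrt{2}}, \quad
#'       z = u - \tfrac14.}
#' The u vertex sits at (0, 0, 0.75) with s, m and l in the plane below.
#' Equal catches map to the origin; every pure catch maps to a vertex at
#' distance 0.75 from the origin.
#'
#' @param relative Named or positional numeric length-4 of relative catches
#'   (order u, s, m, l), summing to 1.
#' @return Named numeric (x, y, z).
#' @export
#' @examples
#' tetraCoordinates(c(0.25, 0.25, 0.25, 0.25))  # achromatic origin
tetraCoordinates <- function(relative) {
  stopifnot(length(relative) == 4)
  if (any(relative < 0) || abs(sum(relative) - 1) > 1e-8)
    stop("relative catches must be non-negative and sum to 1")
  u <- relative[[1]]; s <- relative[[2]]; m <- relative[[3]]
  c(
    x = sqrt(3 / 2) * (1 - 2 * s - m - u) / 2,
    y = (-1 + 3 * m + u) / (2 * sqrt(2)),
    z = u - 1 / 4
  )
}

#' Unweighted Euclidean colour distance
#'
#' Euclidean distance between two colours in Cartesian tetrahedral colour
#' space. Accepts either quantum-catch results (from [quantumCatches()]) or
#' bare xyz coordinate vectors. Perceptually more similar colours have
#' smaller distances; no receptor-noise weighting is applied.
#'
#' @param a,b Quantum-catch lists with an \code{xyz} field, or numeric
#'   length-3 xyz vectors.
#' @return Non-negative distance.
#' @export
colorDistance <- function(a, b) {
  xyz <- function(v) if (is.list(v)) v$xyz else v
  pa <- xyz(a); pb <- xyz(b)
  stopifnot(length(pa) == 3, length(pb) == 3)
  sqrt(sum((pa - pb)^2))
}
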
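## On-disk formats: CSV for fields, series, spectra and counts; multi-page
## TIFF (or numbered PNG) plus a JSON sidecar for eyeshine stacks.

#' Write and read a SigmaField as CSV
#'
#' CSV columns: \code{patch_id}, \code{q}, \code{r}, \code{col_label},
#' \code{row_label}, \code{sigma_deg}, \code{measured}.
#'
#' @param field A [SigmaField-class].
#' @param path File path.
#' @param patch_id Patch identifier written with every row (defaults to the
#'   field's \code{patch_id} metadata, or \code{"patch1"}).
#' @return \code{writeSigmaField} returns \code{path} invisibly;
#'   \code{readSigmaField} returns a [SigmaField-class].
#' @export
writeSigmaField <- function(field, path, patch_id = NULL) {
  stopifnot(is(field, "SigmaField"))
  if (is.null(patch_id))
    patch_id <- patchMetadata(field)$patch_id %||% "patch1"
  cc <- latticeCoords(field)
  utils::write.csv(data.frame(
    patch_id = patch_id, q = cc$q, r = cc$r,
    col_label = sprintf("C%d", cc$q + 1L),
    row_label = sprintf("R%d", cc$r + 1L),
    sigma_deg = sigmaValues(field),
    measured = isMeasured(field)
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSigmaField
#' @export
readSigmaField <- function(path) {
  d <- utils::read.csv(path)
  SigmaField(d$q, d$r, d$sigma_deg, measured = d$measured,
    metadata = list(patch_id = d$patch_id[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read intensity series as long-format CSV
#'
#' CSV columns: \code{patch_id}, \code{q}, \code{r}, \code{channel},
#' \code{theta_deg}, \code{intensity}.
#'
#' @param series data.frame from [extractIntensitySeries()].
#' @param path File path.
#' @param patch_id Patch identifier.
#' @return \code{writeIntensitySeries} returns \code{path} invisibly;
#'   \code{readIntensitySeries} returns the series data.frame.
#' @export
writeIntensitySeries <- function(series, path, patch_id = "patch1") {
  utils::write.csv(data.frame(
    patch_id = patch_id, q = series$q, r = series$r,
    channel = series$channel, theta_deg = series$theta_deg,
    intensity = series$intensity
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntensitySeries
#' @export
readIntensitySeries <- function(path) {
  utils::read.csv(path)
}

#' Write and read a reflectance spectrum as two-column CSV
#'
#' @param spec data.frame with columns \code{wavelength_nm},
#'   \code{reflectance}.
#' @param path File path.
#' @return \code{writeSpectrum} returns \code{path} invisibly;
#'   \code{readSpectrum} returns the spectrum data.frame.
#' @export
writeSpectrum <- function(spec, path) {
  utils::write.csv(spec[, c("wavelength_nm", "reflectance")], path,
    row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  utils::read.csv(path)
}

#' Write and read an eyeshine stack (TIFF or PNG series + JSON sidecar)
#'
#' Frames are written per channel as 16-bit multi-page TIFF (ascending
#' theta) or as an 8-bit numbered PNG series, scaled by the stack's intensity
#' ceiling; roll angles, spacing, spot centres and the scale factor go to a
#' JSON sidecar (\code{<prefix>.json}). Reading restores the stack up to
#' 16-bit quantisation of the intensities.
#'
#' @param stack An [EyeshineStack-class].
#' @param prefix Path prefix; files are \code{<prefix>_<channel>.tif} (or
#'   \code{<prefix>_<channel>_<frame>.png}) and \code{<prefix>.json}.
#' @param format \code{"tiff"} or \code{"png"}.
#' @param scale Intensity ceiling used for normalisation (defaults to the
#'   maximum across frames).
#' @return \code{writeEyeshineStack} returns \code{prefix} invisibly;
#'   \code{readEyeshineStack} returns an [EyeshineStack-class].
#' @export
writeEyeshineStack <- function(stack, prefix, format = c("tiff", "png"),
                               scale = NULL) {
  stopifnot(is(stack, "EyeshineStack"))
  format <- match.arg(format)
  if (is.null(scale))
    scale <- max(vapply(stack@frames, max, numeric(1)))
  if (scale <= 0) scale <- 1
  files <- list()
  for (ch in stack@channels) {
    a <- pmin(pmax(stack@frames[[ch]] / scale, 0), 1)
    nt <- dim(a)[3]
    if (format == "tiff") {
      f <- paste0(prefix, "_", ch, ".tif")
      tiff::writeTIFF(lapply(seq_len(nt), function(k) a[, , k]), f,
        bits.per.sample = 16)
      files[[ch]] <- basename(f)
    } else {
      fs <- sprintf("%s_%s_%03d.png", prefix, ch, seq_len(nt))
      for (k in seq_len(nt)) png::writePNG(a[, , k], fs[k])
      files[[ch]] <- basename(fs)
    }
  }
  sidecar <- list(
    thetas = stack@thetas, channels = stack@channels, format = format,
    scale = scale, spacing = stack@spacing,
    centers = stack@centers, files = files
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeEyeshineStack
#' @export
readEyeshineStack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
    simplifyVector = TRUE)
  dirn <- dirname(prefix)
  frames <- list()
  for (ch in meta$channels) {
    if (meta$format == "tiff") {
      pages <- tiff::readTIFF(file.path(dirn, meta$files[[ch]]),
        all = TRUE)
    } else {
      pages <- lapply(file.path(dirn, meta$files[[ch]]), png::readPNG)
    }
    a <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
    for (k in seq_along(pages)) a[, , k] <- pages[[k]]
    frames[[ch]] <- a * meta$scale
  }
  new("EyeshineStack",
    thetas = as.numeric(meta$thetas), frames = frames,
    channels = as.character(meta$channels),
    spacing = as.numeric(meta$spacing),
    centers = as.data.frame(meta$centers)
  )
}

#' Write patch metrics (plus metadata) as JSON
#'
#' @param metrics Metrics list from [patchMetrics()].
#' @param path File path.
#' @param metadata Optional named list (e.g. \code{patch_id}, \code{sex},
#'   \code{elevation_deg}, \code{azimuth_deg}) merged into the record.
#' @return \code{path}, invisibly.
#' @export
writeMetricsJSON <- function(metrics, path, metadata = list()) {
  jsonlite::write_json(c(metadata, metrics), path,
    auto_unbox = TRUE, digits = 10)
  invisible(path)
}
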
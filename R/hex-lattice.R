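## Axial ("pointy-top") hexagonal lattice geometry shared by the generator,
## the ROI grid and the neighbour analysis.

#' Axial neighbour offsets of a hexagonal lattice
#'
#' The six axial-coordinate offsets \code{(dq, dr)} of the nearest neighbours
#' of a cell in a pointy-top hexagonal lattice.
#'
#' @return A two-column integer matrix with columns \code{dq} and \code{dr}.
#' @export
#' @examples
#' hexAxialOffsets()
hexAxialOffsets <- function() {
  m <- rbind(
    c(1L, 0L), c(-1L, 0L),
    c(0L, 1L), c(0L, -1L),
    c(1L, -1L), c(-1L, 1L)
  )
  colnames(m) <- c("dq", "dr")
  m
}

#' Pixel position of an axial lattice coordinate
#'
#' Maps axial coordinates \code{(q, r)} of a pointy-top hexagonal lattice to
#' pixel positions so that the six nearest neighbours of every cell are
#' exactly \code{spacing} pixels away.
#'
#' @param q,r Integer axial coordinates (vectorised).
#' @param spacing Centre-to-centre distance between adjacent cells, pixels.
#' @param origin Numeric length-2, pixel position \code{(x, y)} of cell (0,0).
#' @return A data.frame with columns \code{q}, \code{r}, \code{x}, \code{y}.
#' @export
hexAxialToPixel <- function(q, r, spacing, origin = c(0, 0)) {
  stopifnot(length(q) == length(r), spacing > 0, length(origin) == 2)
  data.frame(
    q = as.integer(q), r = as.integer(r),
    x = origin[1] + spacing * (q + r / 2),
    y = origin[2] + spacing * (sqrt(3) / 2) * r
  )
}

#' Column/row label of a lattice coordinate
#'
#' Human-readable labels of the form \code{"C<col>R<row>"} used to annotate
#' ommatidia, with 1-based column \code{q + 1} and row \code{r + 1}.
#'
#' @param q,r Integer axial coordinates (vectorised).
#' @return Character vector of labels.
#' @export
hexColRowLabel <- function(q, r) {
  sprintf("C%dR%d", as.integer(q) + 1L, as.integer(r) + 1L)
}

## All cells of a rhombic patch, sweep (row-major) order.
rhombicCoords <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  expand.grid(q = 0:(cols - 1L), r = 0:(rows - 1L), KEEP.OUT.ATTRS = FALSE)
}
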
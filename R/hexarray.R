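## Neighbour analysis on the hexagonal ommatidial lattice: adjacent-pair
## Delta-Sigma distributions, edge-detector (ED) chains, robust
## polarization-detector (PD) pairs, and patch-level metrics.

## Lookup from (q, r) to row index of a field; NA when absent/unmeasured.
fieldIndex <- function(field) {
  cc <- latticeCoords(field)
  idx <- seq_len(nrow(cc))
  names(idx) <- paste(cc$q, cc$r, sep = ",")
  idx
}

#' Measured axial neighbours of a lattice cell
#'
#' The subset of the six axial neighbour coordinates of \code{(q, r)} that
#' are present in the field and measured.
#'
#' @param field A [SigmaField-class].
#' @param q,r Axial coordinates of the focal cell.
#' @return data.frame of neighbour coordinates (columns \code{q}, \code{r}).
#' @export
measuredNeighbors <- function(field, q, r) {
  offs <- hexAxialOffsets()
  nb <- data.frame(q = q + offs[, "dq"], r = r + offs[, "dr"])
  idx <- fieldIndex(field)
  pos <- idx[paste(nb$q, nb$r, sep = ",")]
  keep <- !is.na(pos) & isMeasured(field)[pos]
  nb[keep, , drop = FALSE]
}

#' Interior ommatidia of a measured patch
#'
#' An ommatidium is interior when it is measured and all six of its axial
#' neighbours are measured. Patch-level metrics are computed over the
#' interior set so that every counted ommatidium has a complete
#' neighbourhood.
#'
#' @param field A [SigmaField-class].
#' @return data.frame of interior coordinates (columns \code{q}, \code{r}).
#' @export
#' @examples
#' f <- generateSigmaField(5, 5, seed = 1)
#' nrow(interiorOmmatidia(f))  # 3 x 3 core of a 5 x 5 rhombus
interiorOmmatidia <- function(field) {
  cc <- latticeCoords(field)
  if (nrow(cc) == 0) stop("field is empty")
  meas <- isMeasured(field)
  idx <- fieldIndex(field)
  offs <- hexAxialOffsets()
  ok <- vapply(seq_len(nrow(cc)), function(i) {
    if (!meas[i]) return(FALSE)
    pos <- idx[paste(cc$q[i] + offs[, "dq"], cc$r[i] + offs[, "dr"],
      sep = ",")]
    !anyNA(pos) && all(meas[pos])
  }, logical(1))
  cc[ok, , drop = FALSE]
}

#' Adjacent measured pairs and their axial differences
#'
#' Enumerates every unordered pair of adjacent measured ommatidia once,
#' with its axial difference Delta-Sigma and the robust polarization
#' detector (PD) flag \code{is_pd = (delta_sigma_deg >= pd_threshold)}.
#'
#' @param field A [SigmaField-class] with at least two measured cells.
#' @param restrict_interior If \code{TRUE}, keep only pairs in which at
#'   least one member is interior.
#' @param pd_threshold Minimum Delta-Sigma (degrees) for a robust PD pair
#'   (default 20).
#' @return data.frame with columns \code{a_q}, \code{a_r}, \code{b_q},
#'   \code{b_r}, \code{delta_sigma_deg}, \code{is_pd}.
#' @export
#' @examples
#' f <- SigmaField(q = c(0, 1), r = c(0, 0), sigma = c(10, 40))
#' adjacentPairs(f)
adjacentPairs <- function(field, restrict_interior = FALSE,
                          pd_threshold = 20) {
  cc <- latticeCoords(field)
  meas <- isMeasured(field)
  if (sum(meas) < 2) stop("need at least two measured ommatidia")
  idx <- fieldIndex(field)
  sig <- sigmaValues(field)
  dirs <- rbind(c(1L, 0L), c(0L, 1L), c(1L, -1L))  # canonical directions
  out <- list()
  for (k in seq_len(nrow(dirs))) {
    bq <- cc$q + dirs[k, 1]; br <- cc$r + dirs[k, 2]
    pos <- idx[paste(bq, br, sep = ",")]
    keep <- meas & !is.na(pos) & meas[ifelse(is.na(pos), 1L, pos)]
    if (!any(keep)) next
    out[[k]] <- data.frame(
      a_q = cc$q[keep], a_r = cc$r[keep],
      b_q = bq[keep], b_r = br[keep],
      delta_sigma_deg = deltaSigma(sig[keep], sig[pos[keep]])
    )
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs) || nrow(pairs) == 0)
    return(data.frame(
      a_q = integer(), a_r = integer(), b_q = integer(), b_r = integer(),
      delta_sigma_deg = numeric(), is_pd = logical()
    ))
  if (restrict_interior) {
    int <- interiorOmmatidia(field)
    ik <- paste(int$q, int$r, sep = ",")
    keep <- paste(pairs$a_q, pairs$a_r, sep = ",") %in% ik |
      paste(pairs$b_q, pairs$b_r, sep = ",") %in% ik
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs$is_pd <- pairs$delta_sigma_deg >= pd_threshold
  rownames(pairs) <- NULL
  pairs
}

## Maximal windows of a numeric run whose members lie pairwise within
## 2 * ed_tol on the axial circle. Returns list of index ranges.
maximalAlignedWindows <- function(sig, ed_tol, min_len) {
  L <- length(sig)
  if (L < min_len) return(list())
  satisfies <- function(i, j) {
    v <- sig[i:j]
    if (length(v) < 2) return(TRUE)
    max(deltaSigma(rep(v, each = length(v)), rep(v, length(v)))) <=
      2 * ed_tol + 1e-9
  }
  res <- list()
  prev_end <- 0L
  for (i in seq_len(L)) {
    j <- i
    while (j < L && satisfies(i, j + 1L)) j <- j + 1L
    if (j - i + 1L >= min_len && j > prev_end) {
      res[[length(res) + 1L]] <- c(i, j)
      prev_end <- j
    }
  }
  res
}

#' Find edge-detector chains
#'
#' Edge detectors are linear groups of three or more ommatidia along one of
#' the three lattice axes whose principal axes deviate from parallel by no
#' more than \code{ed_tol} degrees. The alignment band is operationalised
#' as a maximum pairwise axial difference of \code{2 * ed_tol} within the
#' run (a band of plus or minus \code{ed_tol} about the run midpoint).
#' Every maximal contiguous run satisfying the condition with length at
#' least \code{min_len} is reported; maximality means no extension along
#' the axis keeps the condition.
#'
#' @param field A [SigmaField-class].
#' @param ed_tol Half-width of the alignment band, degrees (default 5).
#' @param min_len Minimum chain length (default 3).
#' @return data.frame with one row per chain member: \code{chain_id},
#'   \code{axis} (one of \code{"row"}, \code{"diag1"}, \code{"diag2"}),
#'   \code{q},
#'   \code{r}, \code{position} (order along the axis), \code{n} (chain
#'   length) and \code{spread_deg} (max pairwise axial difference).
#' @export
#' @examples
#' f <- SigmaField(q = 0:3, r = rep(0, 4), sigma = rep(30, 4))
#' findEdChains(f)
findEdChains <- function(field, ed_tol = 5, min_len = 3) {
  cc <- latticeCoords(field)
  if (nrow(cc) == 0) stop("field is empty")
  meas <- isMeasured(field)
  sig <- sigmaValues(field)
  ## the three lattice axes: direction, invariant line key, position along
  axes <- list(
    list(name = "row",   pos = cc$q, line = cc$r),        # dir (1, 0)
    list(name = "diag1", pos = cc$r, line = cc$q),        # dir (0, 1)
    list(name = "diag2", pos = cc$q, line = cc$q + cc$r)  # dir (1,-1)
  )
  out <- list()
  cid <- 0L
  for (ax in axes) {
    for (ln in unique(ax$line[meas])) {
      sel <- which(ax$line == ln & meas)
      sel <- sel[order(ax$pos[sel])]
      if (length(sel) < min_len) next
      ## split at positional gaps (missing/unmeasured cells break the run)
      pos <- ax$pos[sel]
      grp <- cumsum(c(1L, diff(pos) != 1L))
      for (g in unique(grp)) {
        run <- sel[grp == g]
        wins <- maximalAlignedWindows(sig[run], ed_tol, min_len)
        for (wdw in wins) {
          mem <- run[wdw[1]:wdw[2]]
          cid <- cid + 1L
          v <- sig[mem]
          spread <- max(deltaSigma(rep(v, each = length(v)),
            rep(v, length(v))))
          out[[length(out) + 1L]] <- data.frame(
            chain_id = cid, axis = ax$name,
            q = cc$q[mem], r = cc$r[mem],
            position = seq_along(mem), n = length(mem),
            spread_deg = spread
          )
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(
      chain_id = integer(), axis = character(), q = integer(),
      r = integer(), position = integer(), n = integer(),
      spread_deg = numeric()
    ))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Patch-level edge-detection and polarization-detection metrics
#'
#' Computes, over the interior ommatidia of a patch (those with six
#' measured neighbours):
#' \itemize{
#'   \item \code{pct_ed}: percentage belonging to at least one
#'     edge-detector chain (chains may extend to non-interior members);
#'   \item \code{pct_pd}: percentage belonging to at least one adjacent
#'     pair with Delta-Sigma of \code{pd_threshold} or more (the partner
#'     may be non-interior);
#'   \item \code{pct_ed_only}, \code{pct_pd_only}: percentages exclusively
#'     in one class;
#'   \item \code{delta_sigma_summary}: fractions of adjacent pairs (with at
#'     least one interior member) that are exactly aligned (below
#'     \code{exact_tol}), within 5 degrees, at 15 degrees or more, and at
#'     20 degrees or more.
#' }
#'
#' @param field A [SigmaField-class] with at least one interior ommatidium.
#' @param ed_tol,min_len Edge-detector chain parameters, see
#'   [findEdChains()].
#' @param pd_threshold Robust PD threshold in degrees (default 20).
#' @param exact_tol Delta-Sigma below which a pair counts as exactly
#'   aligned (default 0.5 degrees; exact zero is measure-zero on estimated
#'   data).
#' @return List with \code{n_interior}, \code{n_pairs_interior},
#'   \code{pct_ed}, \code{pct_pd}, \code{pct_ed_only}, \code{pct_pd_only}
#'   and \code{delta_sigma_summary} (list \code{exact}, \code{within5},
#'   \code{ge15}, \code{ge20}), plus the parameters used.
#' @export
patchMetrics <- function(field, ed_tol = 5, min_len = 3, pd_threshold = 20,
                         exact_tol = 0.5) {
  interior <- interiorOmmatidia(field)
  if (nrow(interior) == 0)
    stop("no interior ommatidia: use a larger patch")
  ikey <- paste(interior$q, interior$r, sep = ",")

  chains <- findEdChains(field, ed_tol = ed_tol, min_len = min_len)
  ed_members <- unique(paste(chains$q, chains$r, sep = ","))

  pairs <- adjacentPairs(field, pd_threshold = pd_threshold)
  pd_pairs <- pairs[pairs$is_pd, , drop = FALSE]
  pd_members <- unique(c(
    paste(pd_pairs$a_q, pd_pairs$a_r, sep = ","),
    paste(pd_pairs$b_q, pd_pairs$b_r, sep = ",")
  ))

  is_ed <- ikey %in% ed_members
  is_pd <- ikey %in% pd_members
  n <- length(ikey)

  ip <- paste(pairs$a_q, pairs$a_r, sep = ",") %in% ikey |
    paste(pairs$b_q, pairs$b_r, sep = ",") %in% ikey
  dpi <- pairs$delta_sigma_deg[ip]

  list(
    n_interior = n,
    n_pairs_interior = length(dpi),
    pct_ed = 100 * mean(is_ed),
    pct_pd = 100 * mean(is_pd),
    pct_ed_only = 100 * mean(is_ed & !is_pd),
    pct_pd_only = 100 * mean(is_pd & !is_ed),
    delta_sigma_summary = list(
      exact = mean(dpi < exact_tol),
      within5 = mean(dpi <= 5),
      ge15 = mean(dpi >= 15),
      ge20 = mean(dpi >= 20)
    ),
    params = list(
      ed_tol = ed_tol, min_len = min_len,
      pd_threshold = pd_threshold, exact_tol = exact_tol
    )
  )
}
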
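## Shared fixtures and independent oracles. Oracles deliberately avoid the
## package's own code paths.

## Noiseless model series for a single ommatidium.
makeSeries <- function(sigma, thetas = seq(0, 180, by = 5),
                       baseline = 40, amplitude = 120) {
  eyeshineModel(thetas, sigma, baseline, amplitude)
}

## Brute-force axial difference: minimum over explicit 90-deg shifts.
bruteDelta <- function(a, b) {
  min(abs(a - b + 90 * (-3:3)))
}

## Brute-force interior set via Euclidean nearest-neighbour counting on
## rendered pixel positions (geometric oracle).
bruteInterior <- function(field, spacing = 20) {
  cc <- latticeCoords(field)
  meas <- isMeasured(field)
  pos <- hexAxialToPixel(cc$q, cc$r, spacing)
  keep <- logical(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    if (!meas[i]) next
    d <- sqrt((pos$x - pos$x[i])^2 + (pos$y - pos$y[i])^2)
    nb <- which(d > 1e-9 & d < spacing * 1.01)
    keep[i] <- length(nb) == 6 && all(meas[nb])
  }
  cc[keep, , drop = FALSE]
}

## Brute-force ED chain scan: enumerate every contiguous collinear window
## along the three axis directions, test all pairwise axial differences,
## keep maximal qualifying windows of sufficient length. Returns a sorted
## character vector of chains encoded as "axis|q:r,q:r,...".
bruteChains <- function(field, ed_tol = 5, min_len = 3) {
  cc <- latticeCoords(field)
  meas <- isMeasured(field)
  sig <- sigmaValues(field)
  key <- paste(cc$q, cc$r, sep = ":")
  look <- stats::setNames(seq_len(nrow(cc)), key)
  dirs <- list(row = c(1, 0), diag1 = c(0, 1), diag2 = c(1, -1))
  ok_window <- function(idx) {
    v <- sig[idx]
    all(outer(v, v, Vectorize(bruteDelta)) <= 2 * ed_tol + 1e-9)
  }
  found <- character()
  for (dn in names(dirs)) {
    d <- dirs[[dn]]
    for (i in which(meas)) {
      for (len in min_len:sum(meas)) {
        qs <- cc$q[i] + d[1] * (0:(len - 1))
        rs <- cc$r[i] + d[2] * (0:(len - 1))
        idx <- look[paste(qs, rs, sep = ":")]
        if (anyNA(idx) || !all(meas[idx])) break
        if (!ok_window(idx)) break
        ## maximal: neither predecessor nor successor extends the window
        pre <- look[paste(cc$q[i] - d[1], cc$r[i] - d[2], sep = ":")]
        nxt <- look[paste(qs[len] + d[1], rs[len] + d[2], sep = ":")]
        ext_pre <- !is.na(pre) && meas[pre] && ok_window(c(pre, idx))
        ext_nxt <- !is.na(nxt) && meas[nxt] && ok_window(c(idx, nxt))
        if (!ext_pre && !ext_nxt)
          found <- c(found,
            paste0(dn, "|", paste(qs, rs, sep = ":", collapse = ",")))
      }
    }
  }
  sort(unique(found))
}

## Encode the package's chain table in the same format as bruteChains.
encodeChains <- function(chains) {
  if (nrow(chains) == 0) return(character())
  out <- vapply(split(chains, chains$chain_id), function(d) {
    d <- d[order(d$position), ]
    paste0(d$axis[1], "|", paste(d$q, d$r, sep = ":", collapse = ","))
  }, character(1))
  sort(unname(out))
}

## Lattice 3-colouring by (q - r) mod 3: along every lattice line the
## colours cycle, so no two collinear ommatidia of equal colour are ever
## adjacent. Used to build fully misaligned patterns.
threePhaseField <- function(rows, cols, sigmas = c(0, 30, 60)) {
  cc <- expand.grid(q = 0:(cols - 1), r = 0:(rows - 1))
  SigmaField(cc$q, cc$r, sigmas[((cc$q - cc$r) %% 3) + 1])
}
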
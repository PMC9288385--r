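# Independent brute-force oracles used to freeze expected values. These
# deliberately re-derive each quantity from first principles (loops,
# enumeration, quadrature) and never call the implementation they check.

# Per-pixel Phansalkar threshold with mirror padding, by explicit window
# extraction.
oraclePhansalkar <- function(img, R, k = 0.25, r = 0.5, p = 2, q = 10) {
  n <- nrow(img); m <- ncol(img)
  ri <- c(rev(seq_len(R)), seq_len(n), n + 1 - seq_len(R))
  ci <- c(rev(seq_len(R)), seq_len(m), m + 1 - seq_len(R))
  pad <- img[ri, ci]
  out <- matrix(FALSE, n, m)
  for (a in seq_len(n)) for (b in seq_len(m)) {
    win <- pad[a:(a + 2 * R), b:(b + 2 * R)]
    mu <- mean(win)
    sd_ <- sqrt(mean(win^2) - mu^2)
    out[a, b] <- img[a, b] > mu * (1 + p * exp(-q * mu) + k * (sd_ / r - 1))
  }
  out
}

# Per-pixel minimum-candidate-ring-index assignment by direct distance
# search over every vessel's pixels.
oracleRingAssign <- function(masks, ringWidth, nRings) {
  dims <- dim(masks[[1]])
  vsets <- lapply(masks, function(m) which(m > 0, arr.ind = TRUE))
  anyVessel <- Reduce(`|`, lapply(masks, `>`, 0))
  vid <- matrix(0L, dims[1], dims[2])
  rix <- matrix(0L, dims[1], dims[2])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    if (anyVessel[i, j]) { vid[i, j] <- NA; rix[i, j] <- NA; next }
    ks <- vapply(vsets, function(vs)
      ceiling(sqrt(min((vs[, 1] - i)^2 + (vs[, 2] - j)^2)) / ringWidth),
      numeric(1))
    ks[ks > nRings] <- Inf
    if (any(is.finite(ks))) {
      mn <- min(ks)
      w <- which(ks == mn)
      if (length(w) == 1L) { vid[i, j] <- w; rix[i, j] <- as.integer(mn) }
    }
  }
  list(vesselId = vid, ringIndex = rix)
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracleMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  uStat <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  uObs <- uStat(a, b)
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) uStat(pooled[idx], pooled[-idx]))
  lo <- mean(us <= uObs); hi <- mean(us >= uObs)
  min(1, 2 * min(lo, hi))
}

# Exact two-sided Wilcoxon signed-rank p by enumerating sign patterns of the
# non-zero differences.
oracleSignedRankP <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  vObs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% rk
  lo <- mean(vs <= vObs); hi <- mean(vs >= vObs)
  min(1, 2 * min(lo, hi))
}

# Two-sided Fisher exact p by summing hypergeometric probabilities of all
# tables with the observed margins that are no more probable.
oracleFisherP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Arc length of a sinusoidal path by dense numerical quadrature.
oracleSinusoidArc <- function(length, amplitude, wavelength, phase = 0) {
  f <- function(t)
    sqrt(1 + (amplitude * 2 * pi / wavelength *
              cos(2 * pi * t / wavelength + phase))^2)
  stats::integrate(f, 0, length, subdivisions = 2000L,
                   rel.tol = 1e-10)$value
}

# Area-weighted mean planted width / unweighted mean planted tortuosity of a
# retina truth object.
truthSummary <- function(truth) {
  arcs <- vapply(truth$segments, `[[`, numeric(1), "arc_length")
  w <- vapply(truth$segments, `[[`, numeric(1), "width_um")
  list(mean_width = sum(w * arcs) / sum(arcs),
       mean_tortuosity = mean(vapply(truth$segments, `[[`, numeric(1),
                                     "tortuosity")),
       branching_index = truth$n_branch_points / truth$roi_area)
}

# Standard synthetic retina -> segmentation -> mask path used by several
# recovery tests.
segmentRetina <- function(out, pixelSize = 1) {
  pre <- preprocessRoi(out$image)
  filterMask(phansalkarThreshold(pre),
             minObjectArea = 25 * pixelSize^2,
             fillHoleArea = 25 * pixelSize^2, pixelSize = pixelSize)
}

# 8-connected digitisation of a circular arc as a pixel set matrix.
digitizeArc <- function(center, radius, from, to, dim) {
  t <- seq(from, to, length.out = 50L * ceiling(radius))
  pix <- unique(cbind(round(center[1] + radius * sin(t)),
                      round(center[2] + radius * cos(t))))
  m <- matrix(0, dim[1], dim[2])
  m[pix] <- 1
  m
}
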
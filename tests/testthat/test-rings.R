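# Perivascular ring assignment, thresholding, densities, coverage.

test_that("a single vessel's ring is the plain annulus", {
  v <- diskMask(c(64, 64), c(31, 31), 6)
  ra <- makeRings(list(v), ringWidth = 10, nRings = 1)
  lb <- ringLabels(ra)
  d <- distToMaskBrute <- matrix(NA_real_, 64, 64)
  vs <- which(v, arr.ind = TRUE)
  for (i in 1:64) for (j in 1:64)
    d[i, j] <- sqrt(min((vs[, 1] - i)^2 + (vs[, 2] - j)^2))
  annulus <- d > 0 & d <= 10 & !v
  got <- !is.na(lb$vesselId) & lb$vesselId == 1L
  expect_identical(got, annulus)
})

test_that("distant vessels get disjoint plain annuli", {
  v1 <- diskMask(c(64, 64), c(15, 15), 1)
  v2 <- diskMask(c(64, 64), c(45, 45), 1)    # > 30 um apart
  ra <- makeRings(list(v1, v2), ringWidth = 10, nRings = 1)
  lb <- ringLabels(ra)
  a1 <- !is.na(lb$vesselId) & lb$vesselId == 1L
  a2 <- !is.na(lb$vesselId) & lb$vesselId == 2L
  expect_false(any(a1 & a2))
  areas <- ringAreas(ra)
  expect_equal(nrow(areas), 2L)
  # each equals its own isolated annulus
  solo1 <- ringLabels(makeRings(list(v1), 10, 1))$vesselId
  soloAnn <- !is.na(solo1) & solo1 == 1L
  expect_identical(a1[3:35, 3:35], soloAnn[3:35, 3:35])
})

test_that("overlapping vessel masks are rejected", {
  v1 <- diskMask(c(32, 32), c(15, 15), 5)
  v2 <- diskMask(c(32, 32), c(18, 15), 5)
  expect_error(makeRings(list(v1, v2), 10, 1), "overlap")
})

test_that("ring assignment equals the brute-force minimum-index rule", {
  set.seed(99)
  done <- 0
  while (done < 20) {
    nV <- sample(2:4, 1)
    masks <- lapply(seq_len(nV), function(v)
      diskMask(c(64, 64), stats::runif(2, 8, 55), stats::runif(1, 2, 6)))
    if (any(Reduce(`+`, lapply(masks, `*`, 1)) > 1)) next
    done <- done + 1
    ra <- makeRings(masks, ringWidth = 7, nRings = 2)
    lb <- ringLabels(ra)
    oracle <- oracleRingAssign(masks, 7, 2)
    expect_identical(lb$vesselId, oracle$vesselId)
    expect_identical(lb$ringIndex, oracle$ringIndex)
    # conservation: assigned + unassigned + vessel interior = all pixels
    nAssigned <- sum(lb$vesselId > 0, na.rm = TRUE)
    nUnassigned <- sum(lb$vesselId == 0, na.rm = TRUE)
    nVesselPx <- sum(is.na(lb$vesselId))
    expect_equal(nAssigned + nUnassigned + nVesselPx, 64 * 64)
  }
})

test_that("thresholdChannel: fixed, percentile and Otsu behave as specified", {
  cb <- matrix(rep(c(0.4, 0.6), 32), 8, 8)     # checkerboard-ish
  mf <- thresholdChannel(cb, "fixed", 0.5)
  expect_equal(mean(mf), 0.5)                  # exactly half positive
  bg <- matrix(stats::rnorm(400, 0.1, 0.01), 20, 20)
  bg <- pmin(pmax(bg, 0), 1)
  mp <- thresholdChannel(bg, "percentile", 99)
  expect_lte(mean(mp), 0.01)
  # bimodal image: Otsu lands between the modes and agrees with an
  # exhaustive inter-class variance maximiser
  set.seed(5)
  img <- matrix(c(stats::rnorm(300, 0.25, 0.03),
                  stats::rnorm(100, 0.75, 0.03)), 20, 20)
  img <- pmin(pmax(img, 0), 1)
  mo <- thresholdChannel(img, "otsu")
  t_otsu <- attr(mo, "threshold")
  expect_gt(t_otsu, 0.35); expect_lt(t_otsu, 0.65)
  cands <- seq(0, 1, length.out = 256)
  icv <- vapply(cands, function(t) {
    a <- img[img <= t]; b <- img[img > t]
    if (!length(a) || !length(b)) return(-Inf)
    length(a) * length(b) * (mean(a) - mean(b))^2
  }, numeric(1))
  # with an empty gap between the modes the maximiser is a plateau: the
  # returned threshold must achieve the same (maximal) inter-class variance
  icvAt <- function(t) {
    a <- img[img <= t]; b <- img[img > t]
    length(a) * length(b) * (mean(a) - mean(b))^2
  }
  expect_equal(icvAt(t_otsu), max(icv))
  expect_warning(thresholdChannel(matrix(0.3, 5, 5), "otsu"), "constant")
})

test_that("ringDensity adjusts counts for area and depth", {
  v <- diskMask(c(64, 64), c(31, 31), 5)
  ra <- makeRings(list(v), ringWidth = 8, nRings = 2)
  empty <- matrix(FALSE, 64, 64)
  rd0 <- ringDensity(ra, empty, depth = 10)
  expect_true(all(rd0$density == 0))
  # positive everywhere: normalised density exactly 1 in every ring
  rdAll <- ringDensity(ra, !v, depth = 10)
  expect_true(all(abs(rdAll$normalized_density - 1) < 1e-12))
  expect_equal(rdAll$density, rdAll$positive_count / (rdAll$area * 10))
  # zero-area ring flagged, not an error
  raFar <- makeRings(list(diskMask(c(20, 20), c(9, 9), 8)), ringWidth = 50,
                     nRings = 2)
  rdz <- ringDensity(raFar, matrix(TRUE, 20, 20))
  expect_true(rdz$undefined[rdz$ring_index == 2])
  expect_true(is.na(rdz$density[rdz$ring_index == 2]))
})

test_that("planted step profiles are recovered ring by ring", {
  okrings <- 0; total <- 0
  for (s in 1:3) {
    cfg <- synthConfig(imageSize = c(128, 128), noiseSd = 0.02, seed = s)
    masks <- list(diskMask(c(128, 128), c(39, 39), 6),
                  diskMask(c(128, 128), c(89, 84), 5))
    plant <- c(0.5, 0.25)
    prof <- function(r) ifelse(r <= 10, plant[1],
                               ifelse(r <= 20, plant[2], 0.1))
    out <- generateSectionImage(cfg, masks, prof)
    pos <- thresholdChannel(getChannel(out$image, "marker"), "fixed", 0.45)
    expect_identical(unname(pos[, ]), unname(out$positive[, ]))
    ra <- makeRings(masks, ringWidth = 10, nRings = 2)
    rd <- ringDensity(ra, pos, depth = cfg$depth)
    for (i in seq_len(nrow(rd))) {
      p <- plant[rd$ring_index[i]]; n <- rd$area[i]
      total <- total + 1
      okrings <- okrings +
        (abs(rd$positive_count[i] / n - p) <= 3 * sqrt(p * (1 - p) / n))
    }
  }
  expect_gte(okrings / total, 0.95)
})

test_that("coverageWithin counts marker pixels inside the vessel outline", {
  set.seed(31)
  v <- diskMask(c(40, 40), c(19, 19), 8)
  expect_equal(coverageWithin(v, matrix(TRUE, 40, 40)), 1)   # marker >= vessel
  expect_equal(coverageWithin(v, matrix(FALSE, 40, 40)), 0)
  for (i in 1:5) {
    mk <- matrix(stats::runif(1600) > 0.5, 40, 40)
    expect_equal(coverageWithin(v, mk), sum(mk & v) / sum(v))
  }
  expect_error(coverageWithin(matrix(FALSE, 4, 4), matrix(TRUE, 4, 4)),
               "empty")
})

test_that("summarizeCoverage averages vessels within image, then images", {
  df <- data.frame(animal = "r1", image = rep(c("i1", "i2", "i3"),
                                              c(1, 1, 1)),
                   coverage = c(0.2, 0.4, 0.6))
  expect_equal(summarizeCoverage(df)$mean_coverage, 0.4)
  dfc <- data.frame(animal = "r2", image = "i1", coverage = rep(0.4, 5))
  expect_equal(summarizeCoverage(dfc)$mean_coverage, 0.4)
  # unbalanced vessel counts: image-first averaging != pooled mean
  dfu <- data.frame(animal = "r3",
                    image = rep(c("i1", "i2"), c(4, 1)),
                    coverage = c(0.1, 0.1, 0.1, 0.1, 0.6))
  s <- summarizeCoverage(dfu)
  expect_equal(s$mean_coverage, mean(c(0.1, 0.6)))           # 0.35
  expect_false(isTRUE(all.equal(s$mean_coverage, mean(dfu$coverage))))
  expect_equal(s$n_vessels, 5)
})

test_that("annulusFraction reports percentage of annulus covered", {
  ann <- diskMask(c(40, 40), c(19, 19), 12) &
    !diskMask(c(40, 40), c(19, 19), 6)
  expect_equal(annulusFraction(ann, matrix(TRUE, 40, 40)), 100)
  expect_equal(annulusFraction(ann, matrix(FALSE, 40, 40)), 0)
  set.seed(8)
  f <- matrix(stats::runif(1600) > 0.6, 40, 40)
  expect_equal(annulusFraction(ann, f), 100 * sum(f & ann) / sum(ann))
  expect_error(annulusFraction(matrix(FALSE, 4, 4), f[1:4, 1:4]), "empty")
})
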
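# Synthetic generators: planted geometry, noise model, determinism.

test_that("makeVesselPath controls arc and chord length analytically", {
  # straight path: tortuosity exactly 1
  p0 <- makeVesselPath(c(5, 5), length = 100, amplitude = 0)
  expect_equal(p0$arc_length, 100)
  expect_equal(p0$chord_length, 100)
  expect_equal(p0$tortuosity, 1)
  # stored arc length is the vertex-to-vertex sum
  p <- makeVesselPath(c(0, 0), length = 100, amplitude = 10, wavelength = 50)
  expect_equal(p$arc_length, sum(sqrt(rowSums(diff(p$coords)^2))))
  # polyline sum agrees with dense quadrature of the sinusoid within 0.5%
  expect_equal(p$arc_length, oracleSinusoidArc(100, 10, 50),
               tolerance = 0.005)
  # seeded phase is reproducible
  expect_identical(makeVesselPath(c(0, 0), 50, 5, 30, seed = 11)$coords,
                   makeVesselPath(c(0, 0), 50, 5, 30, seed = 11)$coords)
  expect_error(makeVesselPath(c(0, 0), length = -1), "length")
  expect_error(makeVesselPath(c(0, 0), length = 10, wavelength = 0),
               "wavelength")
})

test_that("tortuosityAmplitude inverts the planted arc/chord ratio", {
  for (tau in c(1, 1.05, 1.2)) {
    a <- tortuosityAmplitude(tau, length = 100, wavelength = 50)
    got <- makeVesselPath(c(0, 0), 100, a, 50)$tortuosity
    expect_equal(got, tau, tolerance = 1e-4)
  }
})

test_that("renderTubes marks exactly the pixels within width/2 of the path", {
  seg <- list(list(coords = cbind(20, seq(10, 50, by = 0.5)), width = 7))
  m <- renderTubes(seg, c(40, 60), 1)
  # brute force: pixel centres within 3.5 um of the segment
  idx <- which(m | !m, arr.ind = TRUE)
  d <- vapply(seq_len(nrow(idx)), function(i) {
    y <- idx[i, 1] - 1; x <- idx[i, 2] - 1
    tproj <- pmin(pmax(x, 10), 50)
    sqrt((y - 20)^2 + (x - tproj)^2)
  }, numeric(1))
  expect_identical(as.vector(m), d <= 3.5)
  # out-of-bounds segments are reported by index
  bad <- list(list(coords = cbind(20, seq(10, 80, by = 1)), width = 7))
  expect_error(renderTubes(bad, c(40, 60), 1), "segment 1")
})

test_that("retina generator: noiseless foreground equals the rendered tube", {
  cfg <- synthConfig(imageSize = c(120, 120), noiseSd = 0, seed = 2)
  out <- generateRetinaImage(cfg, nBranches = 0, tortuosity = 1.02)
  # vessels dark on bright background: foreground = low-intensity pixels
  expect_identical(out$image < 0.5, out$render)
  expect_equal(sum(out$image < 0.5), sum(out$render))
})

test_that("retina truth lists the planted branch points and segments", {
  cfg <- synthConfig(imageSize = c(200, 200), noiseSd = 0, seed = 5)
  out <- generateRetinaImage(cfg, nBranches = 1)   # Y-tree: one junction
  expect_equal(out$truth$n_branch_points, 1L)
  expect_equal(nrow(out$truth$branch_points), 1L)
  # 1 junction splits the trunk in two + 1 branch = 3 segments
  expect_length(out$truth$segments, 3L)
  for (s in out$truth$segments)
    expect_gte(s$arc_length, s$chord_length - 1e-9)
  # branch point coincides with a vertex of the trunk polyline
  trunkish <- rbind(out$truth$segments[[1]]$coords,
                    out$truth$segments[[2]]$coords)
  dmin <- min(sqrt((trunkish[, 1] - out$truth$branch_points[1, 1])^2 +
                   (trunkish[, 2] - out$truth$branch_points[1, 2])^2))
  expect_lt(dmin, 1e-9)
})

test_that("fixed layout re-imaged under many noise seeds keeps its truth", {
  cfg <- synthConfig(imageSize = c(160, 160), noiseSd = 0.03, seed = 9)
  ref <- generateRetinaImage(cfg, nBranches = 2)
  imgs <- lapply(1:20, function(k)
    generateRetinaImage(cfg, nBranches = 2, noiseSeed = 1000 + k))
  for (out in imgs) {
    expect_identical(out$truth, ref$truth)     # identical planted geometry
    expect_identical(out$render, ref$render)   # identical noiseless render
  }
  expect_false(identical(imgs[[1]]$image, imgs[[2]]$image))
  # same seed twice: bit-identical everything
  expect_identical(generateRetinaImage(cfg, nBranches = 2)$image, ref$image)
})

test_that("section generator plants an exact Bernoulli ring profile", {
  cfg <- synthConfig(imageSize = c(100, 100), noiseSd = 0, seed = 3)
  masks <- list(diskMask(c(100, 100), c(49, 49), 5))
  # p = 0 everywhere: marker channel is all background
  out0 <- generateSectionImage(cfg, masks, function(r) r * 0)
  expect_true(all(getChannel(out0$image, "marker") ==
                  cfg$backgroundLevel))
  # p = 1 everywhere: every non-vessel pixel positive
  out1 <- generateSectionImage(cfg, masks, function(r) r * 0 + 1)
  expect_identical(out1$positive, !masks[[1]])
  # invalid probabilities rejected
  expect_error(generateSectionImage(cfg, masks, function(r) r * 0 + 1.2),
               "\\[0, 1\\]")
  # step profile: per-band positive fraction within 3 binomial SDs, with
  # the bands defined by brute-force distance to the vessel mask
  prof <- function(r) ifelse(r <= 10, 0.5, 0.1)
  out <- generateSectionImage(cfg, masks, prof)
  vs <- which(masks[[1]], arr.ind = TRUE)
  dm <- matrix(0, 100, 100)
  for (i in 1:100) for (j in 1:100)
    dm[i, j] <- sqrt(min((vs[, 1] - i)^2 + (vs[, 2] - j)^2))
  for (band in list(c(1e-9, 10, 0.5), c(10, 35, 0.1))) {
    sel <- dm > band[1] & dm <= band[2] & !masks[[1]]
    n <- sum(sel); phat <- sum(out$positive & sel) / n
    expect_lt(abs(phat - band[3]), 3 * sqrt(band[3] * (1 - band[3]) / n))
  }
})

test_that("tracer generator plants plateau and leak exactly", {
  cfg <- synthConfig(imageSize = c(60, 60), pixelSize = 1, noiseSd = 0,
                     backgroundLevel = 0.1, seed = 4)
  out <- generateTracerImage(cfg, center = c(29, 29), radius = 5,
                             leak = c(dextran = 0.3, cadaverine = 0))
  dx <- getChannel(out$image, "dextran")
  d <- sqrt(outer(((0:59) - 29)^2, ((0:59) - 29)^2, `+`))
  # noise 0: extravascular pixels are exactly background + leak
  expect_true(all(dx[d >= 5] == 0.4))
  expect_true(all(dx[d < 5] == 0.8))
  # leak 0: extravascular equals background exactly
  cd <- getChannel(out$image, "cadaverine")
  expect_true(all(cd[d >= 5] == 0.1))
  # with noise, the sample mean respects the CLT over >= 1000 pixels
  cfgN <- synthConfig(imageSize = c(60, 60), noiseSd = 0.03,
                      backgroundLevel = 0.1, seed = 4)
  outN <- generateTracerImage(cfgN, center = c(29, 29), radius = 5,
                              leak = c(dextran = 0.3, cadaverine = 0))
  ext <- d >= 8
  expect_gte(sum(ext), 1000)
  m <- mean(getChannel(outN$image, "dextran")[ext])
  expect_lt(abs(m - 0.4), 3 * 0.03 / sqrt(sum(ext)))
  expect_error(generateTracerImage(cfg, center = c(29, 29), radius = 5,
                                   leak = c(dextran = -1, cadaverine = 0)),
               "non-negative")
  expect_error(generateTracerImage(cfg, center = c(3, 3), radius = 5),
               "fit")
})

test_that("EM particle counts are Poisson at the planted density", {
  cells <- data.frame(volume = c(10, 5, 2), density = c(14, 0, 7))
  counts <- generateEmCounts(cells, seed = 8)
  expect_identical(counts, generateEmCounts(cells, seed = 8))
  expect_identical(counts[2], 0L)              # density 0 -> count 0
  # mean over 10^4 draws within 3 SE of density * volume = 140
  big <- data.frame(volume = rep(10, 1e4), density = 14)
  draws <- generateEmCounts(big, seed = 9)
  expect_lt(abs(mean(draws) - 140), 3 * sqrt(140 / 1e4))
  expect_error(generateEmCounts(data.frame(volume = 0, density = 1)),
               "volume")
  expect_error(generateEmCounts(data.frame(volume = 1, density = -2)),
               "densities")
})

test_that("planted tortuosity is always >= 1 and truth is internally consistent", {
  for (s in 1:10) {
    cfg <- synthConfig(imageSize = c(200, 200), noiseSd = 0, seed = 40 + s)
    out <- generateRetinaImage(cfg, nBranches = 2 + s %% 3)
    taus <- vapply(out$truth$segments, `[[`, numeric(1), "tortuosity")
    expect_true(all(taus >= 1 - 1e-12))
    expect_equal(out$truth$n_branch_points, nrow(out$truth$branch_points))
  }
})
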
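# Skeletonisation, graph construction, tortuosity, diameters.

test_that("a 7 px bar skeletonises to its centre row with EDT 4", {
  m <- matrix(0, 30, 70); m[12:18, 10:60] <- 1
  sk <- skeletonize(m)
  co <- skeletonCoords(sk)
  mid <- co[, 2] > 15 & co[, 2] < 55
  expect_true(all(co[mid, 1] == 15))           # centre row
  # distance to nearest background pixel centre is exactly 4 px
  expect_true(all(skeletonRadius(sk)[mid] == 4))
  # calibrated diameter with the axis-aligned half-pixel correction: 7 px
  expect_true(all(skeletonDiameters(sk, halfPixelCorrection = TRUE)[mid]
                  == 7))
  # brute-force nearest-background check at one skeleton pixel
  bg <- which(m == 0, arr.ind = TRUE)
  p <- co[which(mid)[1], ]
  expect_equal(min(sqrt((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2)), 4)
})

test_that("a disk collapses to a central cluster with max radius ~ its own", {
  m <- diskMask(c(41, 41), c(20, 20), 10)
  sk <- skeletonize(m)
  expect_lt(max(abs(skeletonCoords(sk) - 21)), 3)
  expect_gt(max(skeletonRadius(sk)), 9)
  expect_lte(max(skeletonRadius(sk)), 11)
})

test_that("empty masks give empty skeletons, not errors", {
  sk <- skeletonize(matrix(0, 10, 10))
  expect_equal(nrow(skeletonCoords(sk)), 0L)
  expect_length(skeletonRadius(sk), 0L)
})

test_that("graph topology: line, Y, and planted trees", {
  m <- matrix(0, 20, 40); m[8:14, 5:35] <- 1
  g <- buildGraph(skeletonize(m))
  expect_equal(sum(graphNodes(g)$kind == "end"), 2L)
  expect_equal(sum(graphNodes(g)$kind == "branch"), 0L)
  expect_equal(nrow(graphEdges(g)), 1L)

  mk <- function(ang) list(coords = cbind(60 + seq(0, 40, 0.5) * cos(ang),
                                          60 + seq(0, 40, 0.5) * sin(ang)),
                           width = 7)
  ym <- renderTubes(list(list(coords = cbind(seq(10, 60, 0.5), 60),
                              width = 7),
                         mk(pi / 4), mk(-pi / 4)), c(120, 120), 1)
  gy <- buildGraph(skeletonize(ym))
  expect_equal(sum(graphNodes(gy)$kind == "branch"), 1L)
  expect_equal(sum(graphNodes(gy)$kind == "end"), 3L)
  expect_equal(nrow(graphEdges(gy)), 3L)
  nd <- graphNodes(gy)
  expect_true(all(nd$degree[nd$kind == "branch"] > 2))
  expect_true(all(nd$degree[nd$kind == "end"] == 1))

  # noiseless planted trees: recovered branch count equals planted count
  for (s in 1:10) {
    cfg <- synthConfig(imageSize = c(256, 256), noiseSd = 0, seed = 700 + s)
    out <- generateRetinaImage(cfg, nBranches = 2 + s %% 4)
    mo <- morphometry(out$render)
    expect_identical(mo$n_branch_points, out$truth$n_branch_points)
  }
})

test_that("edge arc >= chord always, and loops are flagged NA", {
  ring <- diskMask(c(41, 41), c(20, 20), 15) &
    !diskMask(c(41, 41), c(20, 20), 9)
  g <- buildGraph(skeletonize(ring))
  e <- graphEdges(g)
  expect_true(all(e$arc >= e$chord - 1e-9))
  expect_true(any(is.na(edgeTortuosity(g))))   # the closed loop
  expect_true(is.nan(meanTortuosity(g)))       # excluded from means
})

test_that("a digitised semicircle has tortuosity pi/2 within 2%", {
  m <- digitizeArc(c(60, 60), 40, 0, pi, c(120, 120))
  g <- buildGraph(skeletonize(m), pruneLen = 0)
  e <- graphEdges(g)
  expect_equal(nrow(e), 1L)
  expect_equal(e$arc / e$chord, pi / 2, tolerance = 0.02)
})

test_that("planted sinusoid tortuosity is recovered within 5%", {
  for (tau in c(1.05, 1.15, 1.3)) {
    amp <- tortuosityAmplitude(tau, 150, 75)
    path <- makeVesselPath(c(30, 20), 150, amp, 75, direction = c(0.3, 1))
    m <- renderTubes(list(list(coords = path$coords, width = 7)),
                     c(100, 200), 1)
    g <- buildGraph(skeletonize(m))
    e <- graphEdges(g)
    expect_equal(nrow(e), 1L)
    expect_equal(e$arc / e$chord, path$tortuosity, tolerance = 0.05)
  }
})

test_that("straight trees have mean tortuosity 1 within digitisation error", {
  m <- renderTubes(list(list(coords = cbind(seq(10, 90, 0.5), 30),
                             width = 5),
                        list(coords = cbind(50, seq(30, 90, 0.5)),
                             width = 5)), c(100, 100), 1)
  g <- buildGraph(skeletonize(m))
  expect_equal(meanTortuosity(g), 1, tolerance = 0.02)
  expect_true(all(edgeTortuosity(g) >= 1 - 0.02))
})

test_that("branching index is branch count per unit area", {
  mk <- function(ang) list(coords = cbind(50 + seq(0, 30, 0.5) * cos(ang),
                                          50 + seq(0, 30, 0.5) * sin(ang)),
                           width = 5)
  ym <- renderTubes(list(list(coords = cbind(seq(10, 50, 0.5), 50),
                              width = 5),
                         mk(pi / 4), mk(-pi / 4)), c(100, 100), 1)
  g <- buildGraph(skeletonize(ym))
  expect_equal(branchingIndex(g, 100 * 100), 1e-4)   # 1 per 100x100 um
  gline <- buildGraph(skeletonize(matrix(c(rep(0, 40), rep(1, 20),
                                           rep(0, 40)), 10, 10)))
  expect_equal(branchingIndex(gline, 1e4), 0)
  expect_error(branchingIndex(g, 0), "roiArea")
  # planted trees: exact equality with truth count / area
  cfg <- synthConfig(imageSize = c(256, 256), noiseSd = 0, seed = 77)
  out <- generateRetinaImage(cfg, nBranches = 3)
  mo <- morphometry(out$render)
  expect_equal(mo$branching_index,
               out$truth$n_branch_points / out$truth$roi_area)
})

test_that("rotating a mask by 90 degrees preserves the morphometry", {
  cfg <- synthConfig(imageSize = c(220, 220), noiseSd = 0, seed = 13)
  out <- generateRetinaImage(cfg, nBranches = 3)
  m <- out$render
  rot <- t(m)[, nrow(m):1]                     # 90 degree rotation
  a <- morphometry(m); b <- morphometry(rot)
  expect_identical(a$n_branch_points, b$n_branch_points)
  expect_equal(a$mean_tortuosity, b$mean_tortuosity, tolerance = 0.02)
  expect_equal(a$mean_diameter, b$mean_diameter, tolerance = 0.02)
})

test_that("majorVesselDiameter measures calliper widths along a centreline", {
  # uniform tube, width 12 um (centreline off the pixel grid, as in real
  # images; an exactly grid-aligned centreline renders one extra pixel row)
  cl <- cbind(40.5, seq(20, 420, by = 1))
  m <- renderTubes(list(list(coords = cl, width = 12)), c(80, 440), 1)
  res <- majorVesselDiameter(m, cl, interval = 100)
  expect_equal(res$mean, 12, tolerance = 1 / 12)   # within 1 px
  expect_equal(res$positions, c(0, 100, 200, 300, 400))
  # linear taper 20 -> 10 um: mean ~ mean of the sampled true widths
  tpos <- seq(20, 420, by = 1)
  segsT <- lapply(seq_along(tpos[-1]), function(i)
    list(coords = cbind(c(40.3, 40.3), tpos[i + 0:1]),
         width = 20 - 10 * (tpos[i] - 20) / 400))
  mt <- renderTubes(segsT, c(80, 440), 1)
  clT <- cbind(40.3, seq(20, 420, by = 1))
  resT <- majorVesselDiameter(mt, clT, interval = 100)
  trueW <- 20 - 10 * resT$positions / 400
  expect_equal(resT$mean, mean(trueW), tolerance = 0.08)
  # centreline shorter than the interval: single measurement at the origin
  short <- majorVesselDiameter(m, cl[1:50, ], interval = 200)
  expect_length(short$widths, 1L)
  # perpendicular exiting the image drops the sample with a warning
  edge <- renderTubes(list(list(coords = cbind(6, seq(20, 420, 1)),
                                width = 12)), c(80, 440), 1)
  expect_warning(majorVesselDiameter(edge, cbind(6, seq(20, 420, 1)),
                                     interval = 100, maxWidth = 40),
                 "dropped")
})

test_that("axon diameter from perimeter assumes a circle", {
  expect_equal(axonDiameterFromPerimeter(pi), 1)
  expect_equal(axonDiameterFromPerimeter(31.4159), 10, tolerance = 1e-5)
  # circle traced at 1 degree resolution, radius 0.5 um
  ang <- seq(0, 2 * pi, length.out = 361)
  poly <- cbind(0.5 * cos(ang), 0.5 * sin(ang))
  per <- sum(sqrt(rowSums(diff(poly)^2)))
  expect_equal(axonDiameterFromPerimeter(per), 1, tolerance = 0.001)
  expect_error(axonDiameterFromPerimeter(0), "perimeter")
})
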
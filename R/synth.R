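# Synthetic-image generators with planted ground truth.
#
# Every quantification stage in the package is validated against images whose
# true diameters, tortuosities, branch points, perivascular marker profiles,
# tracer leak levels and particle densities are known exactly. The geometry
# convention is shared with the rest of the package: pixel [i, j] has its
# centre at ((i-1) * pixel_size, (j-1) * pixel_size) micrometres, and a pixel
# belongs to a rendered tube iff its centre lies within width/2 (Euclidean)
# of the tube's centreline polyline.

#' Synthetic-acquisition configuration
#'
#' Bundles the acquisition parameters shared by all generators. The defaults
#' emulate a widefield/confocal acquisition of a 10 um cryosection at 1 um
#' per pixel with mild additive Gaussian read noise.
#'
#' @param imageSize integer (rows, cols) in pixels.
#' @param pixelSize micrometres per pixel (> 0).
#' @param depth section thickness in micrometres (> 0).
#' @param noiseSd SD of additive Gaussian intensity noise (images are clipped
#'   to \code{[0, 1]} after adding noise).
#' @param backgroundLevel background intensity in \code{[0, 1)}.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return a validated \code{SynthConfig} list.
#' @examples
#' cfg <- synthConfig(imageSize = c(128, 128), noiseSd = 0)
#' @export
synthConfig <- function(imageSize = c(256L, 256L), pixelSize = 1, depth = 10,
                        noiseSd = 0.02, backgroundLevel = 0.1, seed = 1L) {
  stopifnot(length(imageSize) == 2L, all(imageSize >= 8))
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  if (depth <= 0) stop("depth must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (backgroundLevel < 0 || backgroundLevel >= 1)
    stop("backgroundLevel must be in [0, 1)")
  structure(list(imageSize = as.integer(imageSize),
                 pixelSize = as.numeric(pixelSize), depth = as.numeric(depth),
                 noiseSd = as.numeric(noiseSd),
                 backgroundLevel = as.numeric(backgroundLevel),
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

addNoise <- function(img, noiseSd) {
  if (noiseSd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noiseSd),
                        nrow(img), ncol(img))
  pmin(pmax(img, 0), 1)
}

#' Sinusoidally perturbed vessel centreline with known arc and chord length
#'
#' Builds a dense polyline along a straight baseline of the given length with
#' a perpendicular sinusoidal offset, so the planted tortuosity (arc/chord)
#' is controlled analytically by the amplitude/wavelength pair. The stored
#' \code{arc_length} is the exact sum of vertex-to-vertex distances and
#' \code{chord_length} the start-to-end distance.
#'
#' @param start numeric (row, col) start point in micrometres.
#' @param length baseline length in micrometres (> 0).
#' @param amplitude sinusoid amplitude in micrometres (0 gives a straight
#'   segment with tortuosity exactly 1).
#' @param wavelength sinusoid wavelength in micrometres (> 0).
#' @param direction unit-free (row, col) direction of the baseline.
#' @param phase sinusoid phase in radians.
#' @param step vertex spacing along the baseline in micrometres.
#' @param seed optional seed; when given, the phase is drawn uniformly so
#'   repeated calls with the same seed give identical polylines.
#' @return list with \code{coords} (n x 2 matrix, micrometres),
#'   \code{arc_length}, \code{chord_length} and \code{tortuosity}.
#' @examples
#' p <- makeVesselPath(c(0, 0), length = 100, amplitude = 0, wavelength = 50)
#' p$tortuosity   # exactly 1
#' @export
makeVesselPath <- function(start, length, amplitude = 0, wavelength = 50,
                           direction = c(0, 1), phase = 0, step = 0.25,
                           seed = NULL) {
  if (length <= 0) stop("length must be > 0")
  if (wavelength <= 0) stop("wavelength must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (!is.null(seed))
    phase <- withSeed(seed, stats::runif(1, 0, 2 * pi))
  u <- direction / sqrt(sum(direction^2))
  v <- c(-u[2], u[1])                      # perpendicular
  t <- seq(0, length, by = step)
  if (t[base::length(t)] < length) t <- c(t, length)
  off <- amplitude * sin(2 * pi * t / wavelength + phase) -
    amplitude * sin(phase)                 # anchor the path at `start`
  coords <- cbind(start[1] + t * u[1] + off * v[1],
                  start[2] + t * u[2] + off * v[2])
  arc <- sum(sqrt(rowSums(diff(coords)^2)))
  chord <- sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
  list(coords = coords, arc_length = arc, chord_length = chord,
       tortuosity = arc / chord)
}

#' Amplitude giving a target planted tortuosity
#'
#' Inverts [makeVesselPath()]'s arc/chord ratio numerically: returns the
#' sinusoid amplitude for which a path of the given baseline length and
#' wavelength has the requested tortuosity.
#'
#' @param tortuosity target arc/chord ratio (>= 1).
#' @param length,wavelength,phase,direction as in [makeVesselPath()].
#' @return amplitude in micrometres.
#' @export
tortuosityAmplitude <- function(tortuosity, length, wavelength,
                                phase = 0, direction = c(0, 1)) {
  stopifnot(tortuosity >= 1)
  if (tortuosity == 1) return(0)
  f <- function(a)
    makeVesselPath(c(0, 0), length, a, wavelength, direction = direction,
                   phase = phase)$tortuosity - tortuosity
  upper <- wavelength
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-6)$root
}

#' Render tube segments into a binary mask
#'
#' A pixel is foreground iff its centre lies within width/2 (Euclidean
#' distance) of the segment's centreline polyline. This is the exact
#' counterpart of the distance-transform radius recovery used by
#' [skeletonize()].
#'
#' @param segments list of segments, each a list with \code{coords}
#'   (n x 2 polyline, micrometres) and \code{width} (micrometres).
#' @param imageSize integer (rows, cols) in pixels.
#' @param pixelSize micrometres per pixel.
#' @return logical matrix.
#' @export
renderTubes <- function(segments, imageSize, pixelSize = 1) {
  nr <- imageSize[1]; nc <- imageSize[2]
  mask <- matrix(FALSE, nr, nc)
  lim <- (c(nr, nc) - 1) * pixelSize
  for (s in seq_along(segments)) {
    seg <- segments[[s]]
    w2 <- seg$width / 2
    xy <- seg$coords
    if (any(xy[, 1] - w2 < 0) || any(xy[, 1] + w2 > lim[1]) ||
        any(xy[, 2] - w2 < 0) || any(xy[, 2] + w2 > lim[2]))
      stop("segment ", s, " (plus its half-width) exceeds the image bounds")
    for (e in seq_len(nrow(xy) - 1L)) {
      p1 <- xy[e, ]; p2 <- xy[e + 1L, ]
      r0 <- max(1L, floor((min(p1[1], p2[1]) - w2) / pixelSize) + 1L)
      r1 <- min(nr, ceiling((max(p1[1], p2[1]) + w2) / pixelSize) + 2L)
      c0 <- max(1L, floor((min(p1[2], p2[2]) - w2) / pixelSize) + 1L)
      c1 <- min(nc, ceiling((max(p1[2], p2[2]) + w2) / pixelSize) + 2L)
      rows <- r0:r1; cols <- c0:c1
      if (!length(rows) || !length(cols)) next
      py <- (rows - 1) * pixelSize; px <- (cols - 1) * pixelSize
      d <- p2 - p1; L2 <- sum(d^2)
      gy <- matrix(py, length(rows), length(cols))
      gx <- matrix(px, length(rows), length(cols), byrow = TRUE)
      tt <- if (L2 > 0)
        pmin(pmax(((gy - p1[1]) * d[1] + (gx - p1[2]) * d[2]) / L2, 0), 1)
      else 0
      dist2 <- (gy - (p1[1] + tt * d[1]))^2 + (gx - (p1[2] + tt * d[2]))^2
      hit <- dist2 <= w2^2
      if (any(hit)) {
        sub <- mask[rows, cols, drop = FALSE]
        mask[rows, cols] <- sub | hit
      }
    }
  }
  mask
}

#' Synthetic retinal vessel tree with planted morphometry truth
#'
#' Renders a vessel tree -- a sinusoidal trunk with side branches attached at
#' known points -- at a known micrometre-per-pixel calibration, emulating a
#' binarisable flat-mount plexus image in which vessels appear dark on a
#' bright background (so that the standard invert-and-threshold protocol of
#' [preprocessRoi()] and [phansalkarThreshold()] applies). The returned
#' ground truth lists every centreline segment between graph nodes (with
#' width, arc length, chord length and tortuosity) and every branch point,
#' so skeleton-based morphometry can be validated against exact values.
#'
#' @param config a [synthConfig()].
#' @param nBranches number of side branches (>= 0).
#' @param trunkWidth,branchWidth tube widths in micrometres; must be at least
#'   3 pixels at \code{config$pixelSize}.
#' @param tortuosity planted trunk tortuosity target (>= 1, applied to the
#'   whole trunk; per-segment truth is recomputed from the split polylines).
#' @param branchTortuosity planted tortuosity of each branch.
#' @param vesselIntensity,backgroundIntensity rendered intensities.
#' @param seed seed for the layout jitter (defaults to
#'   \code{config$seed}).
#' @param noiseSeed separate seed for the additive noise, so a fixed layout
#'   can be re-imaged under independent noise realisations.
#' @return list with \code{image} (noisy), \code{render} (noiseless logical
#'   mask) and \code{truth}: list of \code{segments} (coords, width_um,
#'   arc_length, chord_length, tortuosity), \code{branch_points} (k x 2
#'   micrometre coordinates), \code{roi_area} (um^2), \code{n_branch_points}.
#' @examples
#' cfg <- synthConfig(imageSize = c(160, 160), noiseSd = 0)
#' out <- generateRetinaImage(cfg, nBranches = 2)
#' out$truth$n_branch_points
#' @export
generateRetinaImage <- function(config, nBranches = 4, trunkWidth = 8,
                                branchWidth = 6, tortuosity = 1.08,
                                branchTortuosity = 1.05,
                                vesselIntensity = 0.15,
                                backgroundIntensity = 0.85,
                                seed = config$seed,
                                noiseSeed = seed + 1L) {
  stopifnot(inherits(config, "SynthConfig"))
  ps <- config$pixelSize
  if (trunkWidth / ps < 3 || branchWidth / ps < 3)
    stop("tube widths must be at least 3 pixels at the configured pixel size")
  nr <- config$imageSize[1]; nc <- config$imageSize[2]
  lim <- (c(nr, nc) - 1) * ps
  margin <- max(12 * ps, trunkWidth)

  layout <- withSeed(seed, {
    trunkLen <- lim[1] - 2 * margin
    wl <- trunkLen / 2
    amp <- tortuosityAmplitude(tortuosity, trunkLen, wl)
    trunk <- makeVesselPath(c(margin, lim[2] / 2 + stats::runif(1, -8, 8) * ps),
                            trunkLen, amp, wl, direction = c(1, 0),
                            step = ps / 4)
    nV <- nrow(trunk$coords)
    attachFrac <- if (nBranches > 0) (seq_len(nBranches)) / (nBranches + 1)
                  else numeric(0)
    attachIdx <- pmax(2L, pmin(nV - 1L, round(attachFrac * nV)))
    segs <- list(); bps <- NULL
    # split the trunk at the attachment vertices: per-piece truth
    cuts <- c(1L, attachIdx, nV)
    for (i in seq_len(length(cuts) - 1L)) {
      co <- trunk$coords[cuts[i]:cuts[i + 1L], , drop = FALSE]
      segs[[length(segs) + 1L]] <- list(coords = co, width = trunkWidth)
    }
    # minimum centreline clearance so rendered tubes never touch except at
    # their planted junctions
    clearance <- (trunkWidth + branchWidth) / 2 + 2 * ps
    minDist <- function(A, B) {
      a <- A[seq(1, nrow(A), by = 4L), , drop = FALSE]
      b <- B[seq(1, nrow(B), by = 4L), , drop = FALSE]
      sqrt(min(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2))
    }
    branchCoords <- list()
    availAxis <- function(pos, d, lo, hi) {
      if (abs(d) < 1e-9) Inf else if (d > 0) (hi - pos) / d
      else (pos - lo) / abs(d)
    }
    for (b in seq_len(nBranches)) {
      at <- trunk$coords[attachIdx[b], ]
      side <- if (b %% 2 == 1) 1 else -1
      # steep angle off the *local* trunk tangent, so the branch separates
      # cleanly instead of running inside the trunk tube
      tang <- trunk$coords[attachIdx[b] + 1L, ] -
              trunk$coords[attachIdx[b] - 1L, ]
      tang <- tang / sqrt(sum(tang^2))
      placed <- FALSE
      for (try in 1:40) {
        ang <- side * stats::runif(1, 55, 75) * pi / 180
        dirv <- c(cos(ang) * tang[1] - sin(ang) * tang[2],
                  sin(ang) * tang[1] + cos(ang) * tang[2])
        avail <- min(availAxis(at[1], dirv[1], margin, lim[1] - margin),
                     availAxis(at[2], dirv[2], margin, lim[2] - margin))
        blen <- min(stats::runif(1, 0.6, 0.9) * avail, 90 * ps)
        if (blen < 20 * ps) next
        bwl <- blen
        bamp <- tortuosityAmplitude(branchTortuosity, blen, bwl)
        br <- makeVesselPath(at, blen, bamp, bwl, direction = dirv,
                             step = ps / 4)
        # clearance: against other branches everywhere, and against the
        # trunk beyond the attachment neighbourhood
        arc <- c(0, cumsum(sqrt(rowSums(diff(br$coords)^2))))
        away <- br$coords[arc > 3 * trunkWidth, , drop = FALSE]
        ok <- all(vapply(branchCoords, function(other)
                minDist(br$coords, other) >= clearance, logical(1))) &&
              (nrow(away) == 0 || minDist(away, trunk$coords) >= clearance)
        if (ok) { placed <- TRUE; break }
      }
      if (!placed)
        stop("branch ", b, " could not be placed without touching another ",
             "vessel; reduce nBranches or enlarge the image")
      branchCoords[[b]] <- br$coords
      segs[[length(segs) + 1L]] <- list(coords = br$coords,
                                        width = branchWidth)
      bps <- rbind(bps, at)
    }
    list(segs = segs, bps = bps)
  })

  render <- renderTubes(layout$segs, config$imageSize, ps)
  img <- withSeed(noiseSeed, {
    base <- matrix(backgroundIntensity, nr, nc)
    base[render] <- vesselIntensity
    addNoise(base, config$noiseSd)
  })
  segments <- lapply(layout$segs, function(s) {
    arc <- sum(sqrt(rowSums(diff(s$coords)^2)))
    chord <- sqrt(sum((s$coords[nrow(s$coords), ] - s$coords[1, ])^2))
    list(coords = s$coords, width_um = s$width, arc_length = arc,
         chord_length = chord, tortuosity = arc / chord)
  })
  truth <- list(segments = segments,
                branch_points = layout$bps,
                n_branch_points = if (is.null(layout$bps)) 0L
                                  else nrow(layout$bps),
                roi_area = nr * nc * ps^2,
                pixel_size = ps)
  list(image = img, render = render, truth = truth)
}

#' Disk-shaped vessel mask
#'
#' @param imageSize integer (rows, cols) pixels.
#' @param center (row, col) centre in micrometres.
#' @param radius radius in micrometres.
#' @param pixelSize micrometres per pixel.
#' @return logical matrix; a pixel is inside iff its centre is within
#'   \code{radius} of \code{center}.
#' @export
diskMask <- function(imageSize, center, radius, pixelSize = 1) {
  py <- ((seq_len(imageSize[1])) - 1) * pixelSize
  px <- ((seq_len(imageSize[2])) - 1) * pixelSize
  outer(py, px, function(y, x) (y - center[1])^2 + (x - center[2])^2) <=
    radius^2
}

#' Synthetic vessel + marker section with a planted perivascular profile
#'
#' Emulates a stained brain section with a vessel channel (rendered masks)
#' and a marker channel whose per-pixel positive probability depends only on
#' the distance of the pixel from the nearest vessel edge: each non-vessel
#' pixel is an independent Bernoulli draw with probability \code{p(r)},
#' positive pixels rendered at \code{markerIntensity} over the background.
#'
#' @param config a [synthConfig()].
#' @param vesselMasks list of non-overlapping logical matrices.
#' @param ringProfile function mapping distance r (micrometres, vectorised)
#'   to a positive-pixel probability in \code{[0, 1]}.
#' @param markerIntensity intensity of positive marker pixels.
#' @param seed seed (defaults to \code{config$seed}).
#' @return list with \code{image} (a \linkS4class{MultiChannelImage} with
#'   channels \code{vessel} and \code{marker}), \code{positive} (the exact
#'   Bernoulli draw, before intensity scaling/noise) and \code{truth}.
#' @export
generateSectionImage <- function(config, vesselMasks, ringProfile,
                                 markerIntensity = 0.8,
                                 seed = config$seed) {
  stopifnot(inherits(config, "SynthConfig"))
  nr <- config$imageSize[1]; nc <- config$imageSize[2]
  vessel <- Reduce(`|`, vesselMasks)
  if (!identical(dim(vessel), c(nr, nc)))
    stop("vessel masks must match config$imageSize")
  d <- distanceToMask(vessel) * config$pixelSize
  p <- matrix(ringProfile(as.numeric(d)), nr, nc)
  if (any(p < 0 | p > 1))
    stop("ringProfile must return probabilities in [0, 1]")
  positive <- withSeed(seed, matrix(stats::runif(nr * nc), nr, nc) < p)
  positive[vessel] <- FALSE
  marker <- withSeed(seed + 1L, {
    m <- matrix(config$backgroundLevel, nr, nc)
    m[positive] <- markerIntensity
    addNoise(m, config$noiseSd)
  })
  vch <- matrix(config$backgroundLevel, nr, nc)
  vch[vessel] <- 0.9
  img <- MultiChannelImage(list(vessel = vch, marker = marker),
                           pixelSize = config$pixelSize, depth = config$depth)
  list(image = img, positive = positive,
       truth = list(n_vessels = length(vesselMasks), depth = config$depth,
                    pixel_size = config$pixelSize))
}

#' Synthetic tracer cross-section with a planted extravascular leak
#'
#' Emulates a perpendicular cross-section through a longitudinally cut
#' vessel after tail-vein tracer injection: the lectin channel delineates
#' the vessel (lumen plus wall, a filled plateau across the vessel on a
#' perpendicular profile), and each tracer channel takes its intravascular
#' plateau value inside the lumen and the acquisition background plus its
#' planted leak level outside, plus additive Gaussian noise. Placing the
#' leak on top of the background pedestal keeps the noise clear of the
#' \code{[0, 1]} clip so planted amplitudes are recoverable without bias.
#'
#' @param config a [synthConfig()].
#' @param center (row, col) vessel centre in micrometres.
#' @param radius lumen radius in micrometres.
#' @param wallThickness vessel wall thickness in micrometres (the lectin
#'   plateau spans \code{radius + wallThickness}).
#' @param plateau named numeric of intravascular intensities, e.g.
#'   \code{c(dextran = 0.8, cadaverine = 0.8)}.
#' @param leak named numeric of extravascular mean intensities above
#'   background (same names).
#' @param lectinIntensity vessel intensity of the lectin channel.
#' @param seed seed (defaults to \code{config$seed}).
#' @return list with \code{image} (channels \code{lectin} + tracers) and
#'   \code{truth} (centre, radius, plateau, leak, background).
#' @export
generateTracerImage <- function(config, center, radius, wallThickness = 2,
                                plateau = c(dextran = 0.8, cadaverine = 0.8),
                                leak = c(dextran = 0, cadaverine = 0),
                                lectinIntensity = 0.9,
                                seed = config$seed) {
  stopifnot(inherits(config, "SynthConfig"))
  if (any(plateau < 0) || any(leak < 0) || lectinIntensity < 0)
    stop("intensities must be non-negative")
  if (!identical(sort(names(plateau)), sort(names(leak))))
    stop("plateau and leak must name the same tracer channels")
  if (any(config$backgroundLevel + leak > 1))
    stop("backgroundLevel + leak must not exceed 1")
  nr <- config$imageSize[1]; nc <- config$imageSize[2]
  lim <- (c(nr, nc) - 1) * config$pixelSize
  if (any(center - radius - wallThickness < 0) ||
      any(center + radius + wallThickness > lim))
    stop("vessel does not fit inside the image")
  py <- (seq_len(nr) - 1) * config$pixelSize
  px <- (seq_len(nc) - 1) * config$pixelSize
  d <- sqrt(outer((py - center[1])^2, (px - center[2])^2, `+`))
  vessel <- d <= radius + wallThickness
  inside <- d < radius
  chans <- list()
  lect <- matrix(config$backgroundLevel, nr, nc)
  lect[vessel] <- lectinIntensity
  chans$lectin <- lect
  for (nm in names(plateau)) {
    m <- matrix(config$backgroundLevel + leak[[nm]], nr, nc)
    m[inside] <- plateau[[nm]]
    chans[[nm]] <- m
  }
  img <- withSeed(seed, {
    noisy <- lapply(chans, addNoise, noiseSd = config$noiseSd)
    MultiChannelImage(noisy, pixelSize = config$pixelSize,
                      depth = config$depth)
  })
  list(image = img,
       truth = list(center = center, radius = radius,
                    wall_thickness = wallThickness,
                    plateau = as.list(plateau), leak = as.list(leak),
                    background = config$backgroundLevel))
}

#' Poisson immunogold particle counts at planted densities
#'
#' Draws one particle count per reconstructed cell,
#' \code{count ~ Poisson(density * volume)}, emulating immunogold labelling
#' of cell profiles of known volume.
#'
#' @param cells data.frame with columns \code{volume} (um^3, > 0) and
#'   \code{density} (particles per um^3, >= 0).
#' @param seed integer seed.
#' @return integer vector of counts, one per row of \code{cells}.
#' @examples
#' generateEmCounts(data.frame(volume = c(10, 5), density = c(14, 0)),
#'                  seed = 1)
#' @export
generateEmCounts <- function(cells, seed = 1L) {
  stopifnot(is.data.frame(cells), all(c("volume", "density") %in% names(cells)))
  if (any(cells$volume <= 0)) stop("volumes must be > 0")
  if (any(cells$density < 0)) stop("densities must be >= 0")
  withSeed(seed, stats::rpois(nrow(cells), cells$density * cells$volume))
}
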
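# ROI selection, preprocessing and binarisation of vessel images, following
# the retinal flat-mount protocol: ROIs placed relative to the optic disc,
# inversion + contrast stretch, Phansalkar local thresholding, then size
# filtering with hole filling and optional exclusion of staining artefacts.

#' Select retinal ROIs relative to the optic disc
#'
#' Extracts square regions of interest placed at radial offsets from the
#' optic-disc centre, the offsets expressed as multiples of the optic-disc
#' diameter (the retina's internal yardstick). The default samples a
#' proximal and a distal ROI in each of the four retinal quadrants
#' (8 ROIs in total).
#'
#' @param image numeric matrix (single channel).
#' @param discCenter (row, col) optic-disc centre in micrometres.
#' @param discDiameter optic-disc diameter in micrometres.
#' @param radiusMultiples radial offsets, in multiples of \code{discDiameter}.
#' @param angles offset directions in degrees (0 = increasing row,
#'   90 = increasing column); one ROI per (radius, angle) pair.
#' @param roiSize ROI side length in pixels.
#' @param pixelSize micrometres per pixel.
#' @return list of ROIs; each is a list with \code{image} (the ROI pixels),
#'   \code{rows}, \code{cols} (index ranges into the source), \code{center}
#'   (micrometres), \code{radiusMultiple}, \code{angle} and \code{zone}
#'   ("proximal"/"distal" for two radii, otherwise the multiple).
#' @export
selectRois <- function(image, discCenter, discDiameter,
                       radiusMultiples = c(2, 4),
                       angles = c(45, 135, 225, 315),
                       roiSize = 64L, pixelSize = 1) {
  stopifnot(is.matrix(image), roiSize > 0, discDiameter > 0, pixelSize > 0)
  ctr <- discCenter / pixelSize + 1      # to pixel indices
  if (any(ctr < 1) || ctr[1] > nrow(image) || ctr[2] > ncol(image))
    stop("discCenter lies outside the image")
  zones <- if (length(radiusMultiples) == 2L) c("proximal", "distal")
           else as.character(radiusMultiples)
  half <- floor(roiSize / 2)
  rois <- list()
  for (i in seq_along(radiusMultiples)) for (a in angles) {
    off <- radiusMultiples[i] * discDiameter / pixelSize
    cpx <- round(ctr + off * c(cos(a * pi / 180), sin(a * pi / 180)))
    rows <- (cpx[1] - half):(cpx[1] + half - 1L + roiSize %% 2L)
    cols <- (cpx[2] - half):(cpx[2] + half - 1L + roiSize %% 2L)
    if (min(rows) < 1 || max(rows) > nrow(image) ||
        min(cols) < 1 || max(cols) > ncol(image))
      stop("ROI at radius multiple ", radiusMultiples[i], ", angle ", a,
           " degrees falls outside the image")
    rois[[length(rois) + 1L]] <- list(
      image = image[rows, cols, drop = FALSE], rows = rows, cols = cols,
      center = (cpx - 1) * pixelSize,
      radiusMultiple = radiusMultiples[i], angle = a, zone = zones[i])
  }
  rois
}

#' Invert and contrast-stretch an ROI
#'
#' Prepares a vessel ROI for local thresholding: intensities are inverted
#' (vessels imaged dark become bright) and linearly stretched so that the
#' 1st and 99th percentiles of the inverted image map to 0 and 1, with
#' clipping beyond. The map is monotone non-increasing in the input
#' (strictly decreasing between the stretch percentiles). A constant image
#' is returned unchanged after inversion.
#'
#' @param roi numeric matrix in \code{[0, 1]}, or an ROI list from
#'   [selectRois()].
#' @param probs the two stretch percentiles.
#' @return numeric matrix in \code{[0, 1]}.
#' @export
preprocessRoi <- function(roi, probs = c(0.01, 0.99)) {
  x <- if (is.list(roi)) roi$image else roi
  stopifnot(is.matrix(x))
  inv <- 1 - x
  q <- stats::quantile(inv, probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    rng <- range(inv)
    if (rng[2] <= rng[1]) return(inv)    # constant image: inversion only
    q <- rng
  }
  pmin(pmax((inv - q[1]) / (q[2] - q[1]), 0), 1)
}

# Reflect-pad a matrix by `r` pixels on every side (mirror including edge).
reflectPad <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  if (r >= n || r >= m) stop("padding radius exceeds image size")
  ri <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  ci <- c(rev(seq_len(r)), seq_len(m), m + 1 - seq_len(r))
  x[ri, ci, drop = FALSE]
}

# Local windowed sums via an integral image of a padded matrix.
localBoxSum <- function(xpad, r, nr, nc) {
  S <- matrix(0, nrow(xpad) + 1L, ncol(xpad) + 1L)
  S[-1, -1] <- apply(apply(xpad, 2, cumsum), 1, cumsum) |> t()
  w <- 2L * r + 1L
  ro <- seq_len(nr); co <- seq_len(nc)
  S[ro + w, co + w] - S[ro, co + w] - S[ro + w, co] + S[ro, co]
}

#' Phansalkar local adaptive thresholding
#'
#' Binarises a low-contrast stained image with the Phansalkar local
#' threshold: a pixel is foreground iff its value exceeds
#' \deqn{t = \mu \, (1 + p\,e^{-q\mu} + k(\sigma/r - 1))}
#' where \eqn{\mu} and \eqn{\sigma} are the mean and (population) standard
#' deviation over the square window of half-width \code{windowRadius}
#' centred on the pixel, computed with mirror padding at the borders. The
#' default constants k = 0.25, r = 0.5, p = 2, q = 10 follow the method's
#' original publication; the image must be normalised to \code{[0, 1]}.
#'
#' @param image numeric matrix in \code{[0, 1]}.
#' @param windowRadius window half-width in pixels (window is
#'   \code{2*windowRadius + 1} on a side).
#' @param k,r,p,q unitless Phansalkar constants.
#' @return logical matrix (TRUE = vessel/foreground), with the parameter set
#'   attached as attribute \code{params}.
#' @examples
#' img <- matrix(0.5, 20, 20)
#' all(phansalkarThreshold(img, windowRadius = 3))   # t ~ 0.382 < 0.5
#' @export
phansalkarThreshold <- function(image, windowRadius = 15L, k = 0.25,
                                r = 0.5, p = 2, q = 10) {
  stopifnot(is.matrix(image))
  if (windowRadius < 1L) stop("windowRadius must be >= 1")
  if (r <= 0) stop("r must be > 0")
  if (2L * windowRadius + 1L > min(dim(image)))
    stop("window (", 2L * windowRadius + 1L,
         " px) is larger than the image")
  if (min(image) < 0 || max(image) > 1)
    stop("image must be normalised to [0, 1]")
  nr <- nrow(image); nc <- ncol(image)
  pad <- reflectPad(image, windowRadius)
  n <- (2L * windowRadius + 1L)^2
  mu <- localBoxSum(pad, windowRadius, nr, nc) / n
  mu2 <- localBoxSum(pad^2, windowRadius, nr, nc) / n
  sd_ <- sqrt(pmax(mu2 - mu^2, 0))
  thr <- mu * (1 + p * exp(-q * mu) + k * (sd_ / r - 1))
  mask <- image > thr
  attr(mask, "params") <- list(windowRadius = windowRadius, k = k, r = r,
                               p = p, q = q)
  mask
}

#' Size-filter a binary mask, fill small holes, apply exclusion zones
#'
#' Cleans a thresholded vessel mask: removes 8-connected foreground
#' components smaller than \code{minObjectArea}, fills interior background
#' holes smaller than \code{fillHoleArea} (holes touching the image border
#' or an exclusion zone are never filled), and clears all pixels under the
#' exclusion mask (staining abnormalities). The operation is idempotent.
#'
#' @param mask logical or 0/1 matrix.
#' @param minObjectArea minimum object area to keep, in square micrometres.
#' @param fillHoleArea holes strictly smaller than this (um^2) are filled.
#' @param exclusionMask optional logical matrix of pixels to clear.
#' @param pixelSize micrometres per pixel.
#' @return logical matrix.
#' @export
filterMask <- function(mask, minObjectArea = 0, fillHoleArea = 0,
                       exclusionMask = NULL, pixelSize = 1) {
  stopifnot(minObjectArea >= 0, fillHoleArea >= 0, pixelSize > 0)
  M <- mask > 0
  if (!is.null(exclusionMask)) {
    stopifnot(identical(dim(exclusionMask), dim(M)))
    M[exclusionMask > 0] <- FALSE
  }
  pxArea <- pixelSize^2
  if (minObjectArea > 0 && any(M)) {
    lab <- labelComponents(M, connectivity = 8)
    sz <- tabulate(lab)
    drop <- which(sz * pxArea < minObjectArea)
    if (length(drop)) M[lab %in% drop] <- FALSE
  }
  if (fillHoleArea > 0 && any(M)) {
    # holes: 4-connected background components not touching the border
    bg <- labelComponents(!M, connectivity = 4)
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    sz <- tabulate(bg)
    excl <- if (is.null(exclusionMask)) integer(0)
            else unique(bg[exclusionMask > 0])
    fill <- setdiff(which(sz * pxArea < fillHoleArea),
                    c(border[border > 0], excl[excl > 0]))
    if (length(fill)) M[bg %in% fill] <- TRUE
  }
  M
}
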
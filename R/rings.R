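# Perivascular concentric-ring quantification: ring assignment with the
# no-double-counting rule, per-image signal thresholding, ring signal
# densities adjusted for ring area and section depth, marker coverage within
# vessel outlines, and annulus feature fractions.

#' Assign perivascular ring labels around vessels
#'
#' Generates \code{nRings} concentric rings of width \code{ringWidth}
#' micrometres around each vessel and assigns every non-vessel pixel to at
#' most one (vessel, ring) pair so that no tissue area is analysed twice.
#' For a pixel at Euclidean distance \eqn{d_v} from vessel \eqn{v}'s mask,
#' the candidate ring index is \eqn{\lceil d_v / w \rceil}; the pixel is
#' assigned to the vessel with the smallest candidate index not exceeding
#' \code{nRings}, and a tie between vessels (the generalisation of
#' subtracting an outermost ring part that overlaps another vessel's
#' innermost ring) leaves the pixel unassigned.
#'
#' @param vesselMasks list of pairwise non-overlapping logical matrices,
#'   one per vessel (overlap is an error).
#' @param ringWidth ring width in micrometres (paper protocol: 10).
#' @param nRings number of rings per vessel.
#' @param pixelSize micrometres per pixel.
#' @return a \linkS4class{RingAssignment}.
#' @examples
#' v <- diskMask(c(64, 64), c(31, 31), 6)
#' ra <- makeRings(list(v), ringWidth = 10, nRings = 1)
#' @export
makeRings <- function(vesselMasks, ringWidth = 10, nRings = 1L,
                      pixelSize = 1) {
  stopifnot(is.list(vesselMasks), length(vesselMasks) >= 1)
  if (ringWidth <= 0) stop("ringWidth must be > 0")
  if (nRings < 1) stop("nRings must be >= 1")
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  dims <- dim(vesselMasks[[1]])
  masks <- lapply(vesselMasks, function(m) {
    stopifnot(identical(dim(m), dims)); m > 0
  })
  overlap <- Reduce(`+`, lapply(masks, `*`, 1))
  if (any(overlap > 1)) stop("vessel masks overlap")
  anyVessel <- overlap > 0
  nV <- length(masks)
  bestIdx <- matrix(Inf, dims[1], dims[2])     # smallest candidate index
  bestVessel <- matrix(0L, dims[1], dims[2])
  tied <- matrix(FALSE, dims[1], dims[2])
  for (v in seq_len(nV)) {
    d <- distanceToMask(masks[[v]]) * pixelSize
    k <- ceiling(d / ringWidth)
    k[masks[[v]]] <- Inf                       # inside the vessel itself
    k[k > nRings] <- Inf
    better <- k < bestIdx
    equal <- is.finite(k) & k == bestIdx
    tied[equal] <- TRUE
    tied[better] <- FALSE
    bestIdx[better] <- k[better]
    bestVessel[better] <- v
  }
  vesselId <- bestVessel
  vesselId[tied | !is.finite(bestIdx)] <- 0L
  ringIndex <- matrix(0L, dims[1], dims[2])
  ok <- vesselId > 0L
  ringIndex[ok] <- as.integer(bestIdx[ok])
  vesselId[anyVessel] <- NA_integer_
  ringIndex[anyVessel] <- NA_integer_
  new("RingAssignment", vesselId = vesselId, ringIndex = ringIndex,
      ringWidth = as.numeric(ringWidth), nRings = as.integer(nRings),
      pixelSize = as.numeric(pixelSize))
}

#' Threshold a channel into a positive-pixel mask
#'
#' Per-image intensity thresholding to separate genuine marker signal from
#' background staining. \code{"otsu"} (default) maximises the inter-class
#' variance per image; \code{"fixed"} applies the given cutoff;
#' \code{"percentile"} keeps the brightest \code{100 - value} percent.
#' A constant image under Otsu falls back to a fixed 0.5 cutoff with a
#' warning.
#'
#' @param image numeric matrix in \code{[0, 1]}.
#' @param method "otsu", "fixed" or "percentile".
#' @param value cutoff for "fixed" (intensity) or "percentile" (0-100).
#' @return logical mask of suprathreshold pixels, with the applied
#'   threshold attached as attribute \code{threshold}.
#' @export
thresholdChannel <- function(image, method = c("otsu", "fixed", "percentile"),
                             value = 0.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  thr <- switch(method,
    otsu = {
      if (max(image) - min(image) < .Machine$double.eps^0.5) {
        warning("constant image: Otsu undefined, falling back to fixed 0.5")
        0.5
      } else as.numeric(EBImage::otsu(EBImage::Image(image),
                                      range = c(0, 1), levels = 256L))
    },
    fixed = value,
    percentile = {
      stopifnot(value >= 0, value <= 100)
      stats::quantile(image, value / 100, names = FALSE)
    })
  mask <- image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Per-ring signal densities adjusted for area and depth
#'
#' Counts positive pixels in every (vessel, ring) label of a
#' \linkS4class{RingAssignment} and adjusts for ring area and tissue-section
#' depth: \code{density = count / (area * depth)} (positives per um^2 of
#' ring per um of depth). \code{normalized_density} divides by the
#' image-wide positive density over all non-vessel pixels, making rings
#' comparable across images and experiments (it is exactly 1 everywhere
#' when signal is uniform). Zero-area rings are reported with
#' \code{undefined = TRUE}.
#'
#' @param assignment a \linkS4class{RingAssignment} from [makeRings()].
#' @param positiveMask logical matrix from [thresholdChannel()].
#' @param depth section thickness in micrometres (1 for per-area densities).
#' @return data.frame with one row per (vessel, ring): \code{vessel_id},
#'   \code{ring_index}, \code{positive_count}, \code{area} (um^2),
#'   \code{depth}, \code{density}, \code{normalized_density},
#'   \code{undefined}.
#' @export
ringDensity <- function(assignment, positiveMask, depth = 1) {
  stopifnot(is(assignment, "RingAssignment"),
            identical(dim(positiveMask), dim(assignment@vesselId)))
  if (depth <= 0) stop("depth must be > 0")
  ps <- assignment@pixelSize
  pos <- positiveMask > 0
  nonVessel <- !is.na(assignment@vesselId)
  globalDensity <- sum(pos & nonVessel) / (sum(nonVessel) * ps^2 * depth)
  out <- expand.grid(vessel_id = seq_len(max(assignment@vesselId,
                                             na.rm = TRUE)),
                     ring_index = seq_len(assignment@nRings))
  out <- out[order(out$vessel_id, out$ring_index), , drop = FALSE]
  rownames(out) <- NULL
  lab <- interaction(assignment@vesselId, assignment@ringIndex, drop = FALSE)
  n <- nrow(out)
  out$positive_count <- out$area <- numeric(n)
  for (i in seq_len(n)) {
    sel <- !is.na(assignment@vesselId) &
      assignment@vesselId == out$vessel_id[i] &
      assignment@ringIndex == out$ring_index[i]
    out$positive_count[i] <- sum(pos & sel)
    out$area[i] <- sum(sel) * ps^2
  }
  out$depth <- depth
  out$undefined <- out$area == 0
  out$density <- ifelse(out$undefined, NA_real_,
                        out$positive_count / (out$area * depth))
  out$normalized_density <- ifelse(out$undefined | globalDensity == 0,
                                   NA_real_, out$density / globalDensity)
  out
}

#' Marker coverage within a vessel outline
#'
#' Fraction of the vessel outline's pixels that are positive for a second
#' marker (pericyte or astrocyte-endfoot coverage).
#'
#' @param vesselMask logical matrix (non-empty).
#' @param markerMask logical matrix of the same dimension.
#' @return fraction in \code{[0, 1]}.
#' @export
coverageWithin <- function(vesselMask, markerMask) {
  stopifnot(identical(dim(vesselMask), dim(markerMask)))
  v <- vesselMask > 0
  if (!any(v)) stop("vessel mask is empty")
  sum(markerMask > 0 & v) / sum(v)
}

#' Per-animal mean coverage, image-first averaging
#'
#' Averages per-vessel coverage fractions within each image, then averages
#' the image means within each animal (the protocol's five-images-per-animal
#' summary). With unbalanced vessel counts this differs from the pooled
#' per-vessel mean.
#'
#' @param coverage data.frame with columns \code{animal}, \code{image},
#'   \code{coverage}.
#' @return data.frame with one row per animal: \code{animal},
#'   \code{mean_coverage}, \code{n_images}, \code{n_vessels}.
#' @export
summarizeCoverage <- function(coverage) {
  stopifnot(all(c("animal", "image", "coverage") %in% names(coverage)))
  byImage <- stats::aggregate(coverage ~ animal + image, coverage, mean)
  byAnimal <- stats::aggregate(coverage ~ animal, byImage, mean)
  counts <- stats::aggregate(coverage ~ animal, coverage, length)
  data.frame(animal = byAnimal$animal,
             mean_coverage = byAnimal$coverage,
             n_images = stats::aggregate(image ~ animal, byImage,
                                         length)$image,
             n_vessels = counts$coverage)
}

#' Percentage of an annulus covered by a feature
#'
#' Feature area as a percentage of annulus area, e.g. disrupted tissue
#' (vacuoles and myelin debris) within a 10 um perivascular ring, or
#' myelinated-axon area within a 5 um ring.
#'
#' @param annulusMask logical matrix (non-empty).
#' @param featureMask logical matrix of the same dimension.
#' @return percentage in \code{[0, 100]}.
#' @export
annulusFraction <- function(annulusMask, featureMask) {
  stopifnot(identical(dim(annulusMask), dim(featureMask)))
  a <- annulusMask > 0
  if (!any(a)) stop("annulus mask is empty")
  100 * sum(featureMask > 0 & a) / sum(a)
}
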
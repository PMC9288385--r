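#' @import methods
NULL

#' MultiChannelImage: calibrated multi-channel microscopy image
#'
#' Container for a set of equally sized 2-D intensity matrices, one per
#' fluorescence channel, together with the spatial calibration needed by all
#' downstream quantification: the pixel size (micrometres per pixel) and the
#' physical section depth (micrometres) of the imaged tissue slice.
#'
#' Pixel \code{[i, j]} has its centre at physical position
#' \code{((i - 1) * pixelSize, (j - 1) * pixelSize)} micrometres; all
#' functions in the package use this convention.
#'
#' @slot channels named list of numeric matrices, all of identical dimension,
#'   intensities in \code{[0, 1]}.
#' @slot pixelSize micrometres per pixel (> 0).
#' @slot depth section thickness in micrometres (> 0).
#'
#' @seealso [generateSectionImage()], [generateTracerImage()],
#'   [sampleProfile()], [writeMultiChannelTiff()]
#' @exportClass MultiChannelImage
setClass("MultiChannelImage",
  representation(channels = "list", pixelSize = "numeric", depth = "numeric"),
  prototype(channels = list(), pixelSize = 1, depth = 1))

setValidity("MultiChannelImage", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) > 0L) {
    if (is.null(names(ch)) || anyDuplicated(names(ch)) || any(names(ch) == ""))
      msg <- c(msg, "channels must be a uniquely named list")
    if (!all(vapply(ch, is.matrix, logical(1))))
      msg <- c(msg, "all channels must be matrices")
    dims <- vapply(ch, dim, integer(2))
    if (length(ch) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all channels must share the same dimensions")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@depth) != 1L || !is.finite(object@depth) || object@depth <= 0)
    msg <- c(msg, "depth must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiChannelImage
#'
#' @param channels named list of numeric matrices (one per channel).
#' @param pixelSize micrometres per pixel.
#' @param depth section thickness in micrometres.
#' @return a [MultiChannelImage-class] object.
#' @examples
#' img <- MultiChannelImage(list(dapi = matrix(0, 8, 8)), pixelSize = 0.5)
#' channelNames(img)
#' @export
MultiChannelImage <- function(channels, pixelSize = 1, depth = 1) {
  new("MultiChannelImage", channels = channels,
      pixelSize = as.numeric(pixelSize), depth = as.numeric(depth))
}

#' Skeleton: one-pixel-wide vessel centreline with local radii
#'
#' Result of [skeletonize()]. Holds the skeleton pixel coordinates together
#' with the local vessel radius at each skeleton pixel, defined as the exact
#' Euclidean distance to the nearest background pixel ("the distance erased"
#' during skeletonisation), calibrated to micrometres.
#'
#' @slot coords integer matrix (n x 2) of (row, col) skeleton pixel indices,
#'   1-based.
#' @slot radius numeric vector, micrometres, one value per skeleton pixel.
#' @slot pixelSize micrometres per pixel.
#' @slot maskDim dimensions of the source mask.
#' @exportClass Skeleton
setClass("Skeleton",
  representation(coords = "matrix", radius = "numeric",
                 pixelSize = "numeric", maskDim = "integer"))

setValidity("Skeleton", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns (row, col)")
  if (nrow(object@coords) != length(object@radius))
    msg <- c(msg, "radius must have one entry per skeleton pixel")
  if (length(object@radius) && any(object@radius <= 0))
    msg <- c(msg, "all radii must be positive")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' SkelGraph: graph of skeleton branch/end nodes and path edges
#'
#' Result of [buildGraph()]. Nodes are skeleton end pixels (degree 1) and
#' merged clusters of branch pixels (degree > 2); edges are the simple pixel
#' paths between them, each carrying its arc length (path length along the
#' pixels, micrometres) and chord length (straight node-to-node Euclidean
#' distance, micrometres). Tortuosity of an edge is arc/chord
#' (see [edgeTortuosity()]).
#'
#' @slot nodes data.frame with columns \code{id}, \code{row}, \code{col}
#'   (1-based pixel coordinates, possibly fractional for merged clusters),
#'   \code{kind} ("branch", "end" or "isolated") and \code{degree}.
#' @slot edges data.frame with columns \code{id}, \code{from}, \code{to},
#'   \code{arc}, \code{chord} (micrometres) and \code{npix}.
#' @slot paths list of integer matrices, the ordered (row, col) pixel path of
#'   each edge.
#' @slot pixelSize micrometres per pixel.
#' @exportClass SkelGraph
setClass("SkelGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 paths = "list", pixelSize = "numeric"))

setValidity("SkelGraph", function(object) {
  msg <- character()
  if (nrow(object@edges) != length(object@paths))
    msg <- c(msg, "one pixel path per edge required")
  if (nrow(object@edges) &&
      any(object@edges$arc + 1e-9 < object@edges$chord))
    msg <- c(msg, "arc length must be >= chord length")
  if (length(msg)) msg else TRUE
})

#' RingAssignment: perivascular concentric-ring label map
#'
#' Result of [makeRings()]. Every non-vessel pixel is assigned to at most one
#' (vessel, ring) pair under the uniqueness rule (smallest candidate ring
#' index wins; ties between vessels leave the pixel unassigned), so no tissue
#' area is ever analysed twice.
#'
#' @slot vesselId integer matrix; 0 where unassigned, \code{NA} inside a
#'   vessel, otherwise the owning vessel's id.
#' @slot ringIndex integer matrix; ring number (1 = innermost) where assigned,
#'   0 otherwise, \code{NA} inside vessels.
#' @slot ringWidth ring width in micrometres.
#' @slot nRings number of concentric rings per vessel.
#' @slot pixelSize micrometres per pixel.
#' @exportClass RingAssignment
setClass("RingAssignment",
  representation(vesselId = "matrix", ringIndex = "matrix",
                 ringWidth = "numeric", nRings = "integer",
                 pixelSize = "numeric"))

setValidity("RingAssignment", function(object) {
  msg <- character()
  if (!identical(dim(object@vesselId), dim(object@ringIndex)))
    msg <- c(msg, "vesselId and ringIndex must have identical dimensions")
  if (object@ringWidth <= 0) msg <- c(msg, "ringWidth must be positive")
  if (object@nRings < 1L) msg <- c(msg, "nRings must be >= 1")
  if (length(msg)) msg else TRUE
})

#' LineProfile: intensities sampled along a line across a vessel
#'
#' Result of [sampleProfile()]. Intensities of every channel of a
#' [MultiChannelImage-class] interpolated bilinearly at evenly spaced
#' positions along a straight sampling line (drawn perpendicular to a vessel
#' wall in the tracer assay).
#'
#' @slot positions numeric vector of distances along the line (micrometres,
#'   strictly increasing, starting at 0).
#' @slot intensities numeric matrix, one column per channel (named).
#' @slot start,end numeric (row, col) endpoints in micrometres.
#' @exportClass LineProfile
setClass("LineProfile",
  representation(positions = "numeric", intensities = "matrix",
                 start = "numeric", end = "numeric"))

setValidity("LineProfile", function(object) {
  msg <- character()
  if (length(object@positions) != nrow(object@intensities))
    msg <- c(msg, "positions and intensity rows must match")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (is.null(colnames(object@intensities)))
    msg <- c(msg, "intensity columns must be named by channel")
  if (length(msg)) msg else TRUE
})
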
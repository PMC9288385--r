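#' Pixel size accessor
#'
#' Micrometres per pixel of a calibrated image-derived object.
#' @param object a \linkS4class{MultiChannelImage}, \linkS4class{Skeleton},
#'   \linkS4class{SkelGraph} or \linkS4class{RingAssignment}.
#' @return a single positive numeric, micrometres per pixel.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "MultiChannelImage", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Skeleton", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "SkelGraph", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "RingAssignment", function(object) object@pixelSize)

#' Channel names of a MultiChannelImage
#' @param object a \linkS4class{MultiChannelImage}.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname channelNames
#' @export
setMethod("channelNames", "MultiChannelImage",
          function(object) names(object@channels))

#' Extract one channel as a matrix
#' @param object a \linkS4class{MultiChannelImage}.
#' @param name channel name.
#' @return numeric matrix of intensities.
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))
#' @rdname getChannel
#' @export
setMethod("getChannel", "MultiChannelImage", function(object, name) {
  if (!name %in% names(object@channels))
    stop("no channel named '", name, "'")
  object@channels[[name]]
})

#' Section depth accessor
#' @param object a \linkS4class{MultiChannelImage}.
#' @return section thickness in micrometres.
#' @export
setGeneric("sectionDepth", function(object) standardGeneric("sectionDepth"))
#' @rdname sectionDepth
#' @export
setMethod("sectionDepth", "MultiChannelImage", function(object) object@depth)

#' Skeleton pixel coordinates
#' @param object a \linkS4class{Skeleton}.
#' @return integer matrix (n x 2) of 1-based (row, col) indices.
#' @export
setGeneric("skeletonCoords", function(object) standardGeneric("skeletonCoords"))
#' @rdname skeletonCoords
#' @export
setMethod("skeletonCoords", "Skeleton", function(object) object@coords)

#' Per-pixel skeleton radii
#' @param object a \linkS4class{Skeleton}.
#' @return numeric vector of radii in micrometres (distance to the nearest
#'   background pixel at each skeleton pixel).
#' @export
setGeneric("skeletonRadius", function(object) standardGeneric("skeletonRadius"))
#' @rdname skeletonRadius
#' @export
setMethod("skeletonRadius", "Skeleton", function(object) object@radius)

#' Nodes of a skeleton graph
#' @param object a \linkS4class{SkelGraph}.
#' @return data.frame of nodes (id, row, col, kind, degree).
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))
#' @rdname graphNodes
#' @export
setMethod("graphNodes", "SkelGraph", function(object) object@nodes)

#' Edges of a skeleton graph
#' @param object a \linkS4class{SkelGraph}.
#' @return data.frame of edges (id, from, to, arc, chord, npix), lengths in
#'   micrometres.
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname graphEdges
#' @export
setMethod("graphEdges", "SkelGraph", function(object) object@edges)

#' Ring label maps
#'
#' @param object a \linkS4class{RingAssignment}.
#' @return \code{ringLabels}: list with integer matrices \code{vesselId} and
#'   \code{ringIndex}; \code{ringAreas}: data.frame with one row per
#'   (vessel, ring) giving its pixel count and area in square micrometres.
#' @export
setGeneric("ringLabels", function(object) standardGeneric("ringLabels"))
#' @rdname ringLabels
#' @export
setMethod("ringLabels", "RingAssignment", function(object)
  list(vesselId = object@vesselId, ringIndex = object@ringIndex))

#' @rdname ringLabels
#' @export
setGeneric("ringAreas", function(object) standardGeneric("ringAreas"))
#' @rdname ringLabels
#' @export
setMethod("ringAreas", "RingAssignment", function(object) {
  ok <- !is.na(object@vesselId) & object@vesselId > 0L
  if (!any(ok))
    return(data.frame(vessel_id = integer(), ring_index = integer(),
                      n_pixels = integer(), area = numeric()))
  tab <- as.data.frame(table(vessel_id = object@vesselId[ok],
                             ring_index = object@ringIndex[ok]),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  data.frame(vessel_id = as.integer(tab$vessel_id),
             ring_index = as.integer(tab$ring_index),
             n_pixels = as.integer(tab$Freq),
             area = tab$Freq * object@pixelSize^2)
})

#' Positions and intensities of a line profile
#' @param object a \linkS4class{LineProfile}.
#' @return \code{profilePositions}: numeric vector of positions along the
#'   line (micrometres); \code{profileIntensities}: matrix with one named
#'   column per channel.
#' @export
setGeneric("profilePositions",
           function(object) standardGeneric("profilePositions"))
#' @rdname profilePositions
#' @export
setMethod("profilePositions", "LineProfile", function(object) object@positions)
#' @rdname profilePositions
#' @export
setGeneric("profileIntensities",
           function(object) standardGeneric("profileIntensities"))
#' @rdname profilePositions
#' @export
setMethod("profileIntensities", "LineProfile",
          function(object) object@intensities)

setMethod("show", "MultiChannelImage", function(object) {
  d <- if (length(object@channels)) dim(object@channels[[1]]) else c(0L, 0L)
  cat("MultiChannelImage:", d[1], "x", d[2], "px,",
      length(object@channels), "channel(s)",
      if (length(object@channels))
        paste0("[", paste(names(object@channels), collapse = ", "), "]"),
      "\n  pixel size:", object@pixelSize, "um/px; depth:",
      object@depth, "um\n")
})

setMethod("show", "Skeleton", function(object) {
  cat("Skeleton:", nrow(object@coords), "pixels from a",
      paste(object@maskDim, collapse = " x "), "mask\n",
      " pixel size:", object@pixelSize, "um/px; radius range:",
      if (length(object@radius))
        paste(signif(range(object@radius), 4), collapse = " - ")
      else "-", "um\n")
})

setMethod("show", "SkelGraph", function(object) {
  k <- table(factor(object@nodes$kind, c("branch", "end", "isolated")))
  cat("SkelGraph:", nrow(object@nodes), "nodes (",
      k[["branch"]], "branch,", k[["end"]], "end ),",
      nrow(object@edges), "edges\n")
})

setMethod("show", "RingAssignment", function(object) {
  cat("RingAssignment:", paste(dim(object@vesselId), collapse = " x "),
      "px;", object@nRings, "ring(s) of", object@ringWidth, "um;",
      sum(object@vesselId > 0L, na.rm = TRUE), "assigned pixels\n")
})

setMethod("show", "LineProfile", function(object) {
  cat("LineProfile:", length(object@positions), "samples over",
      signif(max(object@positions), 4), "um; channels:",
      paste(colnames(object@intensities), collapse = ", "), "\n")
})
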
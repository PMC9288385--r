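# Blood-brain-barrier tracer analysis: intensities sampled along lines drawn
# perpendicular to a vessel wall, vessel extent delineated from the lectin
# channel, and mean extravascular tracer intensity per channel.

#' Sample a multi-channel intensity profile along a line
#'
#' Bilinearly interpolates every channel of a
#' \linkS4class{MultiChannelImage} at \code{nSamples} evenly spaced points
#' between two endpoints (micrometre coordinates). Reversing the endpoints
#' reverses the profile exactly.
#'
#' @param image a \linkS4class{MultiChannelImage}.
#' @param start,end (row, col) endpoints in micrometres, inside the image.
#' @param nSamples number of samples (>= 2).
#' @return a \linkS4class{LineProfile}.
#' @export
sampleProfile <- function(image, start, end, nSamples = 200L) {
  stopifnot(is(image, "MultiChannelImage"), nSamples >= 2)
  ps <- image@pixelSize
  d <- dim(image@channels[[1]])
  lim <- (d - 1) * ps
  for (pt in list(start, end))
    if (any(pt < 0) || pt[1] > lim[1] || pt[2] > lim[2])
      stop("line endpoint (", pt[1], ", ", pt[2],
           ") um lies outside the image")
  f <- seq(0, 1, length.out = nSamples)
  rr <- (start[1] + f * (end[1] - start[1])) / ps + 1
  cc <- (start[2] + f * (end[2] - start[2])) / ps + 1
  intens <- vapply(image@channels, function(ch) bilinearAt(ch, rr, cc),
                   numeric(nSamples))
  if (is.null(dim(intens))) intens <- matrix(intens, nrow = nSamples)
  colnames(intens) <- names(image@channels)
  lineLen <- sqrt(sum((end - start)^2))
  new("LineProfile", positions = f * lineLen, intensities = intens,
      start = as.numeric(start), end = as.numeric(end))
}

#' Delineate the vessel extent from the lectin profile
#'
#' The wall-bound lectin channel delineates the vessel on a perpendicular
#' line profile: the background is estimated as the mean of the outer
#' \code{outerFraction} of samples at both line ends, and the vessel
#' boundaries are the outermost half-maximum crossings -- the positions,
#' found by walking outwards from the lectin peak and linearly interpolating
#' between samples, where the profile falls to
#' \code{background + 0.5 * (max - background)}. Profiles with no peak above
#' background (prominence below \code{minProminence}) are flagged and
#' excluded from downstream means.
#'
#' @param profile a \linkS4class{LineProfile}.
#' @param channel name of the lectin channel.
#' @param outerFraction fraction of samples at each line end used for the
#'   background estimate.
#' @param minProminence minimum (max - background) for a usable peak.
#' @return list with \code{inner}, \code{outer} (boundary positions,
#'   micrometres), \code{flagged} (logical) and \code{background}.
#' @export
findVesselExtent <- function(profile, channel = "lectin",
                             outerFraction = 0.1, minProminence = 0.1) {
  stopifnot(is(profile, "LineProfile"))
  y <- profile@intensities[, channel]
  x <- profile@positions
  n <- length(y)
  k <- max(1L, floor(outerFraction * n))
  bg <- mean(c(y[seq_len(k)], y[n + 1 - seq_len(k)]))
  pk <- which.max(y)
  if (y[pk] - bg < minProminence)
    return(list(inner = NA_real_, outer = NA_real_, flagged = TRUE,
                background = bg))
  half <- bg + 0.5 * (y[pk] - bg)
  crossOut <- function(idx) {           # walk outwards from the peak
    dir <- if (idx < pk) -1L else 1L
    i <- pk
    while (i + dir >= 1 && i + dir <= n && y[i + dir] >= half) i <- i + dir
    j <- i + dir
    if (j < 1 || j > n) return(x[i])
    x[i] + (x[j] - x[i]) * (y[i] - half) / (y[i] - y[j])
  }
  list(inner = crossOut(1L), outer = crossOut(n), flagged = FALSE,
       background = bg)
}

#' Mean extravascular tracer intensity
#'
#' Averages each non-lectin channel over the profile samples lying outside
#' the vessel boundaries by more than \code{margin} micrometres (the margin
#' keeps wall bleed-through out of the extravascular estimate).
#'
#' @param profile a \linkS4class{LineProfile}.
#' @param extent boundary list from [findVesselExtent()].
#' @param margin extra distance beyond each boundary, micrometres.
#' @param background known per-channel acquisition background to subtract
#'   (single number or named by channel; 0 reports raw means).
#' @param lectinChannel channel to exclude from the means.
#' @return named numeric vector of per-channel extravascular means.
#' @export
extravascularMean <- function(profile, extent, margin = 1, background = 0,
                              lectinChannel = "lectin") {
  stopifnot(is(profile, "LineProfile"))
  if (isTRUE(extent$flagged) || is.na(extent$inner))
    stop("vessel extent is flagged/undefined; profile excluded")
  x <- profile@positions
  outside <- x < extent$inner - margin | x > extent$outer + margin
  if (!any(outside)) stop("no profile samples outside the vessel")
  chans <- setdiff(colnames(profile@intensities), lectinChannel)
  bg <- if (length(background) == 1L && is.null(names(background)))
    stats::setNames(rep(background, length(chans)), chans)
  else background
  vapply(chans, function(ch)
    mean(profile@intensities[outside, ch]) - bg[[ch]], numeric(1))
}

#' Per-animal tracer summary with a minimum-vessel rule
#'
#' Averages per-vessel extravascular means within each animal; animals with
#' fewer than \code{minVessels} analysed vessels are flagged as insufficient
#' (the protocol requires at least 7 vessels per animal).
#'
#' @param records data.frame with a column \code{animal} plus one numeric
#'   column per tracer channel.
#' @param minVessels minimum vessels per animal.
#' @return data.frame with one row per animal: per-channel means,
#'   \code{n_vessels} and \code{insufficient}.
#' @export
animalSummary <- function(records, minVessels = 7L) {
  stopifnot("animal" %in% names(records))
  chans <- setdiff(names(records), c("animal", "vessel_id"))
  chans <- chans[vapply(records[chans], is.numeric, logical(1))]
  animals <- unique(records$animal)
  out <- data.frame(animal = animals)
  for (ch in chans)
    out[[ch]] <- vapply(animals, function(a)
      mean(records[[ch]][records$animal == a]), numeric(1))
  out$n_vessels <- vapply(animals, function(a)
    sum(records$animal == a), numeric(1))
  out$insufficient <- out$n_vessels < minVessels
  out
}
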
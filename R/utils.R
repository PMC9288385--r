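# Shared internal helpers: seeded evaluation, binary-matrix primitives,
# path-length estimation, and calibrated file I/O.

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shiftMat <- function(M, dr, dc) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(FALSE, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(m, m + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

.NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dc = c(-1,  0,  1, -1, 1, -1, 0, 1))
.NB4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))

#' Label connected components of a binary mask
#'
#' Connected-component labelling with selectable connectivity. Used for
#' object-size filtering and hole filling; 8-connectivity matches the
#' skeleton connectivity used downstream.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same dimension; 0 for background, 1..k for
#'   the k components.
#' @examples
#' m <- matrix(0, 5, 5); m[1, 1] <- 1; m[2, 2] <- 1; m[5, 5] <- 1
#' max(labelComponents(m))        # 2: diagonal pixels touch under 8-conn
#' max(labelComponents(m, 4))     # 3
#' @export
labelComponents <- function(mask, connectivity = 8) {
  M <- mask > 0
  idx <- which(M)
  lab <- matrix(0L, nrow(M), ncol(M))
  if (!length(idx)) return(lab)
  nb <- if (connectivity == 8) .NB8 else if (connectivity == 4) .NB4
        else stop("connectivity must be 4 or 8")
  n <- nrow(M)
  id <- matrix(0L, nrow(M), ncol(M))
  id[idx] <- seq_along(idx)
  rc <- arrayInd(idx, dim(M))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(nb))) {
    r2 <- rc[, 1] + nb[k, 1]; c2 <- rc[, 2] + nb[k, 2]
    ok <- r2 >= 1 & r2 <= n & c2 >= 1 & c2 <= ncol(M)
    ok[ok] <- M[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      from <- c(from, id[idx[ok]])
      to <- c(to, id[cbind(r2[ok], c2[ok])])
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp[seq_along(idx)])
  lab
}

# Arc length of an ordered pixel path (n x 2 of row, col indices) in pixels.
# Raw 8-chain step sums overestimate smooth curve length by up to ~8%
# depending on orientation; summing chords of the path resampled every
# `spacing` pixels keeps the error within ~1.5% on digitised lines and arcs.
pathArcLength <- function(coords, spacing = 5L) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  if (n <= spacing + 1L)
    return(sum(sqrt(rowSums(diff(coords)^2))))
  idx <- unique(c(seq(1L, n, by = spacing), n))
  p <- coords[idx, , drop = FALSE]
  sum(sqrt(rowSums(diff(p)^2)))
}

# Bilinear interpolation of matrix `img` at fractional (row, col) positions.
bilinearAt <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(pmax(floor(r), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(c), 1L), nc - 1L)
  fr <- pmin(pmax(r - r0, 0), 1)
  fc <- pmin(pmax(c - c0, 0), 1)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# Exact Euclidean distance (in pixels) from every pixel to the nearest TRUE
# pixel of `target`. Pixels outside the image are ignored.
distanceToMask <- function(target) {
  if (!any(target > 0)) return(matrix(Inf, nrow(target), ncol(target)))
  d <- EBImage::distmap(1 - (target > 0))
  matrix(as.numeric(d), nrow(target), ncol(target))
}

#' Write and read multi-channel TIFF images
#'
#' One TIFF page per channel; channel names, pixel size and depth travel in a
#' JSON sidecar written next to the image (same path with extension
#' \code{.json}).
#'
#' @param object a \linkS4class{MultiChannelImage}.
#' @param path TIFF file path.
#' @return \code{writeMultiChannelTiff}: the path, invisibly;
#'   \code{readMultiChannelTiff}: a \linkS4class{MultiChannelImage}.
#' @export
writeMultiChannelTiff <- function(object, path) {
  stopifnot(is(object, "MultiChannelImage"))
  pages <- lapply(object@channels, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = names(object@channels),
               pixel_size = object@pixelSize, depth = object@depth)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMultiChannelTiff
#' @export
readMultiChannelTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stop("missing calibration sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  names(pages) <- meta$channels
  MultiChannelImage(pages, pixelSize = meta$pixel_size, depth = meta$depth)
}

#' Serialise planted ground truth as JSON
#'
#' Ground truth generated alongside synthetic images (segment polylines,
#' branch points, ring profiles, leak levels, particle densities) is stored
#' as structured text so fixtures stay language-neutral.
#'
#' @param truth a ground-truth list as returned by the generators.
#' @param path JSON file path.
#' @return \code{writeGroundTruth}: the path, invisibly;
#'   \code{readGroundTruth}: the truth list.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
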
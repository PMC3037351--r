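#' @import methods
NULL

#' PyramidPlan: geometry of a tiled slide
#'
#' A \code{PyramidPlan} describes how a whole-slide raster is cut into a
#' pyramid of fixed-size tiles in the XYZ (slippy-map) convention: zoom level
#' \code{z = 0} is the single-tile overview and \code{z = zMax} holds the
#' image at native resolution. Level \code{z} has dimensions
#' \code{ceiling(dim / 2^(zMax - z))} and is cut into
#' \code{ceiling(levelDim / tileSize)} tiles per axis.
#'
#' @slot sourceWidth,sourceHeight source image dimensions in pixels.
#' @slot tileSize tile edge length in pixels (256 for web-map viewers).
#' @slot zMax zoom level of the full-resolution layer.
#' @slot levels \code{data.frame} with one row per level: \code{z},
#'   \code{width}, \code{height} (level pixel dims), \code{tilesX},
#'   \code{tilesY}.
#' @seealso [planPyramid()], [tileCount()], [tileImage()]
#' @export
setClass("PyramidPlan",
  representation(
    sourceWidth  = "integer",
    sourceHeight = "integer",
    tileSize     = "integer",
    zMax         = "integer",
    levels       = "data.frame"
  )
)

setValidity("PyramidPlan", function(object) {
  w <- object@sourceWidth; h <- object@sourceHeight; ts <- object@tileSize
  lv <- object@levels
  if (length(w) != 1L || length(h) != 1L || length(ts) != 1L ||
      is.na(w) || is.na(h) || is.na(ts) || w < 1L || h < 1L || ts < 1L)
    return("sourceWidth, sourceHeight and tileSize must be positive scalars")
  zm <- object@zMax
  # smallest z with max(w, h) <= ts * 2^z
  zExpect <- 0L
  while (max(w, h) > ts * 2^zExpect) zExpect <- zExpect + 1L
  if (zm != zExpect)
    return(sprintf("zMax is %d but must be %d for a %dx%d image with tile size %d",
                   zm, zExpect, w, h, ts))
  if (!identical(lv$z, 0:zm))
    return("levels must be contiguous from z = 0 to z = zMax")
  for (i in seq_len(nrow(lv))) {
    sc <- 2^(zm - lv$z[i])
    if (lv$width[i]  != as.integer(ceiling(w / sc)) ||
        lv$height[i] != as.integer(ceiling(h / sc)))
      return(sprintf("level z=%d has wrong pixel dimensions", lv$z[i]))
    if (lv$tilesX[i] != as.integer(ceiling(lv$width[i]  / ts)) ||
        lv$tilesY[i] != as.integer(ceiling(lv$height[i] / ts)))
      return(sprintf("level z=%d has wrong tile grid", lv$z[i]))
  }
  if (lv$tilesX[1] != 1L || lv$tilesY[1] != 1L)
    return("level 0 must hold exactly one tile")
  TRUE
})

#' Plan a tile pyramid for an image
#'
#' Computes the zoom levels, per-level pixel dimensions and tile grids for an
#' image of the given size. The full-resolution level is
#' \code{zMax = max(0, ceiling(log2(max(width, height) / tileSize)))}; each
#' coarser level halves both dimensions with ceiling until the whole image
#' fits a single tile at \code{z = 0}.
#'
#' @param width,height source image dimensions in pixels (>= 1).
#' @param tileSize tile edge length in pixels (default 256).
#' @return a [PyramidPlan-class] object.
#' @examples
#' planPyramid(4096, 4096)        # zMax 4, 341 tiles in total
#' planPyramid(1000, 600)         # zMax 2: 4x3, 2x2, 1x1 tile grids
#' @export
planPyramid <- function(width, height, tileSize = 256L) {
  if (!is.numeric(width) || !is.numeric(height) || !is.numeric(tileSize) ||
      length(width) != 1L || length(height) != 1L || length(tileSize) != 1L ||
      is.na(width) || is.na(height) || is.na(tileSize) ||
      width < 1 || height < 1 || tileSize < 1)
    stopInvalid("width, height and tileSize must be positive scalars")
  w <- as.integer(width); h <- as.integer(height); ts <- as.integer(tileSize)
  zMax <- 0L
  while (max(w, h) > ts * 2^zMax) zMax <- zMax + 1L
  z <- 0:zMax
  sc <- 2^(zMax - z)
  lw <- as.integer(ceiling(w / sc)); lh <- as.integer(ceiling(h / sc))
  levels <- data.frame(
    z = z, width = lw, height = lh,
    tilesX = as.integer(ceiling(lw / ts)),
    tilesY = as.integer(ceiling(lh / ts))
  )
  new("PyramidPlan", sourceWidth = w, sourceHeight = h, tileSize = ts,
      zMax = zMax, levels = levels)
}

#' @rdname planPyramid
#' @param plan a \code{PyramidPlan}.
#' @return \code{tileCount} returns the total number of tiles across all
#'   levels (sum of \code{tilesX * tilesY}).
#' @examples
#' tileCount(planPyramid(53248, 40960))  # 44382, a typical 40x slide
#' @export
tileCount <- function(plan) {
  stopifnot(is(plan, "PyramidPlan"))
  sum(as.numeric(plan@levels$tilesX) * plan@levels$tilesY)
}

#' @describeIn planPyramid accessor for the per-level geometry table.
#' @export
pyramidLevels <- function(plan) {
  stopifnot(is(plan, "PyramidPlan"))
  plan@levels
}

#' @describeIn planPyramid accessor for the full-resolution zoom level.
#' @export
zoomMax <- function(plan) {
  stopifnot(is(plan, "PyramidPlan"))
  plan@zMax
}

#' @describeIn planPyramid accessor for the tile edge length in pixels.
#' @export
tileSize <- function(plan) {
  stopifnot(is(plan, "PyramidPlan"))
  plan@tileSize
}

setMethod("show", "PyramidPlan", function(object) {
  cat(sprintf("PyramidPlan: %d x %d px, tile %d px, z = 0..%d, %s tiles\n",
              object@sourceWidth, object@sourceHeight, object@tileSize,
              object@zMax, format(tileCount(object), big.mark = ",")))
  print(object@levels, row.names = FALSE)
  invisible(NULL)
})
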
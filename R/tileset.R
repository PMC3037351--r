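#' TileSet: an on-disk pyramid of image tiles
#'
#' A \code{TileSet} records where a tiled slide lives and how it was written:
#' the [PyramidPlan-class], the output directory, the JPEG quality (or
#' lossless PNG mode), the background colour used to pad partial edge tiles,
#' and a manifest enumerating every tile with its byte size. Tiles are laid
#' out as \code{\{z\}/\{x\}/\{y\}.jpg} with x increasing rightward and y
#' downward from the top-left origin -- the standard XYZ slippy-map layout
#' any web-map client can consume.
#'
#' @slot plan the [PyramidPlan-class] the tiles realise.
#' @slot rootPath tile tree root directory.
#' @slot jpegQuality integer 1-100 (ignored in lossless mode).
#' @slot lossless logical; \code{TRUE} writes PNG tiles for exact round trips.
#' @slot background length-3 RGB in [0,1] used to pad partial edge tiles.
#' @slot manifest \code{data.frame(z, x, y, path, bytes)}, one row per tile.
#' @seealso [tileImage()], [assembleLevel()], [readTileSet()]
#' @export
setClass("TileSet",
  representation(
    plan        = "PyramidPlan",
    rootPath    = "character",
    jpegQuality = "integer",
    lossless    = "logical",
    background  = "numeric",
    manifest    = "data.frame"
  )
)

setValidity("TileSet", function(object) {
  if (object@jpegQuality < 1L || object@jpegQuality > 100L)
    return("jpegQuality must be in 1..100")
  if (length(object@background) != 3L ||
      any(object@background < 0 | object@background > 1))
    return("background must be RGB in [0,1]")
  if (nrow(object@manifest) != tileCount(object@plan))
    return(sprintf("manifest has %d tiles but the plan requires %d",
                   nrow(object@manifest), tileCount(object@plan)))
  TRUE
})

setMethod("show", "TileSet", function(object) {
  cat(sprintf("TileSet at %s: %s tiles, %s, background #%s\n",
              object@rootPath,
              format(nrow(object@manifest), big.mark = ","),
              if (object@lossless) "lossless PNG"
              else sprintf("JPEG q=%d", object@jpegQuality),
              paste(sprintf("%02X", round(object@background * 255)),
                    collapse = "")))
  show(object@plan)
  invisible(NULL)
})

#' @describeIn tileImage accessor for the tile manifest table.
#' @export
tileManifest <- function(tileset) {
  stopifnot(is(tileset, "TileSet"))
  tileset@manifest
}

#' @describeIn tileImage accessor for the plan of a tile set.
#' @export
tilePlan <- function(tileset) {
  stopifnot(is(tileset, "TileSet"))
  tileset@plan
}

# --- raster helpers --------------------------------------------------------

# Rasters are numeric arrays [height, width, 3] with values in [0, 1],
# matching the orientation of png::readPNG / tiff::readTIFF.

asRaster3 <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  } else if (length(dim(img)) != 3L) {
    stopInvalid("expected a [height, width, channel] raster array")
  }
  img
}

#' Read a single-plane raster image
#'
#' Reads a PNG or TIFF image into a numeric \code{[height, width, 3]} array
#' with intensities in [0, 1]. Greyscale images are expanded to RGB and any
#' alpha channel is dropped.
#'
#' @param path image file (extension decides the decoder: png/tif/tiff).
#' @return numeric array \code{[height, width, 3]}.
#' @export
readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stopInvalid("unsupported image format ", sQuote(ext),
                " (expected png, tif/tiff or jpg)")
  )
  asRaster3(img)
}

#' @rdname readRaster
#' @param img raster array to write.
#' @param quality JPEG quality 1-100 (jpg output only).
#' @export
writeRaster <- function(img, path, quality = 85L) {
  img <- asRaster3(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(img, path, quality = quality / 100),
    stopInvalid("unsupported image format ", sQuote(ext))
  )
  invisible(path)
}

#' Area-mean 2x downsampling
#'
#' Halves both image dimensions (with ceiling for odd sizes) by averaging
#' each 2x2 pixel block; truncated edge blocks average the pixels present.
#' This is the filter used between pyramid levels, chosen for its simple
#' closed form: a constant image is exactly invariant under it.
#'
#' @param img raster array \code{[h, w, 3]}.
#' @return raster array \code{[ceiling(h/2), ceiling(w/2), 3]}.
#' @export
downsample2x <- function(img) {
  img <- asRaster3(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  rg <- as.integer(ceiling(seq_len(h) / 2))
  cg <- as.integer(ceiling(seq_len(w) / 2))
  nr <- rg[h]; nc <- cg[w]
  cnt <- tabulate(rg, nr) %o% tabulate(cg, nc)
  out <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) {
    s <- rowsum(img[, , ch], rg, reorder = FALSE)      # sum rows into groups
    s <- t(rowsum(t(s), cg, reorder = FALSE))          # then columns
    out[, , ch] <- s / cnt
  }
  out
}

#' Peak signal-to-noise ratio between two rasters
#'
#' @param a,b raster arrays of identical dimensions, intensities in [0,1].
#' @return PSNR in decibels (\code{Inf} for identical images).
#' @export
psnr <- function(a, b) {
  a <- asRaster3(a); b <- asRaster3(b)
  stopifnot(identical(dim(a), dim(b)))
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}

# --- tiling ----------------------------------------------------------------

tileExt <- function(lossless) if (lossless) "png" else "jpg"

#' Cut an image into a pyramidal XYZ tile set
#'
#' Writes every tile of the pyramid described by \code{plan} under
#' \code{out}, as \code{\{z\}/\{x\}/\{y\}.jpg} (or \code{.png} in lossless
#' mode). Level \code{zMax} is the source image; each coarser level is the
#' 2x area-mean downsample of the level above. Partial edge tiles are padded
#' to the full tile size with \code{background} -- never cropped -- so every
#' emitted tile decodes to exactly \code{tileSize x tileSize} pixels. A
#' \code{manifest.json} describing the plan and every tile is written at the
#' root.
#'
#' @param img raster array \code{[height, width, 3]} in [0,1] (see
#'   [readRaster()]).
#' @param out output directory (created if needed).
#' @param plan optional [PyramidPlan-class]; defaults to
#'   \code{planPyramid(width, height, tileSize)} of the image. If supplied,
#'   its source dimensions must match the image.
#' @param tileSize tile edge length used when \code{plan} is not supplied.
#' @param quality JPEG quality 1-100 (default 85).
#' @param background RGB padding colour in [0,1]; default white, suiting
#'   brightfield histology.
#' @param lossless write PNG tiles instead of JPEG for exact round trips.
#' @return a [TileSet-class]; its manifest enumerates exactly the planned
#'   tiles.
#' @examples
#' img <- synthSlide(512, 384, seed = 1)
#' ts <- tileImage(img, file.path(tempdir(), "tiles-ex"), lossless = TRUE)
#' nrow(tileManifest(ts)) == tileCount(tilePlan(ts))
#' @export
tileImage <- function(img, out, plan = NULL, tileSize = 256L, quality = 85L,
                      background = c(1, 1, 1), lossless = FALSE) {
  img <- asRaster3(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (is.null(plan)) plan <- planPyramid(w, h, tileSize)
  if (plan@sourceWidth != w || plan@sourceHeight != h)
    stopInvalid(sprintf(
      "image is %dx%d but the plan was made for %dx%d",
      w, h, plan@sourceWidth, plan@sourceHeight))
  quality <- as.integer(quality)
  if (is.na(quality) || quality < 1L || quality > 100L)
    stopInvalid("quality must be in 1..100")
  if (length(background) != 3L || any(background < 0 | background > 1))
    stopInvalid("background must be RGB in [0,1]")
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("cannot create output directory ", sQuote(out))

  ts <- plan@tileSize
  ext <- tileExt(lossless)
  rows <- vector("list", plan@zMax + 1L)
  cur <- img
  for (z in plan@zMax:0) {
    lv <- plan@levels[plan@levels$z == z, ]
    stopifnot(dim(cur)[1] == lv$height, dim(cur)[2] == lv$width)
    zrows <- vector("list", lv$tilesX * lv$tilesY)
    k <- 1L
    for (x in 0:(lv$tilesX - 1L)) {
      dir.create(file.path(out, z, x), recursive = TRUE, showWarnings = FALSE)
      for (y in 0:(lv$tilesY - 1L)) {
        r0 <- y * ts + 1L; r1 <- min((y + 1L) * ts, lv$height)
        c0 <- x * ts + 1L; c1 <- min((x + 1L) * ts, lv$width)
        tile <- array(rep(background, each = ts * ts), dim = c(ts, ts, 3L))
        tile[seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L), ] <-
          cur[r0:r1, c0:c1, , drop = FALSE]
        rel <- file.path(z, x, paste0(y, ".", ext))
        writeRaster(tile, file.path(out, rel), quality = quality)
        zrows[[k]] <- data.frame(
          z = z, x = x, y = y, path = rel,
          bytes = file.size(file.path(out, rel)))
        k <- k + 1L
      }
    }
    rows[[z + 1L]] <- do.call(rbind, zrows)
    if (z > 0L) cur <- downsample2x(cur)
  }
  manifest <- do.call(rbind, rows)
  manifest <- manifest[order(manifest$z, manifest$x, manifest$y), ]
  rownames(manifest) <- NULL
  tileset <- new("TileSet", plan = plan, rootPath = out,
                 jpegQuality = quality, lossless = lossless,
                 background = as.numeric(background), manifest = manifest)
  writeManifest(tileset)
  tileset
}

writeManifest <- function(tileset) {
  p <- tileset@plan
  obj <- list(
    source_width = p@sourceWidth, source_height = p@sourceHeight,
    tile_size = p@tileSize, z_max = p@zMax,
    jpeg_quality = tileset@jpegQuality, lossless = tileset@lossless,
    background = tileset@background,
    tiles = tileset@manifest
  )
  jsonlite::write_json(obj, file.path(tileset@rootPath, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tileset)
}

#' Load a tile set from its manifest
#'
#' @param root directory containing a \code{manifest.json} written by
#'   [tileImage()].
#' @return a [TileSet-class].
#' @export
readTileSet <- function(root) {
  mf <- file.path(root, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", sQuote(root))
  obj <- jsonlite::read_json(mf, simplifyVector = TRUE)
  plan <- planPyramid(obj$source_width, obj$source_height, obj$tile_size)
  new("TileSet", plan = plan, rootPath = root,
      jpegQuality = as.integer(obj$jpeg_quality),
      lossless = isTRUE(obj$lossless),
      background = as.numeric(obj$background),
      manifest = as.data.frame(obj$tiles))
}

#' Stitch one zoom level back into an image
#'
#' Reads every tile of level \code{z}, stitches them in XYZ order and crops
#' the padding so the result has exactly that level's pixel dimensions. Used
#' to verify round trips: in lossless mode the assembled \code{zMax} level is
#' pixel-identical to the source.
#'
#' @param tileset a [TileSet-class].
#' @param z zoom level to assemble (0..zMax).
#' @return raster array \code{[levelHeight, levelWidth, 3]}.
#' @export
assembleLevel <- function(tileset, z) {
  stopifnot(is(tileset, "TileSet"))
  plan <- tileset@plan
  if (!(z %in% plan@levels$z))
    stopInvalid("zoom level ", z, " is not in this tile set (0..",
                plan@zMax, ")")
  lv <- plan@levels[plan@levels$z == z, ]
  ts <- plan@tileSize
  ext <- tileExt(tileset@lossless)
  out <- array(0, dim = c(lv$tilesY * ts, lv$tilesX * ts, 3L))
  for (x in 0:(lv$tilesX - 1L)) {
    for (y in 0:(lv$tilesY - 1L)) {
      f <- file.path(tileset@rootPath, z, x, paste0(y, ".", ext))
      if (!file.exists(f))
        stop(sprintf("corrupt tile set: missing tile z=%d x=%d y=%d (%s)",
                     z, x, y, f), call. = FALSE)
      tile <- readRaster(f)
      if (dim(tile)[1] != ts || dim(tile)[2] != ts)
        stop(sprintf("corrupt tile set: tile z=%d x=%d y=%d is %dx%d, not %dx%d",
                     z, x, y, dim(tile)[2], dim(tile)[1], ts, ts),
             call. = FALSE)
      out[(y * ts + 1):((y + 1) * ts), (x * ts + 1):((x + 1) * ts), ] <- tile
    }
  }
  out[seq_len(lv$height), seq_len(lv$width), , drop = FALSE]
}
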
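# Deep Zoom Image (DZI) coordinate algebra.
#
# DZI levels run 0 .. max_level, max_level = ceiling(log2(max(w, h))), with
# level max_level at full resolution and each lower level halved (ceiling).
# Note the numbering runs opposite to stored pyramid levels (where 0 = full
# resolution); map_to_pyramid() converts between the two.

#' DZI descriptor
#'
#' Tile size, overlap, tile format and full-resolution dimensions; defines
#' the tile coordinate system a Deep Zoom viewer navigates.
#'
#' @param width,height full-resolution image size in pixels.
#' @param tile_size tile edge in pixels (>= 16; default 256).
#' @param overlap extra pixels shared between neighboring tiles on each side
#'   (`0 <= overlap < tile_size`; default 1, the Deep Zoom convention most
#'   viewers expect for seam-free rendering).
#' @param tile_format `"png"` (lossless; default for fluorescence) or
#'   `"jpeg"`.
#' @return object of class `dzi_descriptor` with a `max_level` field.
#' @export
dzi_descriptor <- function(width, height, tile_size = 256L, overlap = 1L,
                           tile_format = c("png", "jpeg")) {
  width <- as_count(width, "width"); height <- as_count(height, "height")
  tile_size <- as_count(tile_size, "tile_size"); overlap <- as_count(overlap, "overlap")
  tile_format <- match.arg(tile_format)
  if (width < 1L || height < 1L) stop_invalid_input("image dimensions must be >= 1")
  if (tile_size < 16L) stop_invalid_input("tile_size must be >= 16")
  if (overlap < 0L || overlap >= tile_size)
    stop_invalid_input("overlap must satisfy 0 <= overlap < tile_size")
  structure(list(width = width, height = height, tile_size = tile_size,
                 overlap = overlap, tile_format = tile_format,
                 max_level = max(0L, as.integer(ceiling(log2(max(width, height)))))),
            class = "dzi_descriptor")
}

check_dzi_level <- function(desc, level) {
  level <- as_count(level, "level")
  if (level < 0L || level > desc$max_level)
    stop_not_found(sprintf("DZI level %d out of range [0, %d]", level, desc$max_level))
  level
}

#' Pixel dimensions of a DZI level
#'
#' Level `l` is the full image scaled by `1 / 2^(max_level - l)`, dimensions
#' rounded up.
#'
#' @param desc a [dzi_descriptor()].
#' @param level DZI level, `0 <= level <= max_level`.
#' @return integer `c(width, height)`.
#' @export
level_dimensions <- function(desc, level) {
  level <- check_dzi_level(desc, level)
  s <- 2^(desc$max_level - level)
  c(width = as.integer(ceiling(desc$width / s)),
    height = as.integer(ceiling(desc$height / s)))
}

#' Tile grid of a DZI level
#'
#' Overlap does not change the grid: tiles are counted over their core
#' (non-overlapping) regions.
#'
#' @inheritParams level_dimensions
#' @return integer `c(cols, rows)`.
#' @export
tile_grid <- function(desc, level) {
  wh <- level_dimensions(desc, level)
  c(cols = as.integer(ceiling(wh[["width"]] / desc$tile_size)),
    rows = as.integer(ceiling(wh[["height"]] / desc$tile_size)))
}

#' Pixel bounds of one tile
#'
#' The tile's core region is the `tile_size`-aligned block clipped to the
#' level extent; the returned bounds expand the core by `overlap` pixels on
#' every side, clamped to the level. Interior tiles therefore measure
#' `tile_size + 2 * overlap`; border tiles are smaller.
#'
#' @inheritParams level_dimensions
#' @param col,row 0-based tile column and row.
#' @return integer `c(y0, x0, y1, x1)`, 0-based half-open, level pixels.
#' @export
tile_bounds <- function(desc, level, col, row) {
  level <- check_dzi_level(desc, level)
  col <- as_count(col, "col"); row <- as_count(row, "row")
  grid <- tile_grid(desc, level)
  if (col < 0L || col >= grid[["cols"]] || row < 0L || row >= grid[["rows"]])
    stop_not_found(sprintf("tile (%d, %d) out of range for level %d grid %d x %d",
                           col, row, level, grid[["cols"]], grid[["rows"]]))
  wh <- level_dimensions(desc, level)
  ts <- desc$tile_size; ov <- desc$overlap
  core <- tile_core(desc, level, col, row)
  c(y0 = max(core[["y0"]] - ov, 0L), x0 = max(core[["x0"]] - ov, 0L),
    y1 = min(core[["y1"]] + ov, wh[["height"]]), x1 = min(core[["x1"]] + ov, wh[["width"]]))
}

# core (overlap-free) region of a tile; tiles' cores partition the level
tile_core <- function(desc, level, col, row) {
  wh <- level_dimensions(desc, level)
  ts <- desc$tile_size
  c(y0 = row * ts, x0 = col * ts,
    y1 = min((row + 1L) * ts, wh[["height"]]), x1 = min((col + 1L) * ts, wh[["width"]]))
}

#' Map a DZI level onto a stored pyramid level
#'
#' A DZI level needing total downscale `s = 2^(max_level - level)` is served
#' from the deepest stored level not exceeding that scale; the remaining
#' power-of-two factor (`residual_factor`) is applied at render time with the
#' same area-mean kernel used to build the pyramid, so the synthesized level
#' is pixel-identical to downscaling the full-resolution data directly.
#'
#' @param desc a [dzi_descriptor()] whose dimensions equal the pyramid's
#'   level-0 dimensions.
#' @param pyramid an `image_pyramid`/`pyramid_store`, or the number of stored
#'   levels.
#' @param level DZI level.
#' @return list with `pyramid_level` (0-based stored level) and
#'   `residual_factor` (power of two, >= 1).
#' @export
map_to_pyramid <- function(desc, pyramid, level) {
  level <- check_dzi_level(desc, level)
  if (is.numeric(pyramid)) {
    np <- as_count(pyramid, "pyramid level count")
  } else {
    if (desc$width != pyramid$base_width || desc$height != pyramid$base_height)
      tf_stop(sprintf("descriptor %d x %d does not match pyramid %d x %d",
                      desc$width, desc$height, pyramid$base_width, pyramid$base_height),
              "tf_config_error")
    np <- n_levels(pyramid)
  }
  if (np < 1L) tf_stop("pyramid must have at least one level", "tf_config_error")
  e <- desc$max_level - level                 # total halvings required
  p <- min(e, np - 1L)
  list(pyramid_level = p, residual_factor = as.integer(2^(e - p)))
}

#' Tile URL path under the Deep Zoom layout
#'
#' External viewers construct `<name>_files/<level>/<col>_<row>.<fmt>`
#' themselves, so the layout is bit-exact.
#'
#' @param name image identifier (the descriptor is at `<name>.dzi`).
#' @param level,col,row tile address.
#' @param fmt `"png"` or `"jpeg"`.
#' @export
tile_path <- function(name, level, col, row, fmt = "png") {
  sprintf("%s_files/%d/%d_%d.%s", name, level, col, row, fmt)
}

dzi_ns <- "http://schemas.microsoft.com/deepzoom/2008"

#' Serialize a descriptor as Deep Zoom XML
#'
#' Emits the standard DZI document (Image element with TileSize, Overlap,
#' Format; Size child with Width, Height) in the deepzoom 2008 namespace.
#' Output is byte-stable for equal inputs.
#'
#' @param desc a [dzi_descriptor()].
#' @return a single XML string.
#' @export
descriptor_xml <- function(desc) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf('<Image TileSize="%d" Overlap="%d" Format="%s" xmlns="%s">\n',
                 desc$tile_size, desc$overlap, desc$tile_format, dzi_ns),
         sprintf('  <Size Width="%d" Height="%d"/>\n', desc$width, desc$height),
         '</Image>\n')
}

#' Parse a Deep Zoom XML descriptor
#' @param text DZI XML document.
#' @return a [dzi_descriptor()].
#' @export
parse_descriptor_xml <- function(text) {
  doc <- xml2::read_xml(text)
  img <- xml2::xml_find_first(doc, "/*[local-name()='Image']")
  size <- xml2::xml_find_first(doc, "//*[local-name()='Size']")
  if (is.na(xml2::xml_name(img)) || is.na(xml2::xml_name(size)))
    stop_invalid_input("not a DZI descriptor document")
  dzi_descriptor(width = as.integer(xml2::xml_attr(size, "Width")),
                 height = as.integer(xml2::xml_attr(size, "Height")),
                 tile_size = as.integer(xml2::xml_attr(img, "TileSize")),
                 overlap = as.integer(xml2::xml_attr(img, "Overlap")),
                 tile_format = xml2::xml_attr(img, "Format"))
}

#' @export
print.dzi_descriptor <- function(x, ...) {
  cat(sprintf("<dzi_descriptor> %d x %d, tile %d, overlap %d, %s, levels 0..%d\n",
              x$width, x$height, x$tile_size, x$overlap, x$tile_format, x$max_level))
  invisible(x)
}
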
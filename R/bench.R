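# Bytes-transferred comparison between two serving strategies for the same
# scripted browsing session: (a) on-demand rendered DZI tiles for a
# k-channel spec, versus (b) shipping the raw unsigned-integer planes of
# all channels for each viewport. Only payload bytes and request counts are
# reported — wall-clock and memory are environment-specific and deliberately
# not measured.

#' Deterministic viewport script over an image
#'
#' Produces `n` viewports of `vw` x `vh` pixels at the full-resolution DZI
#' level, spread over the image on a fixed diagonal-staggered lattice (no
#' randomness): the browsing session every benchmark replays.
#'
#' @param desc a [dzi_descriptor()].
#' @param n number of viewports.
#' @param vw,vh viewport size in level pixels (clipped to the image).
#' @return data frame with columns `level`, `y0`, `x0`, `y1`, `x1`.
#' @export
default_viewports <- function(desc, n = 10L, vw = 1024L, vh = 1024L) {
  level <- desc$max_level
  wh <- level_dimensions(desc, level)
  vw <- min(vw, wh[["width"]]); vh <- min(vh, wh[["height"]])
  i <- seq_len(n) - 1L
  span_x <- wh[["width"]] - vw; span_y <- wh[["height"]] - vh
  x0 <- if (n > 1L) round(i * span_x / (n - 1L)) else 0L
  y0 <- if (n > 1L) round(((i * 3L) %% n) * span_y / (n - 1L)) else 0L
  data.frame(level = level, y0 = as.integer(y0), x0 = as.integer(x0),
             y1 = as.integer(y0 + vh), x1 = as.integer(x0 + vw))
}

# tiles whose core regions intersect a viewport window
viewport_tiles <- function(desc, level, y0, x0, y1, x1) {
  ts <- desc$tile_size
  cols <- (x0 %/% ts):((x1 - 1L) %/% ts)
  rows <- (y0 %/% ts):((y1 - 1L) %/% ts)
  expand.grid(col = cols, row = rows)
}

#' Replay a viewport script and account bytes for both strategies
#'
#' For every scripted viewport, strategy (a) requests each DZI tile whose
#' core intersects the viewport, rendered with `spec`; strategy (b) is
#' charged the raw bytes of all channels of the viewport at the source bit
#' depth (`width x height x channels x bytes_per_sample`). Tiles are
#' requested without caching, so repeated tiles are charged every time —
#' the conservative accounting for strategy (a).
#'
#' @param app a [tile_app()].
#' @param image_id registered image.
#' @param viewports data frame from [default_viewports()].
#' @param spec a [render_spec()] or wire string: the channels the viewer
#'   actually displays.
#' @param fmt tile encoding.
#' @return list with `tile_bytes`, `raw_bytes`, `tile_requests`,
#'   `rendered_channels`, `total_channels`, `reduction_fold`.
#' @export
bench_viewports <- function(app, image_id, viewports, spec, fmt = "png") {
  if (is.character(spec)) spec <- parse_spec(spec)
  store <- app_store(app, image_id)
  desc <- app_descriptor(app, image_id, fmt)
  nch <- length(store$channel_names)
  bps <- dtype_bytes(store$dtype)
  tile_bytes <- 0; raw_bytes <- 0; tile_requests <- 0L
  for (v in seq_len(nrow(viewports))) {
    vp <- viewports[v, ]
    tiles <- viewport_tiles(desc, vp$level, vp$y0, vp$x0, vp$y1, vp$x1)
    for (t in seq_len(nrow(tiles))) {
      res <- handle_tile(app, image_id, vp$level, tiles$col[t], tiles$row[t],
                         spec, fmt = fmt, use_cache = FALSE)
      tile_bytes <- tile_bytes + length(res$body)
      tile_requests <- tile_requests + 1L
    }
    raw_bytes <- raw_bytes + (vp$y1 - vp$y0) * (vp$x1 - vp$x0) * nch * bps
  }
  list(tile_bytes = tile_bytes, raw_bytes = raw_bytes,
       tile_requests = tile_requests,
       rendered_channels = length(spec$entries), total_channels = nch,
       reduction_fold = raw_bytes / tile_bytes)
}

#' Stitch all tiles of a DZI level into one raster
#'
#' Requests every tile of the level through the tile pipeline, decodes it,
#' trims the overlap margins, and places the core regions side by side.
#' Because tile cores partition the level, the result must equal a direct
#' render of the whole level — the stitching identity used throughout the
#' test suite.
#'
#' @param app a [tile_app()].
#' @param image_id registered image.
#' @param level DZI level.
#' @param spec a [render_spec()] or wire string.
#' @param fmt tile encoding (`"png"` for exact comparisons).
#' @return integer array `(level_height, level_width, 3)`.
#' @export
stitch_level <- function(app, image_id, level, spec, fmt = "png") {
  desc <- app_descriptor(app, image_id, fmt)
  wh <- level_dimensions(desc, level)
  grid <- tile_grid(desc, level)
  out <- array(0L, dim = c(wh[["height"]], wh[["width"]], 3L))
  for (col in seq_len(grid[["cols"]]) - 1L) {
    for (row in seq_len(grid[["rows"]]) - 1L) {
      res <- handle_tile(app, image_id, level, col, row, spec, fmt = fmt,
                         use_cache = FALSE)
      raster <- decode_tile(res$body, fmt)
      b <- tile_bounds(desc, level, col, row)
      core <- tile_core(desc, level, col, row)
      ys <- core[["y0"]] - b[["y0"]]; xs <- core[["x0"]] - b[["x0"]]
      ch <- core[["y1"]] - core[["y0"]]; cw <- core[["x1"]] - core[["x0"]]
      out[(core[["y0"]] + 1L):core[["y1"]], (core[["x0"]] + 1L):core[["x1"]], ] <-
        raster[(ys + 1L):(ys + ch), (xs + 1L):(xs + cw), , drop = FALSE]
    }
  }
  out
}
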
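#' Build a multiscale image pyramid
#'
#' Repeatedly downsamples each channel by a 2x2 area mean until the largest
#' dimension is at most `stop_size`. Level 0 is the input, bit for bit; level
#' p has height `ceiling(H / 2^p)` and width `ceiling(W / 2^p)`. Odd trailing
#' rows/columns are averaged over the pixels actually present (1x2, 2x1 or
#' 1x1 blocks), which keeps the ceiling shape law exact with no padding.
#' Block means are accumulated in doubles and rounded half up back to the
#' input dtype, so pyramids are bit-reproducible across platforms.
#'
#' @param image a [raster_image()].
#' @param chunk_h,chunk_w chunk geometry recorded for storage (pixels, both
#'   >= 16). Chunks never span channels, so a reader touching k channels does
#'   I/O for exactly k channels.
#' @param stop_size generation stops at the first level whose largest
#'   dimension is `<= stop_size`. Deeper zoom-out levels are synthesized at
#'   render time by residual scaling (see [map_to_pyramid()]).
#' @return an object of class `image_pyramid`: fields `levels` (list of
#'   `(c, y, x)` arrays), `chunk_shape`, `base_width`, `base_height`,
#'   `channel_names`, `pixel_kind`, `dtype`.
#' @examples
#' img <- raster_image(array(40L, dim = c(1, 8, 8)), dtype = "uint8")
#' p <- build_pyramid(img, stop_size = 1)
#' n_levels(p)            # 4 levels: 8, 4, 2, 1
#' @export
build_pyramid <- function(image, chunk_h = 256L, chunk_w = 256L, stop_size = 512L) {
  if (!inherits(image, "raster_image")) image <- raster_image(image)
  chunk_h <- as_count(chunk_h, "chunk_h"); chunk_w <- as_count(chunk_w, "chunk_w")
  stop_size <- as_count(stop_size, "stop_size")
  if (chunk_h < 16L || chunk_w < 16L) stop_invalid_input("chunk dimensions must be >= 16")
  if (stop_size < 1L) stop_invalid_input("stop_size must be >= 1")
  d <- dim(image$pixels)
  levels <- list(image$pixels)
  while (max(dim(levels[[length(levels)]])[2:3]) > stop_size) {
    levels[[length(levels) + 1L]] <- downsample_level(levels[[length(levels)]])
  }
  structure(list(levels = levels,
                 chunk_shape = c(1L, chunk_h, chunk_w),
                 base_width = d[3L], base_height = d[2L],
                 channel_names = image$channel_names,
                 pixel_kind = image$pixel_kind,
                 dtype = image$dtype),
            class = "image_pyramid")
}

# One 2x area-mean halving of a (c, y, x) array.
downsample_level <- function(a) {
  d <- dim(a)
  out <- array(0L, dim = c(d[1L], ceiling(d[2L] / 2), ceiling(d[3L] / 2)))
  for (ch in seq_len(d[1L])) out[ch, , ] <- downsample2x(matrix(a[ch, , ], d[2L], d[3L]))
  out
}

#' 2x2 area-mean downsampling of one channel plane
#'
#' Sums each 2x2 block (trailing blocks may be 1x2, 2x1 or 1x1 at odd edges),
#' divides by the number of pixels present, and rounds half up. This is the
#' single downsampling kernel used everywhere — pyramid construction and
#' residual DZI-level synthesis — so rendering a zoom level through the
#' pyramid is pixel-identical to downscaling the full-resolution plane.
#'
#' @param m integer matrix (y, x).
#' @return integer matrix of shape `(ceiling(nrow/2), ceiling(ncol/2))`.
#' @export
downsample2x <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h == 1L && w == 1L) return(m)
  io <- seq.int(1L, h, by = 2L)
  s <- m[io, , drop = FALSE] * 1.0
  ie <- io + 1L
  full_rows <- ie <= h
  if (any(full_rows))
    s[full_rows, ] <- s[full_rows, , drop = FALSE] + m[ie[full_rows], , drop = FALSE]
  jo <- seq.int(1L, w, by = 2L)
  s2 <- s[, jo, drop = FALSE]
  je <- jo + 1L
  full_cols <- je <= w
  if (any(full_cols))
    s2[, full_cols] <- s2[, full_cols, drop = FALSE] + s[, je[full_cols], drop = FALSE]
  counts <- outer(ifelse(full_rows, 2, 1), ifelse(full_cols, 2, 1))
  out <- floor(s2 / counts + 0.5)        # round half up
  storage.mode(out) <- "integer"
  out
}

#' Number of stored levels in a pyramid or pyramid store
#' @param pyramid an `image_pyramid` or `pyramid_store`.
#' @export
n_levels <- function(pyramid) UseMethod("n_levels")

#' @export
n_levels.image_pyramid <- function(pyramid) length(pyramid$levels)

#' Height and width of one stored level
#' @param pyramid an `image_pyramid` or `pyramid_store`.
#' @param level 0-based stored-level index (0 = full resolution).
#' @return integer `c(height, width)`.
#' @export
level_shape <- function(pyramid, level) UseMethod("level_shape")

#' @export
level_shape.image_pyramid <- function(pyramid, level) {
  level <- check_level(pyramid, level)
  dim(pyramid$levels[[level + 1L]])[2:3]
}

check_level <- function(pyramid, level) {
  level <- as_count(level, "level")
  if (level < 0L || level >= n_levels(pyramid))
    stop_not_found(sprintf("level %d out of range [0, %d)", level, n_levels(pyramid)))
  level
}

# Shared request validation for read_region implementations; returns
# normalized integer parameters.
check_region <- function(pyramid, level, y0, x0, y1, x1, channels) {
  level <- check_level(pyramid, level)
  hw <- level_shape(pyramid, level)
  y0 <- as_count(y0, "y0"); x0 <- as_count(x0, "x0")
  y1 <- as_count(y1, "y1"); x1 <- as_count(x1, "x1")
  if (y0 < 0L || x0 < 0L || y0 >= y1 || x0 >= x1 || y1 > hw[1L] || x1 > hw[2L])
    stop_not_found(sprintf(
      "region [%d,%d)x[%d,%d) out of bounds for level %d (%d x %d)",
      y0, y1, x0, x1, level, hw[1L], hw[2L]))
  channels <- vapply(channels, as_count, integer(1), what = "channel index")
  nc <- length(channel_names_of(pyramid))
  if (length(channels) == 0L) stop_bad_request("at least one channel is required")
  if (anyDuplicated(channels)) stop_bad_request("duplicate channel index in request")
  if (any(channels < 0L) || any(channels >= nc))
    stop_bad_request(sprintf("channel index out of range [0, %d)", nc))
  list(level = level, y0 = y0, x0 = x0, y1 = y1, x1 = x1, channels = channels)
}

channel_names_of <- function(x) UseMethod("channel_names_of")
#' @export
channel_names_of.image_pyramid <- function(x) x$channel_names
#' @export
channel_names_of.pyramid_store <- function(x) x$channel_names

#' Read a rectangular region of one pyramid level
#'
#' Returns the requested channels of the half-open window
#' `[y0, y1) x [x0, x1)` at a stored level. For an on-disk store only the
#' chunks intersecting the window — and only for the requested channels —
#' are read (verifiable through [store_access_log()]). Out-of-bounds regions
#' raise an error; there is no silent clamping.
#'
#' @inheritParams level_shape
#' @param y0,x0,y1,x1 0-based half-open bounds in level pixels.
#' @param channels 0-based distinct channel indices.
#' @return integer array `(length(channels), y1 - y0, x1 - x0)`.
#' @export
read_region <- function(pyramid, level, y0, x0, y1, x1, channels) UseMethod("read_region")

#' @export
read_region.image_pyramid <- function(pyramid, level, y0, x0, y1, x1, channels) {
  q <- check_region(pyramid, level, y0, x0, y1, x1, channels)
  lv <- pyramid$levels[[q$level + 1L]]
  lv[q$channels + 1L, (q$y0 + 1L):q$y1, (q$x0 + 1L):q$x1, drop = FALSE]
}

#' @export
print.image_pyramid <- function(x, ...) {
  cat(sprintf("<image_pyramid> %d x %d px, %d channel(s), %s, %d level(s)\n",
              x$base_width, x$base_height, length(x$channel_names), x$dtype, n_levels(x)))
  for (p in seq_len(n_levels(x)) - 1L) {
    hw <- level_shape(x, p)
    cat(sprintf("  level %d: %d x %d\n", p, hw[2L], hw[1L]))
  }
  invisible(x)
}
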
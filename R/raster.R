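#' Multi-channel raster image
#'
#' Container for one 2-D multi-channel image: a 3-D integer array indexed
#' `(channel, y, x)` plus channel names and a pixel-kind tag. Samples must be
#' unsigned 8- or 16-bit integers; floating-point input is rejected rather
#' than silently normalized (fluorescence instruments emit integer counts;
#' display normalization belongs to the render spec).
#'
#' All tileforge APIs use the same coordinate convention: `(y, x)` = (row,
#' column), 0-based, half-open intervals. Channel indices are 0-based too,
#' matching the wire protocol (see [parse_spec()]).
#'
#' @param pixels 3-D array `(channel, height, width)` of non-negative
#'   integers, or a 2-D matrix (treated as one channel).
#' @param channel_names character vector, one per channel. Defaults to
#'   `"CH0" ... "CHn-1"`.
#' @param pixel_kind one of `"fluorescence"`, `"brightfield_rgb"`,
#'   `"grayscale"`. `brightfield_rgb` requires exactly 3 channels.
#' @param dtype `"uint8"` or `"uint16"`. Inferred from the value range when
#'   omitted (max > 255 implies uint16, else uint8).
#' @return an object of class `raster_image` with fields `pixels`,
#'   `channel_names`, `pixel_kind`, `dtype`.
#' @examples
#' img <- raster_image(array(0:23, dim = c(2, 3, 4)), dtype = "uint8")
#' dim(img$pixels)
#' @export
raster_image <- function(pixels, channel_names = NULL,
                         pixel_kind = c("fluorescence", "brightfield_rgb", "grayscale"),
                         dtype = NULL) {
  pixel_kind <- match.arg(pixel_kind)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(1L, dim(pixels)))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop_invalid_input("pixels must be a (channel, y, x) 3-D array")
  if (any(dim(pixels) < 1L) || length(pixels) == 0L)
    stop_invalid_input("empty image: all dimensions must be >= 1")
  if (is.double(pixels)) {
    if (any(pixels != floor(pixels)))
      tf_stop("floating-point samples are not supported; window/normalize at render time",
              "tf_unsupported_dtype")
    storage.mode(pixels) <- "integer"
  }
  if (!is.integer(pixels))
    tf_stop(sprintf("unsupported sample type '%s'", typeof(pixels)), "tf_unsupported_dtype")
  if (anyNA(pixels) || min(pixels) < 0L)
    tf_stop("samples must be non-negative integers (unsigned 8/16-bit)", "tf_unsupported_dtype")
  mx <- max(pixels)
  if (is.null(dtype)) dtype <- if (mx > 255L) "uint16" else "uint8"
  dtype <- match.arg(dtype, c("uint8", "uint16"))
  if (mx > dtype_max(dtype))
    tf_stop(sprintf("sample value %d exceeds %s range", mx, dtype), "tf_unsupported_dtype")
  nc <- dim(pixels)[1L]
  if (pixel_kind == "brightfield_rgb" && nc != 3L)
    stop_invalid_input("brightfield_rgb requires exactly 3 channels")
  if (is.null(channel_names)) channel_names <- default_channel_names(nc, pixel_kind)
  if (length(channel_names) != nc)
    stop_invalid_input(sprintf("channel_names has length %d but image has %d channels",
                               length(channel_names), nc))
  structure(list(pixels = pixels, channel_names = as.character(channel_names),
                 pixel_kind = pixel_kind, dtype = dtype),
            class = "raster_image")
}

default_channel_names <- function(n, pixel_kind = "fluorescence") {
  if (pixel_kind == "brightfield_rgb" && n == 3L) c("R", "G", "B")
  else paste0("CH", seq_len(n) - 1L)
}

dtype_max <- function(dtype) switch(dtype, uint8 = 255L, uint16 = 65535L,
                                    stop_invalid_input(sprintf("unknown dtype '%s'", dtype)))

dtype_bytes <- function(dtype) switch(dtype, uint8 = 1L, uint16 = 2L)

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d px, %d channel(s), %s, %s\n",
              d[3L], d[2L], d[1L], x$dtype, x$pixel_kind))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)
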
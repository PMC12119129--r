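# Server-side channel compositing: per-channel intensity windowing followed
# by additive color blending with saturation clip — the standard visual model
# for co-localized fluorophores. Arithmetic is fixed (float accumulate, clip,
# round half up, cast to 8-bit) so tiles are bit-reproducible across
# platforms. Windowing is linear; no gamma or LUT.

#' Per-channel render instruction
#'
#' @param channel 0-based channel index.
#' @param color integer `c(r, g, b)`, each in `[0, 255]`, the display tint.
#' @param low,high intensity window in source sample units; values `<= low`
#'   map to black, `>= high` to full tint brightness, linear in between.
#' @return object of class `channel_render`.
#' @export
channel_render <- function(channel, color, low, high) {
  channel <- as_count(channel, "channel")
  if (channel < 0L) stop_bad_request("channel index must be >= 0")
  color <- vapply(color, as_count, integer(1), what = "color component")
  if (length(color) != 3L || any(color < 0L) || any(color > 255L))
    stop_bad_request("color must be three integers in [0, 255]")
  low <- as_count(low, "window low"); high <- as_count(high, "window high")
  if (low >= high)
    tf_stop(sprintf("invalid window: low (%d) >= high (%d)", low, high), "tf_bad_request")
  structure(list(channel = channel, color = color, low = low, high = high),
            class = "channel_render")
}

#' Channel selection for one rendering request
#'
#' @param entries list of [channel_render()] objects with distinct channels;
#'   non-empty for additive mode.
#' @param mode `"additive"` (fluorescence compositing, the default) or
#'   `"rgb_passthrough"` (brightfield RGB: channels 0, 1, 2 copied to R, G, B
#'   after windowing — requires exactly the identity channel mapping).
#' @return object of class `render_spec`.
#' @export
render_spec <- function(entries, mode = c("additive", "rgb_passthrough")) {
  mode <- match.arg(mode)
  if (inherits(entries, "channel_render")) entries <- list(entries)
  if (!is.list(entries) || !all(vapply(entries, inherits, logical(1), "channel_render")))
    stop_bad_request("entries must be a list of channel_render objects")
  if (length(entries) == 0L) stop_bad_request("render spec must have at least one entry")
  chans <- vapply(entries, function(e) e$channel, integer(1))
  if (anyDuplicated(chans))
    stop_bad_request(sprintf("duplicate channel %d in render spec",
                             chans[anyDuplicated(chans)]))
  if (mode == "rgb_passthrough" && !identical(chans, 0:2))
    stop_bad_request("rgb_passthrough requires exactly channels 0, 1, 2 in order")
  structure(list(entries = entries, mode = mode), class = "render_spec")
}

spec_channels <- function(spec) vapply(spec$entries, function(e) e$channel, integer(1))

#' Window one channel plane to the unit interval
#'
#' `clip((plane - low) / (high - low), 0, 1)` in floating point.
#'
#' @param plane numeric or integer matrix.
#' @param low,high window bounds, `low < high`.
#' @return double matrix in `[0, 1]`.
#' @export
normalize_channel <- function(plane, low, high) {
  if (low >= high)
    tf_stop(sprintf("invalid window: low (%s) >= high (%s)", format(low), format(high)),
            "tf_bad_request")
  pmin(pmax((plane - low) / (high - low), 0), 1)
}

#' Composite channel planes into an 8-bit RGB raster
#'
#' Additive mode: each plane is windowed to `[0, 1]` and multiplied by its
#' display color; contributions are summed per pixel per color component,
#' clipped to `[0, 255]` and rounded half up. Summation is commutative, so
#' the result is independent of entry order. `rgb_passthrough` copies the
#' three windowed planes to R, G, B scaled to `[0, 255]`.
#'
#' @param planes array `(n_entries, h, w)`: one plane per spec entry, in
#'   entry order (e.g. the output of [read_region()] for the spec's
#'   channels). A matrix is accepted for a single entry.
#' @param spec a [render_spec()].
#' @return integer array `(h, w, 3)` with values in 0..255.
#' @export
mix_channels <- function(planes, spec) {
  stopifnot(inherits(spec, "render_spec"))
  if (is.matrix(planes)) planes <- array(planes, dim = c(1L, dim(planes)))
  if (!is.array(planes) || length(dim(planes)) != 3L)
    stop_invalid_input("planes must be a (entry, y, x) array")
  ne <- length(spec$entries)
  if (dim(planes)[1L] != ne)
    stop_invalid_input(sprintf("planes has %d slice(s) but spec has %d entr(ies)",
                               dim(planes)[1L], ne))
  h <- dim(planes)[2L]; w <- dim(planes)[3L]
  acc <- array(0, dim = c(h, w, 3L))
  for (i in seq_len(ne)) {
    e <- spec$entries[[i]]
    nrm <- normalize_channel(matrix(planes[i, , ], h, w), e$low, e$high)
    if (spec$mode == "additive") {
      for (k in 1:3) acc[, , k] <- acc[, , k] + nrm * e$color[k]
    } else {
      acc[, , i] <- nrm * 255
    }
  }
  out <- floor(pmin(pmax(acc, 0), 255) + 0.5)   # clip then round half up
  storage.mode(out) <- "integer"
  out
}

#' Encode an RGB raster as PNG or JPEG
#'
#' PNG is lossless (`decode_tile(encode_tile(x, "png")) == x` bit for bit);
#' JPEG quality trades bytes for fidelity.
#'
#' @param rgb integer array `(h, w, 3)`, values 0..255.
#' @param fmt `"png"` or `"jpeg"`.
#' @param quality JPEG quality in `[1, 100]` (default 90); ignored for PNG.
#' @return raw vector of encoded bytes.
#' @export
encode_tile <- function(rgb, fmt = "png", quality = 90L) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop_invalid_input("rgb must be an (h, w, 3) array")
  if (!fmt %in% c("png", "jpeg"))
    stop_bad_request(sprintf("unsupported tile format '%s' (png or jpeg)", fmt))
  img <- rgb / 255
  if (fmt == "png") png::writePNG(img)
  else {
    quality <- as_count(quality, "jpeg quality")
    if (quality < 1L || quality > 100L) stop_bad_request("jpeg quality must be in [1, 100]")
    jpeg::writeJPEG(img, quality = quality / 100)
  }
}

#' Decode tile bytes back to an integer RGB array
#' @param bytes raw vector from [encode_tile()].
#' @param fmt `"png"` or `"jpeg"`.
#' @return integer array `(h, w, 3)`, values 0..255.
#' @export
decode_tile <- function(bytes, fmt = "png") {
  if (!fmt %in% c("png", "jpeg"))
    stop_bad_request(sprintf("unsupported tile format '%s'", fmt))
  img <- if (fmt == "png") png::readPNG(bytes) else jpeg::readJPEG(bytes)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  out <- floor(img * 255 + 0.5)
  storage.mode(out) <- "integer"
  out
}
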
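# Deterministic synthetic multichannel images. Gaussian blobs on a flat
# background with seeded Gaussian noise: blobs survive area-mean
# downsampling predictably, so pyramid- and tile-level tests can assert
# where signal must appear. These fixtures stand in for multiplex
# immunofluorescence scans in every test; no external data is needed.

#' Specification of a synthetic multichannel image
#'
#' @param width,height image size in pixels.
#' @param channels channel count.
#' @param dtype `"uint8"` or `"uint16"`.
#' @param seed RNG seed; identical specs produce bit-identical images.
#' @param background flat background level, sample units.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param blobs list of length `channels`; each element a data frame with
#'   columns `cy`, `cx` (0-based center), `radius` (pixels, truncation
#'   radius) and `peak` (added intensity at the center; may be negative to
#'   darken, e.g. brightfield tissue). Blob centers must lie within bounds
#'   and `|peak|` within the dtype range.
#' @param pixel_kind see [raster_image()].
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(width, height, channels, dtype = "uint16", seed = 1L,
                         background = 0L, noise_sd = 0, blobs = NULL,
                         pixel_kind = "fluorescence") {
  width <- as_count(width, "width"); height <- as_count(height, "height")
  channels <- as_count(channels, "channels")
  dtype <- match.arg(dtype, c("uint8", "uint16"))
  if (is.null(blobs)) blobs <- rep(list(empty_blobs()), channels)
  if (length(blobs) != channels)
    stop_invalid_input("blobs must have one element per channel")
  mx <- dtype_max(dtype)
  for (b in blobs) {
    if (nrow(b) == 0L) next
    if (any(b$cy < 0) || any(b$cy >= height) || any(b$cx < 0) || any(b$cx >= width))
      stop_invalid_input("blob center out of image bounds")
    if (any(abs(b$peak) > mx))
      stop_invalid_input(sprintf("blob peak exceeds %s range", dtype))
    if (any(b$radius <= 0)) stop_invalid_input("blob radius must be positive")
  }
  structure(list(width = width, height = height, channels = channels,
                 dtype = dtype, seed = as_count(seed, "seed"),
                 background = background, noise_sd = noise_sd, blobs = blobs,
                 pixel_kind = pixel_kind),
            class = "fixture_spec")
}

empty_blobs <- function() data.frame(cy = numeric(0), cx = numeric(0),
                                     radius = numeric(0), peak = numeric(0))

blob_df <- function(cy, cx, radius, peak) data.frame(cy = cy, cx = cx,
                                                     radius = radius, peak = peak)

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the synthetic image described by a fixture spec
#'
#' Each channel is `background + sum of Gaussian blobs + N(0, noise_sd)`,
#' rounded and clipped to the dtype range. Blob profiles are
#' `peak * exp(-d^2 / (2 * sigma^2))` with `sigma = radius / 3`, truncated
#' at `radius`. Identical seeds give bit-identical images.
#'
#' @param spec a [fixture_spec()].
#' @return a [raster_image()].
#' @export
make_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mx <- dtype_max(spec$dtype)
  bg <- spec$background
  if (length(bg) == 1L) bg <- rep(bg, spec$channels)
  pixels <- array(0L, dim = c(spec$channels, spec$height, spec$width))
  with_seed(spec$seed, {
    for (ch in seq_len(spec$channels)) {
      plane <- matrix(as.numeric(bg[ch]), spec$height, spec$width)
      b <- spec$blobs[[ch]]
      for (i in seq_len(nrow(b)))
        plane <- add_blob(plane, b$cy[i], b$cx[i], b$radius[i], b$peak[i])
      if (spec$noise_sd > 0)
        plane <- plane + matrix(stats::rnorm(length(plane), 0, spec$noise_sd),
                                nrow(plane), ncol(plane))
      pixels[ch, , ] <- as.integer(pmin(pmax(floor(plane + 0.5), 0), mx))
    }
  })
  raster_image(pixels,
               channel_names = default_channel_names(spec$channels, spec$pixel_kind),
               pixel_kind = spec$pixel_kind, dtype = spec$dtype)
}

add_blob <- function(plane, cy, cx, radius, peak) {
  h <- nrow(plane); w <- ncol(plane)
  ys <- max(0, floor(cy - radius)):min(h - 1, ceiling(cy + radius))
  xs <- max(0, floor(cx - radius)):min(w - 1, ceiling(cx + radius))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  sigma <- radius / 3
  g <- peak * exp(-d2 / (2 * sigma^2))
  g[d2 > radius^2] <- 0
  plane[ys + 1L, xs + 1L] <- plane[ys + 1L, xs + 1L] + g
  plane
}

#' Write a fixture image as a multi-page TIFF
#'
#' Fluorescence/grayscale images are written one page per channel;
#' brightfield RGB images as a single interleaved RGB page. Lossless: the
#' file read back through [read_tiff_image()] equals the input.
#'
#' @param image a [raster_image()] (or a [fixture_spec()], which is
#'   generated first).
#' @param path output file.
#' @export
make_tiff <- function(image, path) {
  if (inherits(image, "fixture_spec")) image <- make_image(image)
  stopifnot(inherits(image, "raster_image"))
  mx <- dtype_max(image$dtype)
  bits <- if (image$dtype == "uint16") 16L else 8L
  d <- dim(image$pixels)
  if (image$pixel_kind == "brightfield_rgb") {
    page <- array(0, dim = c(d[2L], d[3L], 3L))
    for (k in 1:3) page[, , k] <- image$pixels[k, , ] / mx
    what <- page
  } else {
    what <- lapply(seq_len(d[1L]), function(ch)
      matrix(image$pixels[ch, , ], d[2L], d[3L]) / mx)
  }
  ok <- tryCatch(tiff::writeTIFF(what, path, bits.per.sample = bits,
                                 compression = "none"),
                 error = function(e) stop_io_error(
                   sprintf("cannot write TIFF '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' Built-in fixture presets
#'
#' * `small` — 512 x 512, 4 channels, uint16; a few bright blobs per
#'   channel. The workhorse for unit tests.
#' * `tma` — 4096 x 4096, 8 channels, uint16; a 6 x 6 grid of blob clusters
#'   mimicking a tissue-microarray mosaic, each core lighting a
#'   deterministic pair of channels. Used by the bandwidth harness.
#' * `he` — 2048 x 2048 RGB, uint8, brightfield; dark tissue-like blobs on
#'   a pale pink background, standing in for an H&E scan.
#'
#' @param preset `"small"`, `"tma"` or `"he"`.
#' @param seed RNG seed for the noise field.
#' @return a [fixture_spec()].
#' @export
fixture_preset <- function(preset = c("small", "tma", "he"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    small = {
      blobs <- list(
        blob_df(cy = c(100, 300, 420), cx = c(120, 260, 60),
                radius = c(30, 40, 25), peak = c(20000, 32000, 15000)),
        blob_df(cy = c(80, 400), cx = c(380, 430), radius = c(35, 30),
                peak = c(28000, 18000)),
        blob_df(cy = 256, cx = 256, radius = 60, peak = 40000),
        blob_df(cy = c(50, 200, 460), cx = c(50, 480, 250),
                radius = c(20, 30, 35), peak = c(12000, 25000, 30000)))
      fixture_spec(512, 512, 4, dtype = "uint16", seed = seed,
                   background = 200, noise_sd = 30, blobs = blobs)
    },
    tma = {
      # 6 x 6 cores on a 640 px pitch; core (i, j) lights channels
      # (i + j) %% 8 and (i + 2 * j + 1) %% 8
      blobs <- rep(list(empty_blobs()), 8L)
      for (i in 0:5) for (j in 0:5) {
        cy <- 448 + i * 640; cx <- 448 + j * 640
        for (ch in unique(c((i + j) %% 8, (i + 2 * j + 1) %% 8))) {
          blobs[[ch + 1L]] <- rbind(blobs[[ch + 1L]],
            blob_df(cy = cy, cx = cx, radius = 150, peak = 30000),
            blob_df(cy = cy - 90, cx = cx + 70, radius = 60, peak = 22000))
        }
      }
      fixture_spec(4096, 4096, 8, dtype = "uint16", seed = seed,
                   background = 100, noise_sd = 20, blobs = blobs)
    },
    he = {
      tissue <- blob_df(cy = c(500, 700, 1300, 1500, 1000),
                        cx = c(600, 1400, 500, 1500, 1024),
                        radius = c(300, 260, 280, 240, 350),
                        peak = c(-70, -60, -80, -55, -40))
      darker <- function(f) { b <- tissue; b$peak <- round(b$peak * f); b }
      fixture_spec(2048, 2048, 3, dtype = "uint8", seed = seed,
                   background = c(238, 222, 233), noise_sd = 4,
                   blobs = list(darker(0.6), darker(1.0), darker(0.7)),
                   pixel_kind = "brightfield_rgb")
    })
}
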
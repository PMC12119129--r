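# Minimal NGFF (OME-ZARR) multiscale store, zarr v2 on-disk layout.
#
# Layout written by write_store():
#   <path>/.zgroup                  {"zarr_format": 2}
#   <path>/.zattrs                  NGFF 0.4 "multiscales" + "omero" + image tags
#   <path>/<p>/.zarray              one zarr array per level p = 0..n-1
#   <path>/<p>/<c>.<by>.<bx>        raw uncompressed chunks, C order, little endian
#
# Chunks are (1, chunk_h, chunk_w): never spanning channels, so serving k
# channels of a tile reads chunks of exactly k channels. Edge chunks are
# stored full-size, zero padded (zarr convention).

zarr_dtype <- function(dtype) switch(dtype, uint8 = "|u1", uint16 = "<u2")
dtype_from_zarr <- function(zd) {
  switch(zd, "|u1" = "uint8", "<u2" = "uint16", "u1" = "uint8",
         stop_store_error(sprintf("unsupported zarr dtype '%s' (uint8/uint16 only)", zd)))
}

#' Write a pyramid to an NGFF multiscale store
#'
#' Serializes an [build_pyramid()] result as an OME-ZARR (NGFF 0.4) group:
#' one zarr array per level with axes `(c, y, x)`, factor-2 scale metadata
#' per level, and channel names in `omero` metadata. Chunks are raw
#' (uncompressed), per-channel, little endian. The write is atomic at the
#' caller's level of [convert_job()]; `write_store` itself refuses to write
#' over a directory that is not a pyramid store.
#'
#' @param pyramid an `image_pyramid`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_store <- function(pyramid, path) {
  stopifnot(inherits(pyramid, "image_pyramid"))
  if (file.exists(path)) {
    if (!dir.exists(path) || !file.exists(file.path(path, ".zattrs")))
      tf_stop(sprintf("'%s' exists and is not a pyramid store; refusing to overwrite", path),
              "tf_collision")
    unlink(path, recursive = TRUE)
  }
  if (!dir.create(path, recursive = TRUE))
    stop_io_error(sprintf("cannot create store directory '%s'", path))
  np <- length(pyramid$levels)
  datasets <- lapply(seq_len(np) - 1L, function(p) list(
    path = as.character(p),
    coordinateTransformations = list(list(type = "scale", scale = c(1, 2^p, 2^p)))))
  attrs <- list(
    multiscales = list(list(
      version = "0.4",
      name = "image",
      axes = list(list(name = "c", type = "channel"),
                  list(name = "y", type = "space", unit = "pixel"),
                  list(name = "x", type = "space", unit = "pixel")),
      datasets = datasets,
      type = "mean")),
    omero = list(channels = lapply(pyramid$channel_names, function(nm) list(label = nm))),
    image = list(pixel_kind = pyramid$pixel_kind, dtype = pyramid$dtype,
                 channel_names = as.list(pyramid$channel_names)))
  write_json_file(list(zarr_format = 2L), file.path(path, ".zgroup"))
  write_json_file(attrs, file.path(path, ".zattrs"))
  ch <- pyramid$chunk_shape[2L]; cw <- pyramid$chunk_shape[3L]
  for (p in seq_len(np) - 1L) {
    lv <- pyramid$levels[[p + 1L]]
    d <- dim(lv)
    lp <- file.path(path, as.character(p))
    dir.create(lp)
    write_json_file(list(
      zarr_format = 2L, shape = d, chunks = c(1L, ch, cw),
      dtype = zarr_dtype(pyramid$dtype), compressor = NULL, fill_value = 0L,
      order = "C", filters = NULL, dimension_separator = "."),
      file.path(lp, ".zarray"), null = "null")
    write_level_chunks(lv, lp, ch, cw, pyramid$dtype)
  }
  invisible(path)
}

write_json_file <- function(x, path, null = "list") {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, null = null, digits = NA)
  writeLines(txt, path)
}

write_level_chunks <- function(lv, level_path, ch, cw, dtype) {
  d <- dim(lv)
  nby <- ceiling(d[2L] / ch); nbx <- ceiling(d[3L] / cw)
  for (c0 in seq_len(d[1L]) - 1L) {
    plane <- matrix(lv[c0 + 1L, , ], d[2L], d[3L])
    for (by in seq_len(nby) - 1L) {
      ys <- by * ch + 1L; ye <- min((by + 1L) * ch, d[2L])
      for (bx in seq_len(nbx) - 1L) {
        xs <- bx * cw + 1L; xe <- min((bx + 1L) * cw, d[3L])
        block <- matrix(0L, ch, cw)
        block[seq_len(ye - ys + 1L), seq_len(xe - xs + 1L)] <-
          plane[ys:ye, xs:xe, drop = FALSE]
        f <- file.path(level_path, paste(c0, by, bx, sep = "."))
        con <- file(f, "wb")
        # C order = x fastest; R fills column-major, so transpose first
        v <- as.integer(t(block))
        if (dtype == "uint8") writeBin(as.raw(v), con)
        else writeBin(v, con, size = 2L, endian = "little")
        close(con)
      }
    }
  }
}

#' Open an NGFF multiscale store lazily
#'
#' Reads only the JSON metadata (`.zattrs`, `.zarray` per level) and returns
#' a lazy handle; no pixel chunk is touched until [read_region()] is called.
#' The store must be a conforming subset of NGFF: axes `(c, y, x)`, unsigned
#' 8/16-bit samples, uncompressed chunks that do not span channels, and
#' factor-2 levels obeying the ceiling shape law.
#'
#' @param path store directory written by [write_store()].
#' @return an object of class `pyramid_store` supporting [n_levels()],
#'   [level_shape()], [read_region()], [store_access_log()].
#' @export
read_store <- function(path) {
  if (!dir.exists(path)) stop_store_error(sprintf("no store at '%s'", path))
  zattrs_path <- file.path(path, ".zattrs")
  if (!file.exists(zattrs_path))
    stop_store_error(sprintf("malformed store '%s': missing .zattrs", path))
  attrs <- jsonlite::fromJSON(zattrs_path, simplifyVector = FALSE)
  ms <- attrs$multiscales
  if (is.null(ms) || length(ms) < 1L)
    stop_store_error(sprintf("malformed store '%s': no multiscales metadata", path))
  ms <- ms[[1L]]
  ax <- vapply(ms$axes, function(a) a$name, character(1))
  if (!identical(ax, c("c", "y", "x")))
    stop_store_error(sprintf("unsupported axes (%s): need (c, y, x)",
                             paste(ax, collapse = ",")))
  ds_paths <- vapply(ms$datasets, function(d) d$path, character(1))
  if (length(ds_paths) < 1L) stop_store_error("multiscales lists no datasets")
  levels <- lapply(ds_paths, function(dp) {
    za_path <- file.path(path, dp, ".zarray")
    if (!file.exists(za_path))
      stop_store_error(sprintf("malformed store: missing %s/.zarray", dp))
    za <- jsonlite::fromJSON(za_path, simplifyVector = TRUE)
    if (!is.null(za$compressor))
      stop_store_error("unsupported layout: compressed chunks")
    if (!identical(za$order, "C")) stop_store_error("unsupported layout: non-C chunk order")
    sep <- if (is.null(za$dimension_separator)) "." else za$dimension_separator
    if (length(za$shape) != 3L || length(za$chunks) != 3L)
      stop_store_error("unsupported layout: arrays must be 3-D (c, y, x)")
    if (za$chunks[1L] != 1L)
      stop_store_error("unsupported layout: chunks must not span channels")
    list(path = file.path(path, dp), shape = as.integer(za$shape),
         chunks = as.integer(za$chunks), dtype = dtype_from_zarr(za$dtype), sep = sep)
  })
  shape0 <- levels[[1L]]$shape
  for (p in seq_along(levels) - 1L) {
    sh <- levels[[p + 1L]]$shape
    expect <- c(shape0[1L], ceiling(shape0[2L] / 2^p), ceiling(shape0[3L] / 2^p))
    if (!identical(sh, as.integer(expect)))
      stop_store_error(sprintf(
        "inconsistent store: level %d has shape (%s), expected (%s) for factor-2 multiscale",
        p, paste(sh, collapse = ","), paste(expect, collapse = ",")))
    if (levels[[p + 1L]]$dtype != levels[[1L]]$dtype)
      stop_store_error("inconsistent store: dtype differs across levels")
  }
  img <- attrs$image
  channel_names <-
    if (!is.null(img$channel_names)) unlist(img$channel_names)
    else if (!is.null(attrs$omero)) vapply(attrs$omero$channels, function(c) c$label, character(1))
    else paste0("CH", seq_len(shape0[1L]) - 1L)
  if (length(channel_names) != shape0[1L])
    stop_store_error("inconsistent store: channel name count != channel count")
  access <- new.env(parent = emptyenv())
  access$chunks <- character(0)
  structure(list(path = path, levels = levels,
                 base_width = shape0[3L], base_height = shape0[2L],
                 channel_names = channel_names,
                 pixel_kind = if (!is.null(img$pixel_kind)) img$pixel_kind else "fluorescence",
                 dtype = levels[[1L]]$dtype,
                 access = access),
            class = "pyramid_store")
}

#' @export
n_levels.pyramid_store <- function(pyramid) length(pyramid$levels)

#' @export
level_shape.pyramid_store <- function(pyramid, level) {
  level <- check_level(pyramid, level)
  pyramid$levels[[level + 1L]]$shape[2:3]
}

#' @export
read_region.pyramid_store <- function(pyramid, level, y0, x0, y1, x1, channels) {
  q <- check_region(pyramid, level, y0, x0, y1, x1, channels)
  meta <- pyramid$levels[[q$level + 1L]]
  ch <- meta$chunks[2L]; cw <- meta$chunks[3L]
  out <- array(0L, dim = c(length(q$channels), q$y1 - q$y0, q$x1 - q$x0))
  by_range <- (q$y0 %/% ch):((q$y1 - 1L) %/% ch)
  bx_range <- (q$x0 %/% cw):((q$x1 - 1L) %/% cw)
  for (i in seq_along(q$channels)) {
    c0 <- q$channels[i]
    for (by in by_range) {
      for (bx in bx_range) {
        block <- read_chunk(pyramid, q$level, c0, by, bx)
        # intersection of chunk extent with the request, in level coords
        ys <- max(q$y0, by * ch); ye <- min(q$y1, (by + 1L) * ch)
        xs <- max(q$x0, bx * cw); xe <- min(q$x1, (bx + 1L) * cw)
        out[i, (ys - q$y0 + 1L):(ye - q$y0), (xs - q$x0 + 1L):(xe - q$x0)] <-
          block[(ys - by * ch + 1L):(ye - by * ch),
                (xs - bx * cw + 1L):(xe - bx * cw), drop = FALSE]
      }
    }
  }
  out
}

read_chunk <- function(store, level, c0, by, bx) {
  meta <- store$levels[[level + 1L]]
  key <- paste0(level, "/", paste(c0, by, bx, sep = "."))
  store$access$chunks <- c(store$access$chunks, key)
  f <- file.path(meta$path, paste(c0, by, bx, sep = meta$sep))
  if (!file.exists(f))
    stop_store_error(sprintf("malformed store: missing chunk %s", key))
  ch <- meta$chunks[2L]; cw <- meta$chunks[3L]
  n <- ch * cw
  con <- file(f, "rb")
  on.exit(close(con))
  v <- if (meta$dtype == "uint8") as.integer(readBin(con, "raw", n = n))
       else readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "little")
  if (length(v) != n) stop_store_error(sprintf("truncated chunk %s", key))
  t(matrix(v, cw, ch))   # stored C order (x fastest) -> (y, x) matrix
}

#' Chunk access log of a store handle
#'
#' Every chunk read through [read_region()] is recorded as
#' `"<level>/<channel>.<block_y>.<block_x>"`. Used to verify the laziness and
#' chunk-frugality contracts: opening a store reads nothing, and a k-channel
#' tile request touches chunks of exactly k channels.
#'
#' @param store a `pyramid_store`.
#' @return character vector of chunk keys in access order.
#' @export
store_access_log <- function(store) store$access$chunks

#' Reset the chunk access log
#' @param store a `pyramid_store`.
#' @export
store_reset_access <- function(store) {
  store$access$chunks <- character(0)
  invisible(store)
}

#' @export
print.pyramid_store <- function(x, ...) {
  cat(sprintf("<pyramid_store> %s\n  %d x %d px, %d channel(s), %s, %d level(s)\n",
              x$path, x$base_width, x$base_height, length(x$channel_names),
              x$dtype, n_levels(x)))
  invisible(x)
}
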
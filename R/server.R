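# HTTP-facing tile service. Handlers are pure functions over immutable
# stores: any number may run at once; the manifest is the only mutable state
# (owned by the ingest module). The channel spec travels in the query string
# of every tile request, so the server is stateless and responses are
# cacheable byte-for-byte.

#' Parse the wire encoding of a channel spec
#'
#' Grammar (bit-exact): comma-separated entries, each
#' `<channel>:<RRGGBB hex>:<low>:<high>`, e.g.
#' `0:FF0000:0:4095,3:00FF00:100:2000`. Entry order is preserved for mixing
#' (which is order-independent anyway); cache keys use a canonical form
#' sorted by channel.
#'
#' @param query_value the `spec=` query parameter.
#' @return a [render_spec()] in additive mode.
#' @export
parse_spec <- function(query_value) {
  if (!is.character(query_value) || length(query_value) != 1L || !nzchar(query_value))
    stop_bad_request("empty channel spec")
  parts <- strsplit(query_value, ",", fixed = TRUE)[[1L]]
  entries <- vector("list", length(parts))
  seen <- integer(0)
  for (i in seq_along(parts)) {
    f <- strsplit(parts[i], ":", fixed = TRUE)[[1L]]
    ctx <- sprintf("spec entry %d ('%s')", i - 1L, parts[i])
    if (length(f) != 4L)
      stop_bad_request(sprintf("%s: expected <channel>:<RRGGBB>:<low>:<high>", ctx))
    if (!grepl("^[0-9]+$", f[1L]))
      stop_bad_request(sprintf("%s: channel must be a non-negative integer", ctx))
    chan <- as.integer(f[1L])
    if (chan %in% seen)
      stop_bad_request(sprintf("%s: duplicate channel %d", ctx, chan))
    seen <- c(seen, chan)
    if (!grepl("^[0-9A-Fa-f]{6}$", f[2L]))
      stop_bad_request(sprintf("%s: color must be 6 hex digits", ctx))
    color <- strtoi(substring(f[2L], c(1L, 3L, 5L), c(2L, 4L, 6L)), base = 16L)
    if (!grepl("^[0-9]+$", f[3L]) || !grepl("^[0-9]+$", f[4L]))
      stop_bad_request(sprintf("%s: window bounds must be non-negative integers", ctx))
    low <- as.integer(f[3L]); high <- as.integer(f[4L])
    if (low >= high)
      stop_bad_request(sprintf("%s: low >= high (%d >= %d)", ctx, low, high))
    entries[[i]] <- channel_render(chan, color, low, high)
  }
  render_spec(entries, mode = "additive")
}

#' Serialize a render spec in the wire grammar
#' @param spec a [render_spec()].
#' @param canonical sort entries by channel (used for cache keys).
#' @export
format_spec <- function(spec, canonical = FALSE) {
  entries <- spec$entries
  if (canonical) entries <- entries[order(vapply(entries, `[[`, integer(1), "channel"))]
  paste(vapply(entries, function(e)
    sprintf("%d:%02X%02X%02X:%d:%d", e$channel, e$color[1L], e$color[2L], e$color[3L],
            e$low, e$high), character(1)), collapse = ",")
}

#' Server configuration
#'
#' @param data_root directory holding the manifest and pyramid stores.
#' @param port TCP port for [cmd_serve()].
#' @param tile_size,overlap DZI geometry served to viewers.
#' @param cache_size maximum tiles held in the LRU tile cache; 0 disables
#'   caching (correctness never depends on the cache).
#' @param jpeg_quality JPEG quality for `fmt=jpeg` tiles.
#' @param log_level `"info"` logs one line per request; `"quiet"` disables.
#' @param json_logs emit request logs as JSON objects instead of key=value.
#' @export
tileforge_config <- function(data_root = ".", port = 8080L, tile_size = 256L,
                             overlap = 1L, cache_size = 512L, jpeg_quality = 90L,
                             log_level = "info", json_logs = FALSE) {
  dzi_descriptor(16L, 16L, tile_size, overlap)  # validates tile_size/overlap
  list(data_root = data_root, port = as_count(port, "port"),
       tile_size = as_count(tile_size, "tile_size"),
       overlap = as_count(overlap, "overlap"),
       cache_size = as_count(cache_size, "cache_size"),
       jpeg_quality = as_count(jpeg_quality, "jpeg_quality"),
       log_level = log_level, json_logs = isTRUE(json_logs))
}

#' Load configuration from a JSON file with optional overrides
#' @param path JSON file of config keys (see [tileforge_config()]); may be
#'   `NULL` for all defaults.
#' @param overrides named list of values taking precedence over the file.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io_error(sprintf("config file '%s' not found", path))
    vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  vals[names(overrides)] <- overrides
  do.call(tileforge_config, vals[names(vals) %in% names(formals(tileforge_config))])
}

#' Tile-serving application state
#'
#' Binds a data root (manifest + stores) to a server configuration. Stores
#' are opened lazily on first request and kept open; the tile cache is a
#' bounded LRU keyed by the canonical request string.
#'
#' @param config a [tileforge_config()].
#' @return object of class `tile_app`.
#' @export
tile_app <- function(config = tileforge_config()) {
  app <- new.env(parent = emptyenv())
  app$config <- config
  app$manifest <- read_manifest(config$data_root)
  app$stores <- new.env(parent = emptyenv())
  app$cache <- new_tile_cache(config$cache_size)
  class(app) <- "tile_app"
  app
}

#' @export
print.tile_app <- function(x, ...) {
  cat(sprintf("<tile_app> data root '%s', %d image(s), tile %d/overlap %d, cache %d\n",
              x$config$data_root, length(ready_ids(x$manifest)), x$config$tile_size,
              x$config$overlap, x$config$cache_size))
  invisible(x)
}

app_store <- function(app, image_id) {
  entry <- manifest_entry(app$manifest, image_id)
  if (is.null(entry) || !identical(entry$status, "ready"))
    stop_not_found(sprintf("unknown image '%s'", image_id))
  if (is.null(app$stores[[image_id]]))
    app$stores[[image_id]] <- read_store(file.path(app$config$data_root, entry$store))
  app$stores[[image_id]]
}

app_descriptor <- function(app, image_id, fmt = NULL) {
  store <- app_store(app, image_id)
  if (is.null(fmt))
    fmt <- if (store$pixel_kind == "brightfield_rgb") "jpeg" else "png"
  dzi_descriptor(store$base_width, store$base_height,
                 tile_size = app$config$tile_size, overlap = app$config$overlap,
                 tile_format = fmt)
}

#' Catalog of served images
#'
#' One entry per ready manifest image, ordered by `image_id`.
#'
#' @param app a [tile_app()].
#' @return list of lists with `image_id`, `width`, `height`,
#'   `channel_names`, `pixel_kind`.
#' @export
handle_catalog <- function(app) {
  ids <- sort(ready_ids(app$manifest))
  lapply(ids, function(id) {
    e <- manifest_entry(app$manifest, id)
    list(image_id = id, width = e$width, height = e$height,
         channel_names = e$channel_names, pixel_kind = e$pixel_kind)
  })
}

#' DZI descriptor endpoint
#' @param app a [tile_app()].
#' @param image_id registered image identifier.
#' @param fmt tile format advertised in the descriptor (default: png for
#'   fluorescence, jpeg for brightfield).
#' @return DZI XML text.
#' @export
handle_descriptor <- function(app, image_id, fmt = NULL) {
  descriptor_xml(app_descriptor(app, image_id, fmt))
}

#' Render one DZI tile on demand
#'
#' The request pipeline: map the DZI level to a stored pyramid level, scale
#' the tile bounds to that level, read only the requested channels' chunks
#' intersecting those bounds, apply the residual area-mean downscale, mix
#' the channels, and encode. Responses are byte-identical for identical
#' requests; with caching enabled a repeat request is served from the LRU
#' cache (`cache_hit` in the result).
#'
#' @param app a [tile_app()].
#' @param image_id registered image identifier.
#' @param level,col,row DZI tile address.
#' @param spec a [render_spec()] or a wire-grammar string (see
#'   [parse_spec()]).
#' @param fmt `"png"` or `"jpeg"`.
#' @param use_cache set `FALSE` to bypass the tile cache.
#' @return list with `body` (raw bytes), `content_type`, `cache_hit`.
#' @export
handle_tile <- function(app, image_id, level, col, row, spec, fmt = "png",
                        use_cache = TRUE) {
  if (is.character(spec)) spec <- parse_spec(spec)
  stopifnot(inherits(spec, "render_spec"))
  if (!fmt %in% c("png", "jpeg"))
    stop_bad_request(sprintf("unsupported tile format '%s'", fmt))
  store <- app_store(app, image_id)
  nc <- length(store$channel_names)
  chans <- spec_channels(spec)
  if (any(chans >= nc))
    stop_bad_request(sprintf("channel %d out of range: image has %d channel(s)",
                             max(chans), nc))
  key <- paste(image_id, level, col, row, fmt, format_spec(spec, canonical = TRUE),
               sep = "|")
  if (use_cache) {
    hit <- cache_get(app$cache, key)
    if (!is.null(hit))
      return(list(body = hit, content_type = content_type_of(fmt), cache_hit = TRUE))
  }
  desc <- app_descriptor(app, image_id, fmt)
  raster <- render_dzi_region_tile(store, desc, level, col, row, spec)
  body <- encode_tile(raster, fmt, quality = app$config$jpeg_quality)
  if (use_cache) cache_set(app$cache, key, body)
  list(body = body, content_type = content_type_of(fmt), cache_hit = FALSE)
}

content_type_of <- function(fmt) switch(fmt, png = "image/png", jpeg = "image/jpeg")

# Multichannel source pixels of a DZI-level window, synthesized from the
# stored pyramid: read at the mapped level, then residual 2x halvings.
# Returns (n_channels, h, w) in `channels` order.
read_dzi_region <- function(store, desc, level, y0, x0, y1, x1, channels) {
  mp <- map_to_pyramid(desc, store, level)
  r <- mp$residual_factor
  phw <- level_shape(store, mp$pyramid_level)
  reg <- read_region(store, mp$pyramid_level,
                     y0 * r, x0 * r, min(y1 * r, phw[1L]), min(x1 * r, phw[2L]),
                     channels)
  while (r > 1L) {
    reg <- downsample_level(reg)
    r <- r %/% 2L
  }
  reg
}

render_dzi_region_tile <- function(store, desc, level, col, row, spec) {
  b <- tile_bounds(desc, level, col, row)
  render_dzi_window(store, desc, level, b[["y0"]], b[["x0"]], b[["y1"]], b[["x1"]], spec)
}

# Window render shared by the tile endpoint and cmd_render (one code path).
render_dzi_window <- function(store, desc, level, y0, x0, y1, x1, spec) {
  effective <- effective_spec(store, spec)
  planes <- read_dzi_region(store, desc, level, y0, x0, y1, x1,
                            spec_channels(effective))
  mix_channels(planes, effective)
}

# Brightfield RGB images requested with the identity mapping (channels
# 0,1,2 -> pure R,G,B tints) are composited in rgb_passthrough mode;
# everything else uses additive blending.
effective_spec <- function(store, spec) {
  if (store$pixel_kind != "brightfield_rgb" || spec$mode != "additive") return(spec)
  chans <- spec_channels(spec)
  if (!identical(chans, 0:2)) return(spec)
  ident <- all(vapply(seq_len(3L), function(i) {
    col <- spec$entries[[i]]$color
    all(col == c(255L, 255L, 255L) * (seq_len(3L) == i))
  }, logical(1)))
  if (ident) render_spec(spec$entries, mode = "rgb_passthrough") else spec
}

# --- request router ---------------------------------------------------------

#' Dispatch one HTTP request path to a handler
#'
#' Endpoint layout (bit-exact, matching what DZI viewers construct):
#' `GET /images` (catalog JSON), `GET /images/{id}.dzi?fmt=` (descriptor
#' XML), `GET /images/{id}_files/{level}/{col}_{row}.{fmt}?spec=` (tile).
#'
#' @param app a [tile_app()].
#' @param path URL path.
#' @param query named list of query parameters.
#' @return list with `status`, `content_type`, `body` (character or raw),
#'   and for tiles `cache_hit`.
#' @export
handle_request <- function(app, path, query = list()) {
  res <- tryCatch({
    if (path == "/images") {
      list(status = 200L, content_type = "application/json",
           body = as.character(jsonlite::toJSON(handle_catalog(app),
                                                auto_unbox = TRUE)))
    } else if (grepl("^/images/[^/]+\\.dzi$", path)) {
      id <- sub("^/images/(.+)\\.dzi$", "\\1", path)
      fmt <- query$fmt
      if (!is.null(fmt) && !fmt %in% c("png", "jpeg"))
        stop_bad_request(sprintf("unsupported fmt '%s'", fmt))
      list(status = 200L, content_type = "application/xml",
           body = handle_descriptor(app, id, fmt))
    } else if (grepl("^/images/.+_files/[0-9]+/[0-9]+_[0-9]+\\.(png|jpeg)$", path)) {
      m <- regmatches(path,
        regexec("^/images/(.+)_files/([0-9]+)/([0-9]+)_([0-9]+)\\.(png|jpeg)$", path))[[1L]]
      if (is.null(query$spec)) stop_bad_request("missing spec query parameter")
      tile <- handle_tile(app, m[2L], as.integer(m[3L]), as.integer(m[4L]),
                          as.integer(m[5L]), query$spec, fmt = m[6L])
      log_request(app, m[2L], as.integer(m[3L]), as.integer(m[4L]), as.integer(m[5L]),
                  query$spec, length(tile$body), tile$cache_hit)
      c(list(status = 200L), tile)
    } else {
      stop_not_found(sprintf("no route for '%s'", path))
    }
  },
  tf_bad_request = function(e) error_response(400L, e),
  tf_not_found = function(e) error_response(404L, e),
  tf_error = function(e) error_response(500L, e))
  res
}

error_response <- function(status, e) {
  list(status = status, content_type = "text/plain",
       body = paste0(conditionMessage(e), "\n"))
}

log_request <- function(app, id, level, col, row, spec, bytes, cache_hit) {
  if (identical(app$config$log_level, "quiet")) return(invisible())
  if (app$config$json_logs) {
    line <- as.character(jsonlite::toJSON(list(
      image = id, level = level, col = col, row = row, spec = spec,
      bytes = bytes, cache_hit = cache_hit), auto_unbox = TRUE))
  } else {
    line <- sprintf("tile image=%s level=%d col=%d row=%d spec=%s bytes=%d cache_hit=%s",
                    id, level, col, row, spec, bytes, tolower(cache_hit))
  }
  cat(line, "\n", file = stderr(), sep = "")
  invisible()
}

# --- bounded LRU tile cache -------------------------------------------------

new_tile_cache <- function(max_size) {
  cache <- new.env(parent = emptyenv())
  cache$store <- new.env(parent = emptyenv(), hash = TRUE)
  cache$order <- character(0)      # least recently used first
  cache$max <- max_size
  cache$hits <- 0L
  cache$misses <- 0L
  cache
}

cache_get <- function(cache, key) {
  if (cache$max <= 0L) return(NULL)
  val <- cache$store[[key]]
  if (is.null(val)) {
    cache$misses <- cache$misses + 1L
    return(NULL)
  }
  cache$hits <- cache$hits + 1L
  cache$order <- c(setdiff(cache$order, key), key)
  val
}

cache_set <- function(cache, key, value) {
  if (cache$max <= 0L) return(invisible())
  if (is.null(cache$store[[key]])) {
    while (length(cache$order) >= cache$max) {
      rm(list = cache$order[1L], envir = cache$store)
      cache$order <- cache$order[-1L]
    }
  } else {
    cache$order <- setdiff(cache$order, key)
  }
  cache$store[[key]] <- value
  cache$order <- c(cache$order, key)
  invisible()
}

#' Tile cache statistics
#' @param app a [tile_app()].
#' @return list with `hits`, `misses`, `size`.
#' @export
cache_stats <- function(app) {
  list(hits = app$cache$hits, misses = app$cache$misses,
       size = length(app$cache$order))
}
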
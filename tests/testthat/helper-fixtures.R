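# Test fixtures built in code: a registered tile app around an arbitrary
# raster image, with configurable pyramid/store geometry.

register_image <- function(manifest, id, img, data_root, chunk_h = 256L,
                           chunk_w = 256L, stop_size = 512L) {
  pyr <- build_pyramid(img, chunk_h = chunk_h, chunk_w = chunk_w,
                       stop_size = stop_size)
  write_store(pyr, file.path(data_root, paste0(id, ".zarr")))
  d <- dim(img$pixels)
  manifest$entries[[id]] <- list(
    store = paste0(id, ".zarr"), source = paste0(id, ".tif"),
    source_size = 0, source_mtime = 0, status = "ready", reason = NULL,
    width = d[3L], height = d[2L], channels = d[1L],
    channel_names = img$channel_names, pixel_kind = img$pixel_kind,
    dtype = img$dtype)
  manifest
}

make_test_app <- function(img, id = "img", tile_size = 256L, overlap = 1L,
                          cache_size = 512L, chunk_h = 256L, chunk_w = 256L,
                          stop_size = 512L, data_root = NULL) {
  if (is.null(data_root)) data_root <- withr::local_tempdir(.local_envir = parent.frame())
  dir.create(data_root, showWarnings = FALSE, recursive = TRUE)
  manifest <- register_image(new_manifest(), id, img, data_root,
                             chunk_h = chunk_h, chunk_w = chunk_w,
                             stop_size = stop_size)
  write_manifest(manifest, data_root)
  tile_app(tileforge_config(data_root = data_root, tile_size = tile_size,
                            overlap = overlap, cache_size = cache_size,
                            log_level = "quiet"))
}

# the seeded 1000 x 600 x 4 workhorse: blobs at known centers per channel
wide_fixture_spec <- function(seed = 42L, channels = 4L) {
  centers <- list(c(300, 700), c(150, 200), c(450, 850), c(100, 500))
  blobs <- lapply(seq_len(channels), function(ch) {
    cc <- centers[[ch]]
    data.frame(cy = cc[1L], cx = cc[2L], radius = 45, peak = 30000)
  })
  fixture_spec(1000L, 600L, channels, dtype = "uint16", seed = seed,
               background = 20, noise_sd = 5, blobs = blobs)
}

three_channel_wire_spec <- "0:FF0000:100:20000,1:00FF00:100:20000,2:0000FF:100:20000"

spec_channels_of <- function(spec) vapply(spec$entries, `[[`, integer(1), "channel")
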
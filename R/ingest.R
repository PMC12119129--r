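# Watch-folder ingestion: scan a folder for new TIFF/OME-TIFF files, convert
# each to a pyramid store, and keep the image manifest (the server's catalog)
# consistent. Conversion is atomic — stores are written under a temporary
# name and renamed on success — so a crash mid-write never leaves a "ready"
# entry pointing at a partial store, and a re-scan simply retries.

recognized_ext <- "\\.(ome\\.)?tiff?$"

#' Create an empty ingest manifest
#' @return object of class `ingest_manifest` with `entries` (image_id ->
#'   metadata, status one of pending/converting/ready/failed) and `watch`
#'   (per-file sizes observed by the previous poll, for growth detection).
#' @export
new_manifest <- function() {
  structure(list(entries = list(), watch = list()), class = "ingest_manifest")
}

manifest_entry <- function(manifest, image_id) manifest$entries[[image_id]]

ready_ids <- function(manifest) {
  ids <- names(manifest$entries)
  ids[vapply(manifest$entries, function(e) identical(e$status, "ready"), logical(1))]
}

manifest_path <- function(data_root) file.path(data_root, "manifest.json")

#' Read the manifest of a data root
#' @param data_root directory holding `manifest.json` and the stores.
#' @return an `ingest_manifest`; empty if none exists yet.
#' @export
read_manifest <- function(data_root) {
  p <- manifest_path(data_root)
  if (!file.exists(p)) return(new_manifest())
  raw <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  m <- new_manifest()
  m$entries <- lapply(raw$entries, function(e) {
    e$channel_names <- as.character(unlist(e$channel_names))
    e
  })
  m$watch <- raw$watch
  m
}

#' Persist a manifest atomically
#' @param manifest an `ingest_manifest`.
#' @param data_root directory to write `manifest.json` into.
#' @export
write_manifest <- function(manifest, data_root) {
  if (!dir.exists(data_root)) dir.create(data_root, recursive = TRUE)
  p <- manifest_path(data_root)
  tmp <- paste0(p, ".tmp")
  write_json_file(list(entries = manifest$entries, watch = manifest$watch), tmp,
                  null = "null")
  if (!file.rename(tmp, p)) stop_io_error(sprintf("cannot write manifest at '%s'", p))
  invisible(manifest)
}

#' @export
print.ingest_manifest <- function(x, ...) {
  cat(sprintf("<ingest_manifest> %d entr(ies)\n", length(x$entries)))
  for (id in names(x$entries)) {
    e <- x$entries[[id]]
    cat(sprintf("  %s [%s] %s\n", id, e$status,
                if (identical(e$status, "failed")) e$reason else e$source))
  }
  invisible(x)
}

#' Scan an ingestion folder once
#'
#' Files with recognized extensions (`.tif`, `.tiff`, `.ome.tif`,
#' `.ome.tiff`) that are not yet in the manifest become pending jobs. A file
#' whose size differs from what the previous poll recorded is considered
#' still growing and is skipped until its size stabilizes. Image ids are the
#' filename stem, deduplicated with a numeric suffix. Re-scanning an
#' unchanged folder yields no jobs; a source file whose size or mtime
#' changed after ingestion is re-queued.
#'
#' @param folder ingestion folder to scan.
#' @param manifest current `ingest_manifest`.
#' @return list with `manifest` (updated) and `jobs` (list of pending jobs
#'   for [convert_job()]).
#' @export
scan_once <- function(folder, manifest = new_manifest()) {
  if (!dir.exists(folder)) stop_io_error(sprintf("cannot read folder '%s'", folder))
  files <- list.files(folder, pattern = recognized_ext, ignore.case = TRUE)
  jobs <- list()
  for (f in files) {
    full <- file.path(folder, f)
    info <- file.info(full)
    if (is.na(info$size)) next
    existing_id <- source_entry_id(manifest, f)
    if (!is.null(existing_id)) {
      e <- manifest$entries[[existing_id]]
      unchanged <- identical(as.numeric(e$source_size), as.numeric(info$size)) &&
        identical(as.numeric(e$source_mtime), as.numeric(info$mtime))
      if (identical(e$status, "converting")) {
        # scan and convert run sequentially in one process, so a
        # "converting" entry seen here is a crash leftover: retry it
        manifest$entries[[existing_id]] <- NULL
      } else if (unchanged || identical(e$status, "pending")) {
        next
      } else {
        # source replaced since ingestion: re-queue through the watch list
        manifest$entries[[existing_id]] <- NULL
      }
    }
    prev <- manifest$watch[[f]]
    manifest$watch[[f]] <- list(size = as.numeric(info$size))
    if (!is.null(prev) && !identical(as.numeric(prev$size), as.numeric(info$size)))
      next   # still growing; wait for a stable poll
    id <- unique_image_id(manifest, f)
    manifest$entries[[id]] <- list(
      store = paste0(id, ".zarr"), source = f,
      source_size = as.numeric(info$size), source_mtime = as.numeric(info$mtime),
      status = "pending", reason = NULL,
      width = NULL, height = NULL, channels = NULL,
      channel_names = character(0), pixel_kind = NULL, dtype = NULL)
    jobs[[length(jobs) + 1L]] <- list(image_id = id, source = full)
  }
  list(manifest = manifest, jobs = jobs)
}

source_entry_id <- function(manifest, filename) {
  for (id in names(manifest$entries))
    if (identical(manifest$entries[[id]]$source, filename)) return(id)
  NULL
}

unique_image_id <- function(manifest, filename) {
  stem <- sub(recognized_ext, "", filename, ignore.case = TRUE)
  id <- stem; k <- 1L
  while (!is.null(manifest$entries[[id]])) {
    id <- sprintf("%s_%d", stem, k)
    k <- k + 1L
  }
  id
}

#' Convert one pending job to a pyramid store
#'
#' Reads the source TIFF, builds the pyramid, and writes the store under a
#' temporary name, renaming it into place only on success. The manifest
#' entry transitions pending -> converting -> ready (with dimensions and
#' channel metadata filled in) or failed (with a human-readable reason; a
#' corrupt file is a failed entry, not a crash). Once ready, the store is
#' authoritative: deleting the source file does not unregister the image.
#'
#' @param job one element of `scan_once()$jobs`.
#' @param manifest current `ingest_manifest`.
#' @param data_root directory for stores; the manifest is persisted here
#'   after every status transition.
#' @param chunk_h,chunk_w,stop_size pyramid parameters, see
#'   [build_pyramid()].
#' @return the updated manifest.
#' @export
convert_job <- function(job, manifest, data_root, chunk_h = 256L, chunk_w = 256L,
                        stop_size = 512L) {
  id <- job$image_id
  e <- manifest$entries[[id]]
  if (is.null(e)) stop_invalid_input(sprintf("job id '%s' not in manifest", id))
  e$status <- "converting"
  manifest$entries[[id]] <- e
  write_manifest(manifest, data_root)
  store_path <- file.path(data_root, e$store)
  tmp_path <- paste0(store_path, ".tmp-", Sys.getpid())
  result <- tryCatch({
    img <- read_tiff_image(job$source)
    pyr <- build_pyramid(img, chunk_h = chunk_h, chunk_w = chunk_w,
                         stop_size = stop_size)
    write_store(pyr, tmp_path)
    read_store(tmp_path)   # validates before publication
    if (dir.exists(store_path)) unlink(store_path, recursive = TRUE)
    if (!file.rename(tmp_path, store_path))
      stop_io_error(sprintf("cannot move store into place at '%s'", store_path))
    list(ok = TRUE, img = img)
  }, error = function(err) {
    unlink(tmp_path, recursive = TRUE)
    list(ok = FALSE, reason = conditionMessage(err))
  })
  if (result$ok) {
    d <- dim(result$img$pixels)
    e$status <- "ready"; e$reason <- NULL
    e$width <- d[3L]; e$height <- d[2L]; e$channels <- d[1L]
    e$channel_names <- result$img$channel_names
    e$pixel_kind <- result$img$pixel_kind
    e$dtype <- result$img$dtype
  } else {
    e$status <- "failed"
    e$reason <- result$reason
  }
  manifest$entries[[id]] <- e
  write_manifest(manifest, data_root)
  manifest
}

#' Read a TIFF / OME-TIFF into a raster image
#'
#' Multi-page TIFFs map pages to channels; a single RGB page becomes three
#' channels. OME-XML channel names in the image description are honored when
#' present, otherwise channels are named `CH0...`. A 3-channel 8-bit file
#' without OME channel metadata is classified `brightfield_rgb` (H&E-style
#' histology); everything else is `fluorescence`.
#'
#' @param path TIFF file.
#' @return a [raster_image()].
#' @export
read_tiff_image <- function(path) {
  if (!file.exists(path)) stop_io_error(sprintf("no such file '%s'", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) tf_stop(
                      sprintf("decode failed for '%s': %s", basename(path),
                              conditionMessage(e)), "tf_decode_error"),
                    warning = function(w) tf_stop(
                      sprintf("decode failed for '%s': %s", basename(path),
                              conditionMessage(w)), "tf_decode_error"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop_invalid_input(sprintf("'%s' has no pages", path))
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  desc_xml <- attr(pages[[1L]], "description")
  planes <- list()
  scaled <- logical(0)   # readTIFF returns multi-sample (RGB) pages in [0, 1]
  for (pg in pages) {
    d <- dim(pg)
    if (length(d) == 2L) {
      planes[[length(planes) + 1L]] <- pg
      scaled <- c(scaled, is.double(pg))
    } else {
      for (k in seq_len(d[3L])) {
        planes[[length(planes) + 1L]] <- pg[, , k]
        scaled <- c(scaled, is.double(pg))
      }
    }
  }
  h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
  for (pl in planes)
    if (nrow(pl) != h || ncol(pl) != w)
      stop_invalid_input(sprintf("'%s': pages have differing dimensions", path))
  nc <- length(planes)
  mx <- 2^bits - 1
  pixels <- array(0L, dim = c(nc, h, w))
  for (i in seq_len(nc)) {
    pl <- planes[[i]]
    # readTIFF honors as.is for grayscale pages only; anything it returned
    # as doubles is scaled to [0, 1] and must be mapped back to samples
    if (scaled[i]) pl <- floor(pl * mx + 0.5)
    pixels[i, , ] <- as.integer(pl)
  }
  ome_names <- ome_channel_names(desc_xml)
  dtype <- if (bits > 8L) "uint16" else "uint8"
  rgb_page <- length(pages) == 1L && length(dim(pages[[1L]])) == 3L &&
    dim(pages[[1L]])[3L] == 3L
  kind <- if (is.null(ome_names) && dtype == "uint8" && nc == 3L && rgb_page)
    "brightfield_rgb" else "fluorescence"
  names <- if (!is.null(ome_names) && length(ome_names) == nc) ome_names
           else default_channel_names(nc, kind)
  raster_image(pixels, channel_names = names, pixel_kind = kind, dtype = dtype)
}

# Channel names from an OME-XML image description, if present and parseable.
ome_channel_names <- function(desc_xml) {
  if (is.null(desc_xml) || !nzchar(desc_xml)) return(NULL)
  if (!grepl("<OME", desc_xml, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc_xml), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  ch <- xml2::xml_find_all(doc, "//*[local-name()='Channel']")
  if (length(ch) == 0L) return(NULL)
  nms <- xml2::xml_attr(ch, "Name")
  if (anyNA(nms)) return(NULL)
  nms
}
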
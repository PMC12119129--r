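test_that("scanning finds new TIFFs once and is idempotent", {
  folder <- withr::local_tempdir()
  root <- withr::local_tempdir()

  res0 <- scan_once(folder, new_manifest())
  expect_length(res0$jobs, 0L)
  expect_length(res0$manifest$entries, 0L)

  make_tiff(random_raster(40, 50, channels = 2, seed = 1),
            file.path(folder, "sampleA.tif"))
  res1 <- scan_once(folder, res0$manifest)
  expect_length(res1$jobs, 1L)
  expect_equal(res1$jobs[[1]]$image_id, "sampleA")
  expect_equal(res1$manifest$entries$sampleA$status, "pending")

  # pending entries are not re-queued
  res2 <- scan_once(folder, res1$manifest)
  expect_length(res2$jobs, 0L)

  m <- convert_job(res1$jobs[[1]], res1$manifest, root)
  expect_equal(m$entries$sampleA$status, "ready")
  # unchanged folder after conversion: still no jobs
  res3 <- scan_once(folder, m)
  expect_length(res3$jobs, 0L)

  # non-TIFF files are ignored
  writeLines("x", file.path(folder, "notes.txt"))
  expect_length(scan_once(folder, m)$jobs, 0L)
  expect_error(scan_once(file.path(folder, "missing"), m), class = "tf_io_error")
})

test_that("conversion produces a validated store with matching metadata", {
  folder <- withr::local_tempdir(); root <- withr::local_tempdir()
  img <- make_image(fixture_spec(120, 90, 4, dtype = "uint16", seed = 9,
                                 background = 10, noise_sd = 3))
  make_tiff(img, file.path(folder, "quad.ome.tif"))
  res <- scan_once(folder, new_manifest())
  expect_equal(res$jobs[[1]]$image_id, "quad")
  m <- convert_job(res$jobs[[1]], res$manifest, root)
  e <- m$entries$quad
  expect_equal(e$status, "ready")
  expect_equal(c(e$width, e$height, e$channels), c(120, 90, 4))
  st <- read_store(file.path(root, e$store))
  expect_identical(read_region(st, 0, 0, 0, 90, 120, 0:3), img$pixels)

  # the store is authoritative: deleting the source keeps the entry ready
  file.remove(file.path(folder, "quad.ome.tif"))
  res2 <- scan_once(folder, m)
  expect_length(res2$jobs, 0L)
  expect_equal(res2$manifest$entries$quad$status, "ready")
})

test_that("corrupt sources fail cleanly with a decode reason", {
  folder <- withr::local_tempdir(); root <- withr::local_tempdir()
  f <- file.path(folder, "broken.tif")
  make_tiff(random_raster(64, 64, seed = 2), f)
  bytes <- readBin(f, "raw", n = file.size(f))
  writeBin(bytes[1:40], f)   # truncate
  res <- scan_once(folder, new_manifest())
  m <- convert_job(res$jobs[[1]], res$manifest, root)
  expect_equal(m$entries$broken$status, "failed")
  expect_match(m$entries$broken$reason, "decode")
  expect_false(dir.exists(file.path(root, "broken.zarr")))
})

test_that("growing files wait for a stable poll before re-queueing", {
  folder <- withr::local_tempdir(); root <- withr::local_tempdir()
  f <- file.path(folder, "grow.tif")
  make_tiff(random_raster(32, 32, seed = 3), f)
  res <- scan_once(folder, new_manifest())
  m <- convert_job(res$jobs[[1]], res$manifest, root)
  expect_equal(m$entries$grow$status, "ready")

  # the source is replaced and still growing: size differs between polls
  make_tiff(random_raster(64, 64, seed = 4), f)
  res2 <- scan_once(folder, m)
  expect_length(res2$jobs, 0L)      # first poll after the change: skip
  res3 <- scan_once(folder, res2$manifest)
  expect_length(res3$jobs, 1L)      # size stable across polls: re-queue
  m3 <- convert_job(res3$jobs[[1]], res3$manifest, root)
  st <- read_store(file.path(root, m3$entries$grow$store))
  expect_equal(st$base_width, 64L)
})

test_that("a crash-leftover converting entry is retried on the next scan", {
  folder <- withr::local_tempdir(); root <- withr::local_tempdir()
  make_tiff(random_raster(32, 32, seed = 5), file.path(folder, "crash.tif"))
  res <- scan_once(folder, new_manifest())
  m <- res$manifest
  m$entries$crash$status <- "converting"   # as if the converter died here
  res2 <- scan_once(folder, m)
  expect_length(res2$jobs, 1L)
  m2 <- convert_job(res2$jobs[[1]], res2$manifest, root)
  expect_equal(m2$entries$crash$status, "ready")
})

test_that("image ids deduplicate when filename stems collide", {
  folder <- withr::local_tempdir()
  make_tiff(random_raster(20, 20, seed = 6), file.path(folder, "dup.tif"))
  make_tiff(random_raster(24, 24, seed = 7), file.path(folder, "dup.tiff"))
  res <- scan_once(folder, new_manifest())
  ids <- sort(vapply(res$jobs, `[[`, character(1), "image_id"))
  expect_equal(ids, c("dup", "dup_1"))
})

test_that("manifests round-trip through JSON", {
  folder <- withr::local_tempdir(); root <- withr::local_tempdir()
  make_tiff(random_raster(40, 40, channels = 3, seed = 8),
            file.path(folder, "rt.tif"))
  res <- scan_once(folder, new_manifest())
  m <- convert_job(res$jobs[[1]], res$manifest, root)
  m2 <- read_manifest(root)
  e <- m2$entries$rt
  expect_equal(e$status, "ready")
  expect_equal(e$channel_names, c("CH0", "CH1", "CH2"))
  expect_equal(as.numeric(e$source_size), as.numeric(m$entries$rt$source_size))
})

test_that("OME-XML channel names are honored and RGB pages classified", {
  folder <- withr::local_tempdir()
  # brightfield: single 8-bit RGB page
  he <- make_image(fixture_spec(48, 64, 3, dtype = "uint8", seed = 10,
                                background = c(240, 220, 230),
                                pixel_kind = "brightfield_rgb"))
  make_tiff(he, file.path(folder, "he.tif"))
  got <- read_tiff_image(file.path(folder, "he.tif"))
  expect_equal(got$pixel_kind, "brightfield_rgb")
  expect_identical(got$pixels, he$pixels)

  # a 3-page 16-bit stack stays fluorescence
  fl <- random_raster(30, 30, channels = 3, dtype = "uint16", seed = 11)
  make_tiff(fl, file.path(folder, "fl.tif"))
  expect_equal(read_tiff_image(file.path(folder, "fl.tif"))$pixel_kind,
               "fluorescence")

  # OME-XML description names win over CH defaults when parseable
  nm <- tileforge:::ome_channel_names(paste0(
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels>',
    '<Channel Name="DAPI"/><Channel Name="CD3"/>',
    '</Pixels></Image></OME>'))
  expect_equal(nm, c("DAPI", "CD3"))
  expect_null(tileforge:::ome_channel_names("not xml"))
})
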
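test_that("the wire grammar parses and rejects exactly as specified", {
  s <- parse_spec("0:FFFFFF:0:255")
  expect_length(s$entries, 1L)
  expect_equal(s$entries[[1]]$color, c(255L, 255L, 255L))
  expect_equal(c(s$entries[[1]]$low, s$entries[[1]]$high), c(0L, 255L))

  s2 <- parse_spec("0:FF0000:0:100,1:00FF00:0:100")
  expect_equal(vapply(s2$entries, `[[`, integer(1), "channel"), c(0L, 1L))

  err <- expect_error(parse_spec("0:FF0000:200:100"), class = "tf_bad_request")
  expect_match(conditionMessage(err), "entry 0")
  expect_match(conditionMessage(err), "low >= high")

  expect_error(parse_spec("0:FF00:0:100"), class = "tf_bad_request")
  expect_error(parse_spec("0:GG0000:0:100"), class = "tf_bad_request")
  expect_error(parse_spec("0:FF0000:0:100,0:00FF00:0:100"), class = "tf_bad_request")
  expect_error(parse_spec("x:FF0000:0:100"), class = "tf_bad_request")
  expect_error(parse_spec("0:FF0000:0:1.5"), class = "tf_bad_request")
  expect_error(parse_spec(""), class = "tf_bad_request")

  # canonical form sorts by channel; request order is preserved in entries
  s3 <- parse_spec("3:0000FF:5:10,1:00FF00:0:100")
  expect_equal(format_spec(s3), "3:0000FF:5:10,1:00FF00:0:100")
  expect_equal(format_spec(s3, canonical = TRUE), "1:00FF00:0:100,3:0000FF:5:10")
})

test_that("catalog lists ready images sorted with pass-through metadata", {
  root <- withr::local_tempdir()
  app0 <- tile_app(tileforge_config(data_root = root, log_level = "quiet"))
  expect_length(handle_catalog(app0), 0L)

  m <- new_manifest()
  imgB <- random_raster(40, 60, channels = 2, dtype = "uint8", seed = 1)
  imgB$channel_names <- c("CD45", "PanCK")
  imgA <- random_raster(30, 30, channels = 1, dtype = "uint8", seed = 2)
  m <- register_image(m, "zeta", imgB, root)
  m <- register_image(m, "alpha", imgA, root)
  write_manifest(m, root)
  app <- tile_app(tileforge_config(data_root = root, log_level = "quiet"))
  cat <- handle_catalog(app)
  expect_equal(vapply(cat, `[[`, character(1), "image_id"), c("alpha", "zeta"))
  expect_equal(cat[[2]]$channel_names, c("CD45", "PanCK"))
  expect_equal(cat[[2]]$width, 60)
})

test_that("descriptor endpoint reflects image dimensions and validates", {
  img <- random_raster(768, 1024, channels = 1, dtype = "uint8", seed = 3)
  app <- make_test_app(img, id = "big")
  xml <- handle_descriptor(app, "big")
  expect_match(xml, 'Width="1024"', fixed = TRUE)
  expect_match(xml, 'Height="768"', fixed = TRUE)
  schema <- xml2::read_xml(system.file("extdata", "deepzoom.xsd",
                                       package = "tileforge"))
  expect_true(xml2::xml_validate(xml2::read_xml(xml), schema))
  expect_error(handle_descriptor(app, "nope"), class = "tf_not_found")
})

test_that("a one-tile image with full window and white color round-trips", {
  img <- random_raster(100, 100, channels = 1, dtype = "uint8", seed = 4)
  app <- make_test_app(img, id = "tiny")
  desc <- parse_descriptor_xml(handle_descriptor(app, "tiny"))
  res <- handle_tile(app, "tiny", desc$max_level, 0, 0, "0:FFFFFF:0:255")
  raster <- decode_tile(res$body, "png")
  for (k in 1:3)
    expect_equal(raster[, , k], matrix(img$pixels[1, , ], 100, 100))
})

test_that("identical requests are byte-identical and hit the cache", {
  img <- make_image(fixture_preset("small", seed = 2))
  app <- make_test_app(img, id = "s")
  spec <- "0:FF0000:400:20000,2:00FF00:400:30000"
  r1 <- handle_tile(app, "s", 9, 1, 1, spec)
  r2 <- handle_tile(app, "s", 9, 1, 1, spec)
  expect_false(r1$cache_hit)
  expect_true(r2$cache_hit)
  expect_identical(r1$body, r2$body)
  expect_equal(cache_stats(app)$hits, 1L)

  # entry order must not matter for the cached bytes either
  r3 <- handle_tile(app, "s", 9, 1, 1, "2:00FF00:400:30000,0:FF0000:400:20000")
  expect_true(r3$cache_hit)
  expect_identical(r3$body, r1$body)

  # cache disabled still yields identical bytes
  app_nc <- make_test_app(img, id = "s", cache_size = 0L)
  r4 <- handle_tile(app_nc, "s", 9, 1, 1, spec)
  expect_false(r4$cache_hit)
  expect_identical(r4$body, r1$body)
})

test_that("the router maps paths and failures to statuses", {
  img <- random_raster(300, 500, channels = 2, dtype = "uint16", seed = 5)
  app <- make_test_app(img, id = "img1")

  ok <- handle_request(app, "/images")
  expect_equal(ok$status, 200L)
  expect_match(ok$body, '"image_id":"img1"', fixed = TRUE)

  dzi <- handle_request(app, "/images/img1.dzi")
  expect_equal(dzi$status, 200L)
  expect_equal(dzi$content_type, "application/xml")

  tile <- handle_request(app, "/images/img1_files/9/0_0.png",
                         list(spec = "0:FFFFFF:0:65535"))
  expect_equal(tile$status, 200L)
  expect_equal(tile$content_type, "image/png")
  expect_true(is.raw(tile$body))

  expect_equal(handle_request(app, "/images/ghost.dzi")$status, 404L)
  expect_equal(handle_request(app, "/images/img1_files/9/99_0.png",
                              list(spec = "0:FFFFFF:0:65535"))$status, 404L)
  expect_equal(handle_request(app, "/nonsense")$status, 404L)
  expect_equal(handle_request(app, "/images/img1_files/9/0_0.png")$status, 400L)
  bad <- handle_request(app, "/images/img1_files/9/0_0.png",
                        list(spec = "0:FF0000:9:1"))
  expect_equal(bad$status, 400L)
  expect_match(bad$body, "entry 0")
  oob_chan <- handle_request(app, "/images/img1_files/9/0_0.png",
                             list(spec = "7:FF0000:0:100"))
  expect_equal(oob_chan$status, 400L)
  expect_match(oob_chan$body, "channel")
})

test_that("a k-channel tile request touches chunks of exactly k channels", {
  img <- random_raster(600, 1000, channels = 4, dtype = "uint16", seed = 6)
  app <- make_test_app(img, id = "fr", chunk_h = 128L, chunk_w = 128L,
                       cache_size = 0L)
  store <- tileforge:::app_store(app, "fr")
  store_reset_access(store)
  desc <- parse_descriptor_xml(handle_descriptor(app, "fr"))
  handle_tile(app, "fr", desc$max_level, 1, 1, "1:FF0000:0:1000,3:00FF00:0:1000")
  log <- store_access_log(store)
  chans <- sort(unique(sub("^[0-9]+/([0-9]+)\\..*$", "\\1", log)))
  expect_equal(chans, c("1", "3"))
  # at most the chunks intersecting the (tile + overlap) source region
  per_channel <- ceiling(258 / 128 + 1) * ceiling(258 / 128 + 1)
  expect_lte(length(log), 2 * per_channel)
})

test_that("query strings parse including URL escapes", {
  q <- tileforge:::parse_query_string("spec=0%3AFF0000%3A0%3A100&fmt=png")
  expect_equal(q$spec, "0:FF0000:0:100")
  expect_equal(q$fmt, "png")
  expect_equal(tileforge:::parse_query_string(""), list())
})
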
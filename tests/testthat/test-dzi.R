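test_that("level dimensions follow the halving-with-ceiling rule", {
  d1 <- dzi_descriptor(1, 1)
  expect_equal(d1$max_level, 0L)
  expect_equal(level_dimensions(d1, 0), c(width = 1L, height = 1L))

  d2 <- dzi_descriptor(1024, 768)
  expect_equal(d2$max_level, 10L)
  expect_equal(level_dimensions(d2, 10), c(width = 1024L, height = 768L))
  expect_equal(level_dimensions(d2, 9), c(width = 512L, height = 384L))
  expect_equal(level_dimensions(d2, 0), c(width = 1L, height = 1L))

  d3 <- dzi_descriptor(1000, 600)
  expect_equal(d3$max_level, 10L)
  expect_equal(level_dimensions(d3, 8), c(width = 250L, height = 150L))
  # oracle: repeatedly halve with ceiling from the top level down
  w <- 1000L; h <- 600L
  for (lv in 10:0) {
    expect_equal(level_dimensions(d3, lv), c(width = w, height = h))
    w <- as.integer(ceiling(w / 2)); h <- as.integer(ceiling(h / 2))
  }
  expect_error(level_dimensions(d3, 11), class = "tf_not_found")
  expect_error(level_dimensions(d3, -1), class = "tf_not_found")
})

test_that("exactly one level falls in each power-of-two size band", {
  for (dims in list(c(1000, 600), c(1, 1), c(4096, 4096), c(513, 77))) {
    d <- dzi_descriptor(dims[1], dims[2])
    maxdims <- vapply(0:d$max_level,
                      function(lv) max(level_dimensions(d, lv)), integer(1))
    expect_true(all(diff(maxdims) >= 0))
    for (k in seq_len(d$max_level)) {
      in_band <- maxdims > 2^(k - 1) & maxdims <= 2^k
      expect_equal(sum(in_band), 1L)
    }
  }
})

test_that("tile grids cover each level like a brute-force interval cover", {
  d <- dzi_descriptor(256, 256)
  expect_equal(tile_grid(d, d$max_level), c(cols = 1L, rows = 1L))
  d2 <- dzi_descriptor(257, 256)
  expect_equal(tile_grid(d2, d2$max_level), c(cols = 2L, rows = 1L))

  d3 <- dzi_descriptor(1000, 600)
  for (lv in 0:d3$max_level) {
    wh <- level_dimensions(d3, lv)
    # brute-force: count tile_size-intervals needed to cover [0, extent)
    cover <- function(extent) length(seq(0, extent - 1, by = d3$tile_size))
    expect_equal(tile_grid(d3, lv),
                 c(cols = cover(wh[["width"]]), rows = cover(wh[["height"]])))
  }
})

test_that("tile bounds expand cores by the overlap, clamped at borders", {
  d0 <- dzi_descriptor(100, 80, overlap = 0)
  lv0 <- 0  # 1 x 1 pixel level
  expect_equal(tile_bounds(d0, 0, 0, 0), c(y0 = 0L, x0 = 0L, y1 = 1L, x1 = 1L))

  d <- dzi_descriptor(512, 512, tile_size = 256, overlap = 1)
  b <- tile_bounds(d, d$max_level, col = 1, row = 0)
  expect_equal(b, c(y0 = 0L, x0 = 255L, y1 = 257L, x1 = 512L))

  # interior tiles measure tile_size + 2 * overlap
  d4 <- dzi_descriptor(1000, 600, overlap = 3)
  b4 <- tile_bounds(d4, d4$max_level, col = 1, row = 1)
  expect_equal(b4[["y1"]] - b4[["y0"]], 256L + 6L)
  expect_error(tile_bounds(d4, d4$max_level, col = 4, row = 0),
               class = "tf_not_found")
})

test_that("tile cores partition every level exactly", {
  d <- dzi_descriptor(1000, 600)
  for (lv in 0:d$max_level) {
    wh <- level_dimensions(d, lv)
    grid <- tile_grid(d, lv)
    hits <- matrix(0L, wh[["height"]], wh[["width"]])
    for (col in seq_len(grid[["cols"]]) - 1L) {
      for (row in seq_len(grid[["rows"]]) - 1L) {
        b <- tile_bounds(d, lv, col, row)
        core <- tileforge:::tile_core(d, lv, col, row)
        # bounds never exceed core by more than the declared overlap
        expect_lte(core[["y0"]] - b[["y0"]], d$overlap)
        expect_lte(b[["y1"]] - core[["y1"]], d$overlap)
        hits[(core[["y0"]] + 1L):core[["y1"]], (core[["x0"]] + 1L):core[["x1"]]] <-
          hits[(core[["y0"]] + 1L):core[["y1"]], (core[["x0"]] + 1L):core[["x1"]]] + 1L
      }
    }
    expect_true(all(hits == 1L))
  }
})

test_that("DZI levels map onto stored pyramid levels with power-of-two residuals", {
  d <- dzi_descriptor(1000, 600)
  expect_equal(map_to_pyramid(d, 8, d$max_level),
               list(pyramid_level = 0L, residual_factor = 1L))
  # 3-level pyramid, DZI level needing scale 16 -> deepest level + residual 4
  lv <- d$max_level - 4L
  expect_equal(map_to_pyramid(d, 3, lv),
               list(pyramid_level = 2L, residual_factor = 4L))
  img <- random_raster(600, 1000, channels = 2, dtype = "uint16", seed = 55)
  p <- build_pyramid(img, stop_size = 200)  # 4 levels: 1000, 500, 250, 125
  expect_equal(n_levels(p), 4L)
  expect_error(map_to_pyramid(dzi_descriptor(999, 600), p, 5),
               class = "tf_config_error")
  # rendering via the mapping equals brute-force downscale of level 0
  for (lv in 0:d$max_level) {
    wh <- level_dimensions(d, lv)
    got <- tileforge:::read_dzi_region(p, d, lv, 0, 0, wh[["height"]],
                                       wh[["width"]], 0:1)
    want <- oracle_downscale_k(img$pixels, d$max_level - lv)
    expect_identical(got, want)
  }
})

test_that("descriptor XML round-trips, is byte-stable, and validates", {
  set.seed(6)
  schema <- xml2::read_xml(system.file("extdata", "deepzoom.xsd",
                                       package = "tileforge"))
  for (i in 1:10) {
    d <- dzi_descriptor(sample(1:5000, 1), sample(1:5000, 1),
                        tile_size = sample(c(16, 254, 256, 512), 1),
                        overlap = sample(0:2, 1),
                        tile_format = sample(c("png", "jpeg"), 1))
    xml <- descriptor_xml(d)
    expect_identical(xml, descriptor_xml(d))      # byte-stable
    expect_equal(parse_descriptor_xml(xml), d)    # round-trip
    expect_true(xml2::xml_validate(xml2::read_xml(xml), schema))
  }
  expect_match(descriptor_xml(dzi_descriptor(10, 10, tile_format = "png")),
               'Format="png"', fixed = TRUE)
})

test_that("tile paths follow the _files layout viewers construct", {
  expect_identical(tile_path("slide", 9, 3, 7, "png"), "slide_files/9/3_7.png")
  expect_identical(tile_path("a b", 0, 0, 0, "jpeg"), "a b_files/0/0_0.jpeg")
})
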
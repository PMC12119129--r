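# Independent oracles. These deliberately use different mechanisms from the
# package internals: explicit per-pixel loops, or rowsum() block sums, so an
# agreement is evidence rather than tautology.

# naive doubly-nested-loop 2x area-mean downsampler (round half up)
naive_downsample <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, ceiling(h / 2), ceiling(w / 2))
  for (y in seq_len(nrow(out))) {
    for (x in seq_len(ncol(out))) {
      ys <- (2 * y - 1):min(2 * y, h)
      xs <- (2 * x - 1):min(2 * x, w)
      out[y, x] <- as.integer(floor(mean(m[ys, xs, drop = FALSE]) + 0.5))
    }
  }
  out
}

# rowsum()-based block-mean downsampler: fast enough for whole-level oracles
rowsum_downsample <- function(m) {
  gy <- (seq_len(nrow(m)) - 1L) %/% 2L
  gx <- (seq_len(ncol(m)) - 1L) %/% 2L
  s <- rowsum(m, gy)
  s <- t(rowsum(t(s), gx))
  cnt <- outer(as.vector(table(gy)), as.vector(table(gx)))
  matrix(as.integer(floor(s / cnt + 0.5)), nrow(s), ncol(s))
}

# downscale a (c, y, x) array by 2^k with repeated rowsum halvings
oracle_downscale_k <- function(a, k) {
  for (i in seq_len(k)) {
    d <- dim(a)
    out <- array(0L, c(d[1L], ceiling(d[2L] / 2), ceiling(d[3L] / 2)))
    for (ch in seq_len(d[1L]))
      out[ch, , ] <- rowsum_downsample(matrix(a[ch, , ], d[2L], d[3L]))
    a <- out
  }
  a
}

# scalar per-pixel additive compositing loop
naive_mix <- function(planes, spec) {
  if (is.matrix(planes)) planes <- array(planes, dim = c(1L, dim(planes)))
  ne <- dim(planes)[1L]; h <- dim(planes)[2L]; w <- dim(planes)[3L]
  out <- array(0L, c(h, w, 3L))
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      acc <- c(0, 0, 0)
      for (i in seq_len(ne)) {
        e <- spec$entries[[i]]
        v <- (planes[i, y, x] - e$low) / (e$high - e$low)
        v <- min(max(v, 0), 1)
        acc <- acc + v * e$color
      }
      out[y, x, ] <- as.integer(floor(pmin(pmax(acc, 0), 255) + 0.5))
    }
  }
  out
}

random_raster <- function(h, w, channels = 1L, dtype = "uint8", seed = 1L) {
  mx <- if (dtype == "uint16") 65535L else 255L
  set.seed(seed)
  raster_image(array(sample.int(mx + 1L, channels * h * w, replace = TRUE) - 1L,
                     dim = c(channels, h, w)),
               dtype = dtype)
}

random_render_spec <- function(n_entries, dtype = "uint8", seed = 1L,
                               include_boundaries = FALSE) {
  mx <- if (dtype == "uint16") 65535L else 255L
  set.seed(seed)
  entries <- lapply(seq_len(n_entries), function(i) {
    if (include_boundaries && i == 1L) {
      # razor-thin window plus saturating color: exercises the clip paths
      low <- sample.int(mx, 1L) - 1L
      channel_render(i - 1L, c(255L, 255L, 255L), low, low + 1L)
    } else {
      b <- sort(sample.int(mx + 1L, 2L) - 1L)
      if (b[1L] == b[2L]) b[2L] <- b[1L] + 1L
      channel_render(i - 1L, sample.int(256L, 3L) - 1L, b[1L], b[2L])
    }
  })
  render_spec(entries)
}
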
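---
title: "Serving multiplexed microscopy images as on-demand Deep Zoom tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serving multiplexed microscopy images as on-demand Deep Zoom tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The serving model

tileforge sits between two established ways of sharing whole-slide
multiplex immunofluorescence data. Serving raw OME-TIFF fragments keeps
every channel and contrast choice open to the viewer but moves large
amounts of 16-bit pixel data on every pan and zoom; pre-rendered Deep Zoom
Image (DZI) pyramids move very little data but bake 3–4 channels and one
contrast setting into the export. tileforge converts each image once into
a chunked multiscale store and renders DZI tiles *at request time* for the
channels, colors and intensity windows named in the request. The viewer
keeps full flexibility; the wire carries only small encoded tiles.

The pipeline for one tile request is:

1. map the DZI level to a stored pyramid level plus a residual
   power-of-two factor;
2. scale the tile bounds to that pyramid level and read, lazily, only the
   chunks that intersect them — and only for the requested channels;
3. apply the residual downscale with the pyramid's own area-mean kernel;
4. window each channel to $[0,1]$, tint it with its display color, sum,
   clip, round;
5. encode as PNG or JPEG.

Because chunks never span channels, a request for $k$ of $C$ channels does
I/O for exactly $k$ channels; the unrequested $C-k$ channels cost nothing.
This is the whole mechanism behind the bandwidth savings: the server reads
little, and the client receives a composited 8-bit tile instead of $C$
16-bit planes.

## Pyramid construction

`build_pyramid()` repeatedly halves each channel with a 2×2 area mean:
block sums are accumulated in doubles, divided by the number of pixels
present, rounded half up and cast back to the input dtype. Level $p$ has
shape $(\lceil H/2^p \rceil, \lceil W/2^p \rceil)$; odd trailing rows and
columns are averaged over 1×2, 2×1 or 1×1 blocks, so no padding value ever
leaks into the data. Generation stops at the first level whose largest
dimension is at most `stop_size`.

Three choices here were genuinely open:

* **Kernel.** The area mean preserves photometry (the grand mean of a
  level changes by at most the per-pixel rounding, exactly 0 when block
  sums divide evenly), which matters when viewers window tight intensity
  ranges; nearest-neighbour subsampling would alias small bright
  structures such as single nuclei. Rounding is fixed at half-up so
  pyramids are bit-reproducible across platforms.
* **Chunk geometry, default (1, 256, 256).** One chunk is roughly one
  tile's worth of 16-bit data, and per-channel chunking is what makes
  channel-selective reads free. Configurable per store.
* **`stop_size`, default 512.** Levels smaller than this are synthesized
  at render time by residual halving rather than stored; below ~512 px the
  storage saved no longer justifies extra files, and the residual work is
  microseconds. Because the residual scaling uses the same kernel as
  construction, a synthesized level is pixel-identical to downscaling the
  full-resolution plane directly — the commutation property the test suite
  asserts exactly, not approximately.

The store layout is the NGFF (OME-ZARR) multiscales convention — one zarr
v2 array per level, axes `(c, y, x)`, factor-2 scale metadata, channel
names in `omero` metadata, uncompressed little-endian chunks. The test
suite includes a conformance check in which an independent zarr reader
opens a tileforge store and reproduces the arrays byte for byte.
Coordinates everywhere are 0-based, half-open, `(y, x)` ordered; channel
indices are 0-based to match the wire grammar.

Input samples must be unsigned 8- or 16-bit integers. Floating-point
images are rejected rather than silently normalized: fluorescence
instruments emit integer counts, and display normalization is the render
spec's job, chosen per request, not a property of the stored data.

## DZI coordinate algebra

DZI levels run $0 \dots \lceil \log_2 \max(W, H) \rceil$ with the top
level at full resolution; each lower level halves the dimensions with
ceiling. Tiles are counted over their overlap-free *core* regions, which
partition every level exactly; the returned bounds expand each core by
`overlap` pixels clamped to the level, so interior tiles measure
`tile_size + 2·overlap`. Defaults are tile size 256 and overlap 1 — the
Deep Zoom convention most viewers expect for seam-free rendering; both are
configurable. Degenerate 1×1 images get max level 0 and a single tile, and
are covered by tests. The descriptor XML and the
`{id}_files/{level}/{col}_{row}.{fmt}` tile path layout are byte-exact,
since external viewers construct these URLs themselves; descriptors are
validated against a Deep Zoom XML schema in the tests.

## Channel compositing

Windowing is linear: values at or below `low` map to 0, at or above
`high` to 1. Mixing is *additive with saturation clip* — each windowed
plane is multiplied by its RGB display color, contributions are summed per
pixel, clipped to [0, 255] and rounded half up. Additive blending is the
fluorescence convention: co-localized markers sum toward white, exactly as
co-localized dyes appear. Max-projection blending is deliberately not
offered in this version, and there is no gamma or nonlinear LUT —
intensity adjustment is the only tone control. The arithmetic order
(float accumulate → clip → round half up → cast) is fixed so tiles are
bit-reproducible; summation commutes, so entry order never changes a tile.

Brightfield H&E images (3-channel 8-bit RGB) bypass additive tinting: a
request with the identity mapping (channels 0, 1, 2 tinted pure red,
green, blue) is composited in `rgb_passthrough` mode, which is pixel-equal
to the additive path for that mapping and exists to make the brightfield
contract explicit. Single-channel grayscale renders as R = G = B via a
white tint.

## The server

Handlers are pure functions over immutable stores; the channel spec
travels in the query string of every tile request
(`spec=0:FF0000:0:4095,3:00FF00:100:2000` — channel, RRGGBB hex, window
low, high), so the server is stateless, trivially concurrent, and tiles
are cacheable byte-for-byte. The wire grammar is this package's
definition; entries are canonicalized (sorted by channel) for cache keys
but kept in request order for mixing, which is order-independent anyway.
The tile cache is a bounded LRU (default 512 tiles) and is purely an
optimization: the tests exercise every path with the cache disabled as
well, and determinism across fresh processes is asserted on encoded
bytes. HTTP details — CORS open for viewer embedding, immutable
cache-control on tiles — live in `cmd_serve()`'s thin httpuv wrapper, not
in the handlers.

## Ingestion

`scan_once()` polls an ingestion folder (polling rather than OS file
notifications: it behaves identically on local disks and mounted buckets,
and makes the contract testable in one call). A new stable file is queued
immediately; a file whose size differs from the previous poll's record is
considered still growing and waits for a stable poll. Conversion writes
the store under a temporary name and renames it into place only after the
store re-opens and validates, so a crash mid-write never publishes a
partial store; a `converting` status encountered during a scan can only be
a crash leftover (scan and convert run sequentially) and is retried.
Re-uploads are detected by size/mtime change and re-ingested under the
same id — this package's choice, as upstream re-upload semantics are
undefined. A corrupt TIFF becomes a `failed` manifest entry whose reason
names the decode error; it never crashes the poller. Once ready, the store
is authoritative: deleting the source file does not unregister the image.

## Synthetic fixtures and what they show

`fixture_preset()` generates deterministic multichannel images: flat
background, per-channel Gaussian blobs (`peak · exp(−d²/2σ²)`, σ =
radius/3, truncated at the radius), seeded Gaussian noise, rounded and
clipped to the dtype. Gaussian blobs survive area-mean downsampling
predictably, which lets end-to-end tests assert *where* signal must appear
at every zoom level, not just that bytes round-trip. The presets model the
package's three serving scenarios: `small` (512², 4×uint16) for unit
tests, `tma` (4096², 8×uint16, a 6×6 grid of blob clusters mimicking a
tissue-microarray mosaic) for the bandwidth harness, and `he` (2048² RGB
uint8, dark blobs on a pale background) for the brightfield path.

What the fixtures do **not** emulate: real tissue texture, autofluorescent
background structure, scanner shading, JPEG-era compression artifacts, or
channel crosstalk. Passing tests therefore demonstrate the *pipeline* —
geometry, photometric arithmetic, laziness, wire conformance — on data
with known ground truth; they do not demonstrate segmentation-grade image
quality on real slides, which is not this package's claim.

## The bandwidth harness

`cmd_bench()` replays a fixed, seedless 10-viewport script (a
diagonal-staggered lattice of 1024² windows at full resolution) against
two strategies: on-demand tiles for a 4-channel display spec, versus the
raw 16-bit planes of *all* channels for the same viewports. It reports
payload bytes and request counts only — wall-clock and memory depend on
hardware, network and client software and are deliberately out of scope.
Tile bytes are counted on every request (no cache), the conservative
accounting. On the `tma` preset the tile strategy moves well under a
quarter of the raw bytes; the exact fold (hundreds, for this fixture's
windowing) is fixture- and codec-specific and is reported, not asserted.

## Problem sizes and numerical notes

The test suite runs the full stitching identity on a 1000×600×4 fixture
across all 11 DZI levels, loop-oracle downsampling on 50 images up to
64×64 in both dtypes, scalar-loop compositing on 100 seeded cases, and the
tma-scale bandwidth harness — sizes chosen so the whole suite completes in
a few minutes on one CPU while still exercising odd dimensions, multi-level
residuals and chunk-boundary tiles. Degenerate inputs are tested
explicitly: 1×1 images and regions, single-tile levels, razor-thin
intensity windows (`high = low + 1`), saturating colors, and empty
catalogs. Out-of-bounds regions and tiles always raise errors; nothing is
silently clamped.

## Known limitations

* 2-D images only: no z-stacks, time series, or non-factor-2 pyramids.
* TIFF/OME-TIFF input only; vendor formats need an upstream converter.
* Additive blending only; no max projection, gamma, or ICC management.
* The HTTP layer is single-process; scale-out is by running more
  processes over the same immutable stores (the handlers are stateless).
* No authentication or upload quotas — deployment concerns, not method.
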
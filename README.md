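# tileforge

On-demand Deep Zoom tile serving for multiplexed microscopy images, in R.

## The problem

Multiplex immunofluorescence platforms (Orion, CODEX, MIBI, ...) produce
whole-slide images with tens to hundreds of intensity channels and tens of
gigabytes per slide. Browsing such data remotely is painful: shipping raw
OME-TIFF fragments is flexible but slow (every pan pulls megabytes of
16-bit planes for every channel), while pre-rendering a pyramid of Deep
Zoom Image (DZI) tiles is fast but freezes a handful of channels and one
contrast setting at export time.

tileforge implements the hybrid strategy: images are converted once into a
chunked multiscale pyramid store (NGFF/OME-ZARR layout, factor-2 levels,
per-channel chunks), and DZI tiles are rendered *per request* from exactly
the chunks the requested channels and region need. The client chooses the
channels, their display colors and their intensity windows on every
request, yet receives only small encoded tiles — so arbitrarily many
channels can be browsed over low bandwidth with any DZI-compatible viewer
(OpenSeadragon and friends).

## The computation at its core

For a request with channel set $S$, per-channel display colors
$c_j \in [0,255]^3$ and intensity windows $(l_j, h_j)$, each requested
tile is composited additively from the windowed channel planes $I_j$:

```
RGB(y, x) = clip( Σ_{j ∈ S}  clip((I_j(y,x) − l_j) / (h_j − l_j), 0, 1) · c_j , 0, 255 )
```

accumulated in floating point, rounded half up, and encoded as PNG
(lossless) or JPEG. The plane $I_j$ at a given DZI level is synthesized
from the stored pyramid: the deepest stored level not past the requested
scale is read lazily (only chunks intersecting the tile, only channels in
$S$), then downscaled by the residual power of two with the same 2×2
area-mean kernel used to build the pyramid — so a rendered level is
pixel-identical to downscaling the full-resolution data directly.

## Worked example

```r
library(tileforge)

folder <- tempfile(); dir.create(folder)   # the "ingestion folder"
root   <- tempfile(); dir.create(root)     # the served data root

# 1. drop a 512 x 512, 4-channel uint16 image into the watch folder
cmd_fixture("small", file.path(folder, "slide.tif"))

# 2. ingest: scan the folder, convert to a pyramid store, update the manifest
cmd_ingest(folder, root, quiet = TRUE)

# 3. serve (handlers work without a socket too)
app <- tile_app(tileforge_config(data_root = root))
cat(handle_descriptor(app, "slide"))
#> <?xml version="1.0" encoding="UTF-8"?>
#> <Image TileSize="256" Overlap="1" Format="png" xmlns="http://schemas.microsoft.com/deepzoom/2008">
#>   <Size Width="512" Height="512"/>
#> </Image>

# 4. one tile: channels 0 and 2, red and green, explicit intensity windows
res <- handle_tile(app, "slide", level = 9, col = 0, row = 0,
                   spec = "0:FF0000:400:20000,2:00FF00:400:30000")
length(res$body)
#> [1] 3856
res$content_type
#> [1] "image/png"
```

The 3856-byte PNG is the 257×257 top-left tile (256 + 1 px overlap) of the
full-resolution DZI level: the raw pixels behind it would be
257 × 257 × 2 channels × 2 bytes ≈ 258 KB, and all 4 channels ≈ 516 KB.
A real viewer fetches the same URLs from `cmd_serve()`:

```
GET /images                                       # catalog (JSON)
GET /images/slide.dzi                             # DZI descriptor (XML)
GET /images/slide_files/9/0_0.png?spec=0:FF0000:400:20000,2:00FF00:400:30000
```

The bandwidth harness quantifies the effect on the built-in 4096×4096,
8-channel tissue-microarray fixture — a scripted 10-viewport browsing
session with a 4-channel display spec:

```r
res <- cmd_bench("tma", n_viewports = 10)
#> bench tma: 212 tile requests, 0.72 MB tiles vs 160.00 MB raw (222.1-fold reduction)
```

i.e. on-demand tiles moved 0.72 MB where raw all-channel planes for the
same viewports would have moved 160 MB.

## Command line

```
tileforge ingest <folder> --data-root <dir> [--watch] [--interval N]
tileforge serve --data-root <dir> [--port N] [--config file.json]
tileforge render <id> <level> <y0,x0,y1,x1> <spec> <out.png>
tileforge fixture --preset {small,tma,he} --out <path>
tileforge bench [--preset tma] [--viewports N]
```

See `vignettes/serving-multiplex-images.Rmd` for the design rationale:
kernel and chunking choices, the DZI↔pyramid level mapping, the additive
blending model, the wire grammar, and what the synthetic fixtures do and
do not emulate.
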
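# Slide preprocessing: tissue masking, tiling, patch encoding. Rasters are
# plain R arrays (H x W x 3, values in [0, 1]) so tests need no image files;
# read_raster() wraps the png package for real inputs.

#' Otsu threshold of an 8-bit histogram
#'
#' Picks the threshold `t` in 0..254 maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the two classes `{<= t}` and `{> t}` over a
#' 256-bin histogram. Ties resolve to the smallest maximizing threshold.
#'
#' @param counts Integer vector of length 256 (bin counts for values 0..255).
#' @return The threshold (integer in 0..254), or `NA` with attribute
#'   `degenerate = TRUE` when fewer than two bins are occupied.
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256L)
  total <- sum(counts)
  if (total == 0L || sum(counts > 0) < 2L) {
    return(structure(NA_integer_, degenerate = TRUE))
  }
  p <- counts / total
  levels <- 0:255
  w0 <- cumsum(p)[1:255]
  mu_cum <- cumsum(p * levels)[1:255]
  mu_tot <- sum(p * levels)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 / (w0[valid] * w1[valid])
  which.max(bcv) - 1L
}

raster_channel <- function(img, channel) {
  if (length(dim(img)) == 2L) {
    if (channel == "saturation") {
      stop_pcm("saturation channel requires an RGB raster", "validation_error")
    }
    return(img)
  }
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  if (channel == "saturation") {
    mx <- pmax(r, g, b)
    mn <- pmin(r, g, b)
    s <- ifelse(mx > 0, (mx - mn) / mx, 0)
    s
  } else {
    0.299 * r + 0.587 * g + 0.114 * b
  }
}

#' Otsu tissue mask from a slide thumbnail
#'
#' Computes the Otsu threshold on the 256-bin histogram of the chosen channel
#' and classifies pixels into tissue and background. On the saturation
#' channel (default) tissue is the *high*-saturation class: H&E-stained
#' tissue is chromatic while glass background is achromatic. On the grayscale
#' channel tissue is the *low*-luminance class (stained tissue is darker than
#' the bright background). A constant-intensity thumbnail has no valid
#' threshold and yields an all-background mask flagged `degenerate`.
#'
#' @param thumbnail Numeric array `H x W x 3` (or matrix for grayscale) with
#'   values in `[0, 1]`.
#' @param channel `"saturation"` (default) or `"grayscale"`.
#' @param downsample_factor Downsample of the thumbnail relative to level 0
#'   (default 32).
#' @return A `pcm_tissue_mask`: list with `mask` (logical matrix, TRUE =
#'   tissue), `threshold` (0..255 or NA), `channel`, `downsample_factor`,
#'   `degenerate`.
#' @export
compute_otsu_mask <- function(thumbnail, channel = c("saturation", "grayscale"),
                              downsample_factor = 32) {
  channel <- match.arg(channel)
  if (length(thumbnail) == 0L) stop_pcm("empty thumbnail", "validation_error")
  ch <- raster_channel(thumbnail, channel)
  bins <- pmin(255L, pmax(0L, as.integer(floor(ch * 256))))
  counts <- tabulate(bins + 1L, nbins = 256L)
  thr <- otsu_threshold(counts)
  if (is.na(thr)) {
    warn_pcm("constant-intensity thumbnail: no valid Otsu threshold, mask is all background",
             "degenerate_mask")
    mask <- matrix(FALSE, nrow(ch), ncol(ch))
    return(structure(list(mask = mask, threshold = NA_integer_,
                          channel = channel,
                          downsample_factor = downsample_factor,
                          degenerate = TRUE),
                     class = "pcm_tissue_mask"))
  }
  mask <- if (channel == "saturation") {
    matrix(bins > thr, nrow(ch), ncol(ch))
  } else {
    matrix(bins <= thr, nrow(ch), ncol(ch))
  }
  structure(list(mask = mask, threshold = thr, channel = channel,
                 downsample_factor = downsample_factor, degenerate = FALSE),
            class = "pcm_tissue_mask")
}

#' Tile a slide into a non-overlapping grid with tissue filtering
#'
#' Lays a regular grid with origin (0, 0) and stride equal to the patch size
#' at the target resolution, drops partial edge tiles (every retained tile is
#' exactly `patch_size_px`^2 at target scale), projects each tile onto the
#' tissue mask and keeps tiles whose tissue fraction reaches
#' `min_tissue_fraction`. Coordinates are 0-based level-0 pixels (x = column).
#' The "10x magnification" working resolution is expressed portably as a
#' target microns-per-pixel (1.0 by default): the level-0 stride is
#' `patch_size_px * target_mpp / native_mpp`.
#'
#' @param slide_dims `(W, H)` level-0 pixel dimensions.
#' @param mask A `pcm_tissue_mask` (or NULL to keep every tile).
#' @param patch_size_px Patch edge at target resolution (default 224).
#' @param target_mpp Target microns per pixel (default 1.0, i.e. 10x).
#' @param native_mpp Level-0 microns per pixel (default 1.0).
#' @param min_tissue_fraction Minimum projected tissue fraction for a tile to
#'   be retained (default 0.25).
#' @return A `pcm_tile_grid` tibble: `x`, `y` (level-0 origins),
#'   `tissue_fraction`; attributes `patch_size_px`, `stride_l0`,
#'   `target_mpp`.
#' @export
tile_slide <- function(slide_dims, mask = NULL, patch_size_px = 224L,
                       target_mpp = 1.0, native_mpp = 1.0,
                       min_tissue_fraction = 0.25) {
  W <- slide_dims[1]; H <- slide_dims[2]
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1) {
    stop_pcm("min_tissue_fraction must lie in [0, 1]", "config_error")
  }
  stride <- as.integer(round(patch_size_px * target_mpp / native_mpp))
  nx <- floor(W / stride); ny <- floor(H / stride)
  if (nx < 1L || ny < 1L) {
    warn_pcm("slide smaller than one tile: empty grid", "empty_grid")
    out <- tibble::tibble(x = integer(), y = integer(), tissue_fraction = numeric())
    return(structure(out, class = c("pcm_tile_grid", class(out)),
                     patch_size_px = patch_size_px, stride_l0 = stride,
                     target_mpp = target_mpp))
  }
  grid <- tidyr::expand_grid(iy = seq_len(ny) - 1L, ix = seq_len(nx) - 1L)
  xs <- grid$ix * stride; ys <- grid$iy * stride
  frac <- rep(1, nrow(grid))
  if (!is.null(mask)) {
    ds <- mask$downsample_factor
    mh <- nrow(mask$mask); mw <- ncol(mask$mask)
    if (abs(mw * ds - W) > ds || abs(mh * ds - H) > ds) {
      stop_pcm(sprintf(
        "mask geometry (%d x %d at %gx) inconsistent with slide dims (%d x %d)",
        mw, mh, ds, W, H), "geometry_error")
    }
    frac <- vapply(seq_along(xs), function(i) {
      cs <- floor(xs[i] / ds) + 1L
      ce <- min(mw, ceiling((xs[i] + stride) / ds))
      rs <- floor(ys[i] / ds) + 1L
      re <- min(mh, ceiling((ys[i] + stride) / ds))
      mean(mask$mask[rs:re, cs:ce])
    }, numeric(1))
  }
  keep <- frac >= min_tissue_fraction
  out <- tibble::tibble(x = as.integer(xs[keep]), y = as.integer(ys[keep]),
                        tissue_fraction = frac[keep])
  structure(out, class = c("pcm_tile_grid", class(out)),
            patch_size_px = patch_size_px, stride_l0 = stride,
            target_mpp = target_mpp)
}

#' Patch encoders
#'
#' A patch encoder is a pluggable interface: a name, an output dimension, and
#' a deterministic function mapping a list of RGB patch arrays to a matrix of
#' embeddings (one row per patch). Foundation-model encoders plug in here;
#' `stub_encoder()` provides a deterministic test encoder that projects
#' simple patch summary statistics (channel means/sds and intensity) through
#' a fixed seeded random matrix.
#'
#' @param name Encoder name.
#' @param dim Output dimension D.
#' @param encode Function `list of patches -> N x dim matrix`.
#' @return A `pcm_encoder`.
#' @export
patch_encoder <- function(name, dim, encode) {
  structure(list(name = name, dim = as.integer(dim), encode = encode),
            class = "pcm_encoder")
}

#' @rdname patch_encoder
#' @param seed Seed for the stub's fixed projection matrix.
#' @export
stub_encoder <- function(dim = 16L, seed = 0L) {
  proj <- withr::with_seed(seed, matrix(rnorm(7L * dim), 7L, dim))
  patch_encoder(
    name = sprintf("stub-%d", dim), dim = dim,
    encode = function(patches) {
      stats_mat <- t(vapply(patches, function(p) {
        c(mean(p[, , 1]), mean(p[, , 2]), mean(p[, , 3]),
          sd(as.vector(p[, , 1])), sd(as.vector(p[, , 2])),
          sd(as.vector(p[, , 3])), mean(p))
      }, numeric(7)))
      stats_mat[!is.finite(stats_mat)] <- 0
      stats_mat %*% proj
    })
}

#' Encode retained tiles into a feature bag
#'
#' Extracts each retained tile from the slide raster (resampling from the
#' native to the target resolution by nearest-neighbour index mapping when
#' they differ), encodes all patches with the supplied encoder, and assembles
#' the feature bag with level-0 coordinates in grid order.
#'
#' @param raster Level-0 slide raster, `H x W x 3` in `[0, 1]`.
#' @param grid A `pcm_tile_grid`.
#' @param encoder A `pcm_encoder`.
#' @param slide_id Slide identifier recorded in the bag.
#' @param magnification Magnification tag recorded in the bag.
#' @return A `pcm_bag` with `N = nrow(grid)` rows in grid order.
#' @export
encode_tiles <- function(raster, grid, encoder, slide_id = "slide",
                         magnification = "10x") {
  stopifnot(inherits(grid, "pcm_tile_grid"), inherits(encoder, "pcm_encoder"))
  if (nrow(grid) == 0L) stop_pcm("tile grid is empty", "validation_error")
  stride <- attr(grid, "stride_l0")
  psz <- attr(grid, "patch_size_px")
  H <- dim(raster)[1]; W <- dim(raster)[2]
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid$x[i]; y0 <- grid$y[i]
    if (x0 + stride > W || y0 + stride > H) {
      stop_pcm(sprintf("tile (%d, %d) extends beyond the raster", x0, y0),
               "io_error")
    }
    rel <- floor((seq_len(psz) - 0.5) * stride / psz)
    rows <- y0 + rel + 1L
    cols <- x0 + rel + 1L
    raster[rows, cols, , drop = FALSE]
  })
  feats <- encoder$encode(patches)
  if (!is.matrix(feats) || nrow(feats) != nrow(grid) || ncol(feats) != encoder$dim) {
    stop_pcm(sprintf(
      "encoder '%s' declared dim %d but returned a %s x %s result for %d patches",
      encoder$name, encoder$dim,
      if (is.matrix(feats)) nrow(feats) else length(feats),
      if (is.matrix(feats)) ncol(feats) else 1L, nrow(grid)),
      "dimension_error")
  }
  feature_bag(features = feats, coords = cbind(grid$x, grid$y),
              slide_id = slide_id, patch_size_px = psz,
              magnification = magnification, encoder_name = encoder$name)
}

#' Read an RGB raster from a PNG file
#'
#' @param path PNG path.
#' @return Numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_raster <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_pcm("reading PNG rasters requires the 'png' package", "io_error")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Preprocess one slide raster into a feature bag
#'
#' Front-to-back preprocessing: builds a thumbnail by subsampling, computes
#' the Otsu tissue mask, tiles the slide with tissue-fraction filtering, and
#' encodes the retained tiles. Returns the bag; writes it when `out` is
#' given.
#'
#' @param raster Slide raster (`H x W x 3` array in `[0, 1]`) or the path to
#'   a PNG file.
#' @param encoder A [patch_encoder()] (default: 16-dim stub).
#' @param slide_id Slide identifier.
#' @param patch_size_px Patch edge at target resolution (default 224).
#' @param target_mpp,native_mpp Microns per pixel of the working resolution
#'   and of the raster (default both 1.0).
#' @param min_tissue_fraction Tile retention threshold (default 0.25).
#' @param thumbnail_downsample Subsampling factor for the masking thumbnail
#'   (default 8).
#' @param channel Otsu channel, see [compute_otsu_mask()].
#' @param out Optional output path for [write_bag()].
#' @return A `pcm_bag` (invisibly when `out` is given).
#' @export
preprocess_slide <- function(raster, encoder = stub_encoder(), slide_id = "slide",
                             patch_size_px = 224L, target_mpp = 1.0,
                             native_mpp = 1.0, min_tissue_fraction = 0.25,
                             thumbnail_downsample = 8L,
                             channel = "saturation", out = NULL) {
  if (is.character(raster)) raster <- read_raster(raster)
  H <- dim(raster)[1]; W <- dim(raster)[2]
  ds <- thumbnail_downsample
  thumb <- raster[seq(1L, H, by = ds), seq(1L, W, by = ds), , drop = FALSE]
  mask <- compute_otsu_mask(thumb, channel = channel, downsample_factor = ds)
  grid <- tile_slide(c(W, H), mask, patch_size_px = patch_size_px,
                     target_mpp = target_mpp, native_mpp = native_mpp,
                     min_tissue_fraction = min_tissue_fraction)
  bag <- encode_tiles(raster, grid, encoder, slide_id = slide_id)
  if (!is.null(out)) {
    write_bag(bag, out)
    return(invisible(bag))
  }
  bag
}
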
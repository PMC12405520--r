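# Attention heatmaps: percentile normalization of patch attention scores,
# spatial mapping onto the slide, and overlay rendering.

#' Percentile-based normalization of attention scores
#'
#' Maps each score to its empirical percentile rank
#' `(rank - 1) / (N - 1)` with midranks for ties, so the minimum maps to 0.0,
#' the maximum to 1.0, the transform is parameter-free and order-isomorphic
#' to the input, and an all-tied vector maps to 0.5. A single score maps to
#' 0.5. An alternative winsorized min-max mode clips at the 1st/99th
#' percentiles before linear rescaling.
#'
#' @param scores Numeric vector of attention scores.
#' @param mode `"rank"` (default) or `"winsor"`.
#' @return Numeric vector in `[0, 1]`.
#' @export
percentile_normalize <- function(scores, mode = c("rank", "winsor")) {
  mode <- match.arg(mode)
  check_finite(scores, "scores")
  n <- length(scores)
  if (n == 0L) stop_pcm("empty score vector", "validation_error")
  if (n == 1L) return(0.5)
  if (mode == "rank") {
    r <- rank(scores, ties.method = "average")
    out <- (r - 1) / (n - 1)
  } else {
    lo <- quantile(scores, 0.01, names = FALSE)
    hi <- quantile(scores, 0.99, names = FALSE)
    if (hi == lo) return(rep(0.5, n))
    out <- pmin(1, pmax(0, (scores - lo) / (hi - lo)))
  }
  out
}

# Separable triangular (bilinear tent) smoothing with a normalized kernel;
# a convex combination per pixel, so values stay within [0, 1].
smooth_bilinear <- function(mat, half_width) {
  if (half_width < 1L) return(mat)
  k <- (half_width + 1L - abs(-half_width:half_width)) / (half_width + 1L)^2 *
    (half_width + 1L)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1L], half_width), v, rep(v[n], half_width))
    vapply(seq_len(n), function(i) sum(padded[i:(i + 2L * half_width)] * k),
           numeric(1))
  }
  mat <- t(apply(mat, 1L, pad_conv))
  apply(mat, 2L, pad_conv)
}

#' Render an attention heatmap for one slide
#'
#' Fills each tile's footprint `[x, x + patch) x [y, y + patch)` with its
#' normalized score on a raster at the working downsample, leaving unscored
#' regions at 0, then (optionally) smooths with a separable bilinear tent
#' kernel of half the tile width. Rendering is deterministic and invariant
#' to tile ordering.
#'
#' @param coords N x 2 matrix of level-0 tile origins (x, y).
#' @param scores Length-N vector of normalized scores in `[0, 1]`.
#' @param slide_dims `(W, H)` level-0 dimensions.
#' @param patch_size_px Tile footprint edge in level-0 pixels.
#' @param downsample Working downsample (default 32).
#' @param smooth Apply bilinear smoothing (default TRUE).
#' @return A `pcm_heatmap`: list with `raster` (matrix in `[0, 1]`,
#'   rows = y), `downsample`, `slide_dims`.
#' @export
render_heatmap <- function(coords, scores, slide_dims, patch_size_px,
                           downsample = 32, smooth = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(scores))
  if (any(scores < 0 | scores > 1)) {
    stop_pcm("scores must be normalized to [0, 1]", "validation_error")
  }
  W <- slide_dims[1]; H <- slide_dims[2]
  if (any(coords[, 1] < 0 | coords[, 2] < 0 |
          coords[, 1] + patch_size_px > W | coords[, 2] + patch_size_px > H)) {
    stop_pcm("tile coordinates fall outside the slide bounds", "geometry_error")
  }
  hw <- ceiling(H / downsample); ww <- ceiling(W / downsample)
  raster <- matrix(0, hw, ww)
  for (i in seq_len(nrow(coords))) {
    cs <- floor(coords[i, 1] / downsample) + 1L
    ce <- max(cs, ceiling((coords[i, 1] + patch_size_px) / downsample))
    rs <- floor(coords[i, 2] / downsample) + 1L
    re <- max(rs, ceiling((coords[i, 2] + patch_size_px) / downsample))
    raster[rs:min(re, hw), cs:min(ce, ww)] <- scores[i]
  }
  if (smooth) {
    raster <- smooth_bilinear(raster, half_width = max(1L, round(patch_size_px / downsample / 2)))
  }
  structure(list(raster = raster, downsample = downsample,
                 slide_dims = slide_dims),
            class = "pcm_heatmap")
}

#' Overlay a heatmap on a slide thumbnail
#'
#' Pixelwise convex blend `out = (1 - alpha) * thumbnail +
#' alpha * colormap(heatmap)` with a perceptually uniform sequential
#' colormap (viridis); the default opacity is 0.3.
#'
#' @param thumbnail RGB array `H x W x 3` in `[0, 1]`, same geometry as the
#'   heatmap raster.
#' @param heatmap A `pcm_heatmap` or a numeric matrix in `[0, 1]`.
#' @param alpha Opacity of the heatmap layer in `[0, 1]` (default 0.3).
#' @param colors Colormap (vector of colors; default 256-step viridis).
#' @return RGB array `H x W x 3`.
#' @export
overlay_heatmap <- function(thumbnail, heatmap, alpha = 0.3,
                            colors = grDevices::hcl.colors(256, "viridis")) {
  if (alpha < 0 || alpha > 1) stop_pcm("alpha must lie in [0, 1]", "validation_error")
  hm <- if (inherits(heatmap, "pcm_heatmap")) heatmap$raster else heatmap
  if (!identical(dim(thumbnail)[1:2], dim(hm))) {
    stop_pcm(sprintf("thumbnail (%s) and heatmap (%s) geometries differ",
                     paste(dim(thumbnail)[1:2], collapse = "x"),
                     paste(dim(hm), collapse = "x")), "geometry_error")
  }
  idx <- pmin(length(colors), pmax(1L, 1L + floor(as.vector(hm) * (length(colors) - 1L) + 0.5)))
  rgb_vals <- grDevices::col2rgb(colors[idx]) / 255
  cm <- array(0, dim(thumbnail))
  cm[, , 1] <- matrix(rgb_vals[1, ], nrow(hm), ncol(hm))
  cm[, , 2] <- matrix(rgb_vals[2, ], nrow(hm), ncol(hm))
  cm[, , 3] <- matrix(rgb_vals[3, ], nrow(hm), ncol(hm))
  (1 - alpha) * thumbnail + alpha * cm
}

#' Attention heatmap for one patient's slide
#'
#' Convenience wrapper: runs the model forward, extracts the attention
#' weights of the requested slide, percentile-normalizes them and renders the
#' spatial heatmap.
#'
#' @param record A `pcm_patient` with loaded bags.
#' @param model A `pcm_model`.
#' @param slide_id Slide to render (default: first bag).
#' @param slide_dims `(W, H)`; defaults to the tile bounding box.
#' @param downsample Working downsample (default 32).
#' @param smooth Apply bilinear smoothing.
#' @return A `pcm_heatmap`.
#' @export
attention_heatmap <- function(record, model, slide_id = NULL,
                              slide_dims = NULL, downsample = 32,
                              smooth = TRUE) {
  fw <- model_forward(record, model)
  pooled <- pool_patient_bag(record)
  sid <- slide_id %||% record$bags[[1L]]$slide_id
  sel <- pooled$provenance$slide_id == sid
  if (!any(sel)) {
    stop_pcm(sprintf("patient has no slide '%s'", sid), "validation_error")
  }
  bag <- record$bags[[match(sid, vapply(record$bags, `[[`, character(1), "slide_id"))]]
  scores <- percentile_normalize(fw$attn[sel])
  if (is.null(slide_dims)) {
    slide_dims <- c(max(bag$coords[, 1]) + bag$patch_size_px,
                    max(bag$coords[, 2]) + bag$patch_size_px)
  }
  render_heatmap(bag$coords, scores, slide_dims, bag$patch_size_px,
                 downsample = downsample, smooth = smooth)
}
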
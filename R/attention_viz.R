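# Attention extraction and heatmap rendering.

#' Attention heatmap of one image
#'
#' Aggregates the image encoder's attention into a per-pixel importance
#' map: head-mean attention per block, attention rollout across blocks
#' (layerwise `(A + I)/2` product, the residual-corrected standard), the
#' CLS row reshaped to the patch grid, bilinear upsampling to the image
#' frame, and per-image min-max normalization to `[0, 1]`.
#'
#' @param model An [stvit_model()].
#' @param image Preprocessed `image_size x image_size x 3` array.
#' @param aggregate `"rollout"` (default) or `"last_layer"`.
#' @return An `attention_map`: list with `grid` (patch-grid weights),
#'   `heat` (H x W normalized map), `layers` (per-block head-mean CLS
#'   attention rows) and `grid_dims`.
#' @export
attention_map <- function(model, image, aggregate = c("rollout",
                                                      "last_layer")) {
  aggregate <- match.arg(aggregate)
  cfg <- model$cfg$encoder
  enc <- encode_image(model, image, return_attention = TRUE)
  if (is.null(enc$attention)) stopf("model returned no attention record")
  ntok <- cfg$n_patches + 1L
  head_mean <- lapply(enc$attention, function(A) {
    M <- A[, , 1]
    if (dim(A)[3] > 1) for (h in 2:dim(A)[3]) M <- M + A[, , h]
    M / dim(A)[3]
  })
  if (aggregate == "rollout") {
    R <- diag(ntok)
    for (M in head_mean) {
      Ahat <- (M + diag(ntok)) / 2
      Ahat <- Ahat / rowSums(Ahat)
      R <- Ahat %*% R
    }
    cls_row <- R[1, -1]
  } else {
    cls_row <- head_mean[[length(head_mean)]][1, -1]
  }
  gh <- cfg$grid[1]
  gw <- cfg$grid[2]
  # cls_row is in patch reading order (grid column fastest)
  grid <- matrix(cls_row, gh, gw, byrow = TRUE)
  heat <- as.matrix(EBImage::resize(EBImage::Image(grid), w = cfg$image_size,
                                    h = cfg$image_size, filter = "bilinear",
                                    antialias = TRUE))
  rng <- range(heat)
  heat_norm <- if (diff(rng) > 0) (heat - rng[1]) / diff(rng) else heat * 0
  structure(list(grid = grid, heat = heat_norm,
                 layers = lapply(head_mean, function(M) M[1, -1]),
                 grid_dims = c(gh, gw)),
            class = "attention_map")
}

# Blue-to-red colormap on [0, 1] (low = blue, high = red).
.heat_rgb <- function(heat) {
  r <- pmin(pmax(1.5 - abs(heat - 0.75) * 4, 0), 1)
  g <- pmin(pmax(1.5 - abs(heat - 0.50) * 4, 0), 1)
  b <- pmin(pmax(1.5 - abs(heat - 0.25) * 4, 0), 1)
  array(c(r, g, b), c(dim(heat), 3))
}

#' Overlay an attention heatmap on its source image
#'
#' Alpha-blends the colormapped heatmap (red = high attention, blue = low)
#' onto the brightfield frame and optionally writes a PNG. Deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param image Grayscale matrix in `[0, 1]` (the raw frame) matching the
#'   map's spatial size.
#' @param amap An [attention_map()].
#' @param alpha Heatmap opacity in `[0, 1]` (0 returns the image unchanged,
#'   1 the pure colormap).
#' @param file Optional PNG output path.
#' @return H x W x 3 RGB array (invisibly when writing a file).
#' @export
overlay_heatmap <- function(image, amap, alpha = 0.45, file = NULL) {
  heat <- amap$heat
  if (!all(dim(image)[1:2] == dim(heat))) {
    stopf("image (%d x %d) and heatmap (%d x %d) sizes differ",
          nrow(image), ncol(image), nrow(heat), ncol(heat))
  }
  base <- array(rep(as.numeric(image), 3), c(dim(heat), 3))
  rgb <- (1 - alpha) * base + alpha * .heat_rgb(heat)
  rgb <- pmin(pmax(rgb, 0), 1)
  if (!is.null(file)) {
    EBImage::writeImage(EBImage::Image(rgb, colormode = "Color"), file,
                        type = "png")
    return(invisible(rgb))
  }
  rgb
}

#' Per-day attention summaries for a stack
#'
#' Mean rollout CLS-attention weight per frame, summarised by day — a
#' tabular view of where in time the encoder concentrates.
#'
#' @param model An [stvit_model()].
#' @param stack An `organoid_stack` (raw; preprocessed internally).
#' @return Tibble: `day`, `z`, `mean_weight`, `max_weight`.
#' @export
attention_by_day <- function(model, stack) {
  prep <- preprocess_stack(stack, size = model$cfg$encoder$image_size)
  rows <- list()
  for (d in seq_along(prep$images)) {
    for (z in seq_along(prep$images[[d]])) {
      am <- attention_map(model, prep$images[[d]][[z]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        day = stack$day_indices[d], z = z - 1L,
        mean_weight = mean(am$grid), max_weight = max(am$grid))
    }
  }
  dplyr::bind_rows(rows)
}
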
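# Field rendering for the synthetic organoid simulator.
#
# An organoid state is a list with fields:
#   cx, cy        centre in pixels
#   radius        current radius in pixels
#   ring          rim thickness in pixels
#   focal_depth   normalized depth in [0, 1] at which the organoid is sharp
#   fragments     NULL while intact, else a data.frame (cx, cy, radius) of
#                 the blobs it has disintegrated into

# Additive intensity layer (deviation from background) of one intact
# organoid: translucent bright lumen surrounded by a darker rim.
.organoid_layer <- function(n, cx, cy, r, ring) {
  d <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`))
  layer <- matrix(0, n, n)
  layer[d <= r + ring / 2] <- -0.32            # dark rim disc
  layer[d <= r - ring / 2] <- 0.14             # translucent hollow lumen
  layer
}

.fragment_layer <- function(n, frags) {
  layer <- matrix(0, n, n)
  for (i in seq_len(nrow(frags))) {
    d <- sqrt(outer((seq_len(n) - frags$cy[i])^2,
                    (seq_len(n) - frags$cx[i])^2, `+`))
    layer[d <= frags$radius[i]] <- -0.45       # condensed dark debris blob
  }
  layer
}

.gblur <- function(x, sigma) {
  if (sigma < 0.35) return(x)
  as.matrix(EBImage::gblur(x, sigma = sigma))
}

#' Render one synthetic brightfield frame
#'
#' Draws a field of organoids at a given focal plane. Intact organoids are
#' rendered as hollow spheres (bright lumen, darker rim); disintegrated
#' organoids as scattered dark debris blobs. Each organoid is blurred with a
#' Gaussian of sigma `defocus_sigma_per_plane * |z_offset - focal_depth|`,
#' so only organoids near the plane's depth appear sharp. Additive Gaussian
#' noise is applied and the frame clipped to `[0, 1]`.
#'
#' @param day 0-based day index (recorded only; states already carry the
#'   day's geometry).
#' @param z_offset Normalized focal depth of the rendered plane, in `[0, 1]`.
#' @param organoid_states List of organoid states (see the file header);
#'   empty list renders a bare background.
#' @param cfg A [sim_config()].
#' @param seed Optional seed for the noise draw; when `NULL` the current RNG
#'   stream is used (as inside [generate_sample()]).
#' @return `image_size x image_size` matrix of intensities in `[0, 1]`.
#' @export
render_field <- function(day, z_offset, organoid_states, cfg, seed = NULL) {
  n <- cfg$image_size
  if (n <= 0) stopf("image size must be positive")
  canvas <- matrix(SIM_BACKGROUND, n, n)
  for (st in organoid_states) {
    if (st$radius < 0) stopf("negative organoid radius")
    layer <- if (is.null(st$fragments)) {
      .organoid_layer(n, st$cx, st$cy, st$radius, st$ring)
    } else {
      .fragment_layer(n, st$fragments)
    }
    sigma <- cfg$defocus_sigma_per_plane * abs(z_offset - st$focal_depth)
    canvas <- canvas + .gblur(layer, sigma)
  }
  add_noise <- function(x) {
    if (cfg$noise_sd > 0) x <- x + matrix(rnorm(n * n, sd = cfg$noise_sd), n, n)
    pmin(pmax(x, 0), 1)
  }
  if (is.null(seed)) add_noise(canvas) else withr::with_seed(seed, add_noise(canvas))
}

#' Foreground mask of a synthetic frame
#'
#' Pixels deviating from the background grey by more than `thresh`; used by
#' the hand-crafted morphology features and by tests.
#'
#' @param img Intensity matrix in `[0, 1]`.
#' @param thresh Absolute deviation threshold (default 0.08).
#' @return Logical matrix.
#' @export
foreground_mask <- function(img, thresh = 0.08) {
  abs(img - stats::median(img)) > thresh
}

#' Count connected foreground components
#'
#' 4-connectivity labelling of a logical mask (via `EBImage::bwlabel`),
#' ignoring components smaller than `min_px` pixels.
#'
#' @param mask Logical matrix.
#' @param min_px Minimum component area in pixels (default 5).
#' @return Integer component count.
#' @export
count_components <- function(mask, min_px = 5) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(0L)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_px)
}
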
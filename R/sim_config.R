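#' Simulator configuration
#'
#' Parameters of the synthetic brightfield organoid generator. The generator
#' emulates the three phenotype classes seen in organoid DILI assays:
#' `vNo-DILI-Concern` organoids grow into translucent hollow spheres,
#' `vLess-DILI-Concern` organoids arrest but keep an intact sphere, and
#' `vMost-DILI-Concern` organoids disintegrate into scattered fragments from
#' the onset day (default Day 2) onward. Each sample is a T-day series of
#' Z-plane focal stacks; planes away from an organoid's focal depth are
#' defocused with a Gaussian blur that grows linearly with the depth offset.
#'
#' Geometry defaults scale with `image_size` so the same phenotype dynamics
#' can be rendered at reduced resolution for fast experiments.
#'
#' @param image_size Pixels per side of each square frame (default 224).
#' @param n_days Number of daily time points, Day 0 .. Day `n_days - 1`
#'   (default 4).
#' @param z_planes_range Inclusive integer range of focal planes per sample
#'   (default `c(12, 20)`); Z is drawn once per sample and shared by all days.
#' @param organoids_per_field Integer range of organoids per field
#'   (default `c(2, 6)`); fewer may be placed when the field is too crowded
#'   to respect minimum separation.
#' @param init_radius_px Range of initial organoid radii in pixels; default
#'   scales with `image_size` (10.1--14.6 px at 224).
#' @param growth_rate_per_day Named per-class relative radius growth per day;
#'   must satisfy `vNo > vLess`, and `vMost` applies only before
#'   disintegration onset.
#' @param disintegration_onset_day Day (0-based) at which `vMost` organoids
#'   fragment (default 2).
#' @param fragment_count_range Range of fragments each disintegrating
#'   organoid breaks into (default `c(3, 5)`).
#' @param defocus_sigma_per_plane Gaussian blur sigma, in pixels per unit of
#'   normalized focal-depth offset (depths span `[0, 1]` across the stack);
#'   default scales with `image_size` (10 px at 224).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (default 0.02 on the `[0, 1]` scale).
#' @param seed Default seed used when a generator call does not supply one.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(image_size = 64, z_planes_range = c(4, 6))
#' cfg$image_size
sim_config <- function(image_size = 224,
                       n_days = 4,
                       z_planes_range = c(12L, 20L),
                       organoids_per_field = c(2L, 6L),
                       init_radius_px = pmax(image_size * c(0.045, 0.065),
                                             c(4.5, 6.5)),
                       growth_rate_per_day = c(vNo = 0.35, vLess = 0.02,
                                               vMost = 0.05),
                       disintegration_onset_day = 2L,
                       fragment_count_range = c(3L, 5L),
                       defocus_sigma_per_plane = 10 * image_size / 224,
                       noise_sd = 0.02,
                       seed = 1L) {
  if (image_size <= 0) stopf("image_size must be positive")
  if (n_days < 1) stopf("n_days must be >= 1")
  if (any(init_radius_px <= 0)) stopf("init_radius_px must be positive")
  if (length(z_planes_range) != 2 || z_planes_range[1] > z_planes_range[2] ||
      z_planes_range[1] < 1) {
    stopf("z_planes_range must be an increasing positive integer range")
  }
  nms <- c("vNo", "vLess", "vMost")
  if (!all(nms %in% names(growth_rate_per_day))) {
    stopf("growth_rate_per_day needs named entries vNo, vLess, vMost")
  }
  if (growth_rate_per_day[["vNo"]] <= growth_rate_per_day[["vLess"]]) {
    stopf("growth_rate_per_day must satisfy vNo > vLess")
  }
  structure(list(
    image_size = as.integer(image_size),
    n_days = as.integer(n_days),
    z_planes_range = as.integer(z_planes_range),
    organoids_per_field = as.integer(organoids_per_field),
    init_radius_px = init_radius_px,
    growth_rate_per_day = growth_rate_per_day[nms],
    disintegration_onset_day = as.integer(disintegration_onset_day),
    fragment_count_range = as.integer(fragment_count_range),
    defocus_sigma_per_plane = defocus_sigma_per_plane,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Background grey level of the synthetic brightfield field.
SIM_BACKGROUND <- 0.55
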
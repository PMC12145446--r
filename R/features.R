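# Hand-crafted morphology features. These exist to certify that the
# synthetic classes are separable by construction (so the learning task is
# solvable) and to probe how much of that separation is temporal.

#' Equivalent foreground radius of a frame
#'
#' Radius of the disc with the same area as the thresholded foreground.
#'
#' @param img Intensity matrix.
#' @param thresh Foreground threshold (see [foreground_mask()]).
#' @return Radius in pixels.
#' @export
equivalent_radius <- function(img, thresh = 0.08) {
  sqrt(sum(foreground_mask(img, thresh)) / pi)
}

#' Morphology features of one stack
#'
#' Focus-fuses each day ([fuse_zstack()]) and measures foreground area and
#' connected-component count; summarises growth and fragmentation between
#' the first and last observed day.
#'
#' @param stack An `organoid_stack` (raw frames).
#' @param thresh Foreground threshold.
#' @param days Restrict to these 0-based days (default all), e.g. `0:1` for
#'   an early-window analysis.
#' @return One-row tibble: `sample_id`, `label`, `area_ratio` (last/first
#'   day foreground area), `comp_ratio` (last/first component count),
#'   `n_comp_last`.
#' @export
stack_features <- function(stack, thresh = 0.08, days = NULL) {
  if (!is.null(days)) {
    keep <- stack$day_indices %in% days
    stack$images <- stack$images[keep]
    stack$day_indices <- stack$day_indices[keep]
  }
  fused <- fuse_zstack(stack)
  per_day <- lapply(fused$images, function(d) {
    m <- foreground_mask(d[[1]], thresh)
    list(area = sum(m), ncomp = count_components(m))
  })
  first <- per_day[[1]]
  last <- per_day[[length(per_day)]]
  tibble::tibble(
    sample_id = stack$sample_id,
    label = as.character(stack$label),
    area_ratio = last$area / max(first$area, 1),
    comp_ratio = last$ncomp / max(first$ncomp, 1),
    n_comp_last = last$ncomp)
}

#' Feature table for a set of stacks
#'
#' @param stacks Named list of `organoid_stack`.
#' @inheritParams stack_features
#' @return Tibble with one row per stack.
#' @export
dataset_features <- function(stacks, thresh = 0.08, days = NULL) {
  dplyr::bind_rows(lapply(stacks, stack_features, thresh = thresh,
                          days = days))
}

#' Classify stacks by the hand-crafted feature rule
#'
#' A two-threshold linear rule on [stack_features()]: fragmentation
#' (`comp_ratio` above `frag_cut`) indicates `vMost`; otherwise clear growth
#' (`area_ratio` above `growth_cut`) indicates `vNo`; otherwise `vLess`.
#'
#' @param features Tibble from [dataset_features()].
#' @param frag_cut Component-ratio cut (default 1.5).
#' @param growth_cut Area-ratio cut (default 1.8).
#' @return Factor of predicted labels in [dili_levels()] order.
#' @export
feature_rule_classify <- function(features, frag_cut = 1.5,
                                  growth_cut = 1.8) {
  pred <- ifelse(features$comp_ratio > frag_cut, dili_levels()[3],
                 ifelse(features$area_ratio > growth_cut, dili_levels()[1],
                        dili_levels()[2]))
  factor(pred, levels = dili_levels())
}
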
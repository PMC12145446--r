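# Image preprocessing: resize, channel replication, standardization.

#' Preprocess a raw image for the encoder
#'
#' Applies the model's fixed input pipeline: anti-aliased bilinear resize to
#' `size x size`, replication of grayscale input to three channels, rescaling
#' of integer intensities to `[0, 1]`, then per-channel standardization with
#' fixed constants (`(x - mean) / sd`; defaults 0.5/0.5 map `[0, 1]` to
#' `[-1, 1]`). Fixed constants keep inference independent of dataset
#' composition; pass dataset statistics to override.
#'
#' @param img Matrix (grayscale) or H x W x 3 array; any spatial size.
#'   Integer-scaled input (max > 1) is assumed 8-bit (max <= 255) or 16-bit.
#' @param size Output spatial size (default 224).
#' @param mean,sd Standardization constants (scalars or per-channel length-3).
#' @return `size x size x 3` array of standardized intensities.
#' @export
#' @examples
#' x <- preprocess_image(matrix(runif(100), 10, 10), size = 32)
#' dim(x)
preprocess_image <- function(img, size = 224, mean = 0.5, sd = 0.5) {
  if (length(img) == 0) stopf("empty image")
  if (!all(is.finite(img))) stopf("image contains non-finite pixels")
  d <- dim(img)
  if (is.null(d) || !(length(d) == 2 || (length(d) == 3 && d[3] == 3))) {
    stopf("expected a 2-D grayscale matrix or an H x W x 3 array")
  }
  mx <- max(img)
  if (mx > 1) img <- img / (if (mx <= 255) 255 else 65535)
  if (length(d) == 2) {
    if (!all(d[1:2] == size)) {
      img <- as.matrix(EBImage::resize(EBImage::Image(img), w = size,
                                       h = size, filter = "bilinear",
                                       antialias = TRUE))
    }
    img <- array(img, dim = c(size, size, 3))
  } else {
    if (!all(d[1:2] == size)) {
      img <- EBImage::imageData(EBImage::resize(
        EBImage::Image(img, colormode = "Color"), w = size, h = size,
        filter = "bilinear", antialias = TRUE))
    }
  }
  mean <- rep_len(mean, 3)
  sd <- rep_len(sd, 3)
  for (c in 1:3) img[, , c] <- (img[, , c] - mean[c]) / sd[c]
  img
}

#' Preprocess every frame of a stack
#'
#' @param stack An `organoid_stack`.
#' @inheritParams preprocess_image
#' @return The stack with each frame replaced by its preprocessed
#'   `size x size x 3` array; marked with attribute `preprocessed = TRUE`.
#' @export
preprocess_stack <- function(stack, size = 224, mean = 0.5, sd = 0.5) {
  stack$images <- lapply(stack$images, function(day) {
    lapply(day, preprocess_image, size = size, mean = mean, sd = sd)
  })
  attr(stack, "preprocessed") <- TRUE
  stack
}
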
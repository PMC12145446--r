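# Focus stacking: collapse a z-stack to one all-in-focus image per day.

# Local Laplacian-variance sharpness of one frame (window w x w).
.sharpness <- function(img, w = 9) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  l <- EBImage::filter2(img, lap)
  box <- matrix(1 / (w * w), w, w)
  m <- EBImage::filter2(l, box)
  v <- EBImage::filter2(l * l, box) - m * m
  as.matrix(v)
}

#' Fuse a z-stack by per-pixel sharpest plane
#'
#' Stand-in for the proprietary instrument fusion: for each pixel the focal
#' plane with maximal local Laplacian-variance sharpness (9 x 9 window) is
#' selected, yielding one all-in-focus composite per day. With Z = 1 the
#' single plane is returned unchanged.
#'
#' @param stack An `organoid_stack` with raw grayscale frames.
#' @param window Sharpness window side (default 9).
#' @return The stack with one fused frame per day (`Z = 1`).
#' @export
fuse_zstack <- function(stack, window = 9) {
  stack$images <- lapply(stack$images, function(planes) {
    if (length(planes) == 1) return(planes)
    fused <- planes[[1]]
    best <- .sharpness(planes[[1]], window)
    for (z in 2:length(planes)) {
      s <- .sharpness(planes[[z]], window)
      take <- s > best
      fused[take] <- planes[[z]][take]
      best[take] <- s[take]
    }
    list(fused)
  })
  stack$z_positions <- 0.5
  attr(stack, "fused") <- TRUE
  stack
}
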
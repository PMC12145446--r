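# Lossless patch extraction and reassembly.

#' Split an image into flattened non-overlapping patches
#'
#' Divides an H x W x C image into `N = H*W/P^2` patches of `P x P` pixels in
#' reading order (left to right, then top to bottom) and flattens each to a
#' row of length `P^2 * C`. The operation is lossless: [unpatchify()]
#' reproduces the input bit-exactly.
#'
#' @param img H x W matrix or H x W x C array; P must divide H and W.
#' @param P Patch side length in pixels (default 16).
#' @return N x (P^2*C) matrix with attributes `grid` (rows, cols of the patch
#'   grid) and `channels`.
#' @export
#' @examples
#' p <- patchify(array(runif(32 * 32 * 3), c(32, 32, 3)), P = 16)
#' dim(p)  # 4 patches of length 768
patchify <- function(img, P = 16) {
  d <- dim(img)
  if (length(d) == 2) {
    img <- array(img, c(d, 1L))
    d <- dim(img)
  }
  if (d[1] %% P != 0 || d[2] %% P != 0) {
    stopf("patch size %d does not divide image dims %d x %d", P, d[1], d[2])
  }
  gh <- d[1] %/% P
  gw <- d[2] %/% P
  ch <- d[3]
  dim(img) <- c(P, gh, P, gw, ch)
  # rows ordered with the grid column fastest => reading order over the grid
  out <- aperm(img, c(4, 2, 1, 3, 5))
  dim(out) <- c(gw * gh, P * P * ch)
  attr(out, "grid") <- c(gh, gw)
  attr(out, "channels") <- ch
  out
}

#' Reassemble patches into an image
#'
#' Inverse of [patchify()].
#'
#' @param patches N x (P^2*C) matrix, ordered as produced by [patchify()].
#' @param grid Patch grid dims `c(rows, cols)`; taken from the attribute if
#'   present.
#' @param P Patch side length.
#' @param channels Channel count; taken from the attribute if present.
#' @return H x W x C array (H x W matrix when C = 1).
#' @export
unpatchify <- function(patches, grid = attr(patches, "grid"), P = 16,
                       channels = attr(patches, "channels") %||% 1L) {
  if (is.null(grid)) stopf("grid dims required")
  gh <- grid[1]
  gw <- grid[2]
  x <- patches
  attributes(x) <- NULL
  dim(x) <- c(gw, gh, P, P, channels)
  img <- aperm(x, c(3, 2, 4, 1, 5))
  dim(img) <- c(gh * P, gw * P, channels)
  if (channels == 1) img <- img[, , 1] else img
}
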
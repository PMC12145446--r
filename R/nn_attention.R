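# Multi-head self-attention over batched equal-length segments.
#
# The packed projection U_qkv has dimension D x (3 * dh * k); for head h the
# column block ((h-1)*3*dh + 1):(h*3*dh) is that head's D x 3dh projection
# [q | k | v], matching the per-head formulation. U_msa is (k*dh) x D.
# The segment/head loops run in C++ (src/nn_kernels.cpp); attention maps
# come back as an (ntok x ntok x k*nseg) array, slice index (s-1)*k + h.

.head_cols <- function(h, dh) {
  off <- (h - 1) * 3 * dh
  list(q = off + 1:dh, k = off + dh + 1:dh, v = off + 2 * dh + 1:dh)
}

# Reformat the packed attention array into one (ntok x ntok x k) array per
# segment (the layout the public API and the visualizer use).
attn_to_list <- function(attn, k, nseg) {
  lapply(seq_len(nseg), function(s) {
    attn[, , ((s - 1) * k + 1):(s * k), drop = FALSE]
  })
}

# X: (nseg*ntok) x D; segments are contiguous row blocks.
msa_fwd <- function(X, Uqkv, Umsa, k, dh, nseg, ntok, keep_attn = TRUE) {
  r <- cpp_msa_fwd(X, Uqkv, Umsa, k, dh, nseg, ntok)
  list(Y = r$Y,
       attn = if (keep_attn) attn_to_list(r$attn, k, nseg) else NULL,
       cache = list(X = X, QKV = r$QKV, heads = r$heads, attn = r$attn,
                    k = k, dh = dh, nseg = nseg, ntok = ntok))
}

msa_bwd <- function(dY, cache, Uqkv, Umsa) {
  r <- cpp_msa_bwd(dY, cache$X, cache$QKV, cache$heads, cache$attn,
                   Uqkv, Umsa, cache$k, cache$dh, cache$nseg, cache$ntok)
  list(dX = r$dX, dUqkv = r$dUqkv, dUmsa = r$dUmsa)
}

#' Scaled dot-product self-attention (single head)
#'
#' Computes `softmax(q k' / sqrt(dh)) v` with `[q, k, v] = x U_qkv`, the
#' attention primitive of every encoder block. The attention matrix is
#' returned for visualization; each of its rows sums to 1.
#'
#' @param x Token matrix, N x D.
#' @param U_qkv Packed projection, D x 3dh (columns `[q | k | v]`).
#' @return List with `output` (N x dh) and `attention` (N x N,
#'   row-stochastic).
#' @export
#' @examples
#' sa <- self_attention(matrix(rnorm(8), 2, 4), matrix(rnorm(4 * 3), 4, 3))
#' rowSums(sa$attention)
self_attention <- function(x, U_qkv) {
  if (ncol(x) != nrow(U_qkv)) stopf("token dim %d does not match U_qkv rows %d",
                                    ncol(x), nrow(U_qkv))
  if (ncol(U_qkv) %% 3 != 0) stopf("U_qkv must have 3*dh columns")
  dh <- ncol(U_qkv) %/% 3
  r <- msa_fwd(x, U_qkv, diag(dh), k = 1, dh = dh, nseg = 1, ntok = nrow(x))
  list(output = r$Y, attention = r$attn[[1]][, , 1])
}

#' Multi-head self-attention
#'
#' Runs k attention heads and projects their concatenated outputs:
#' `MSA(x) = [SA_1(x); ...; SA_k(x)] U_msa`.
#'
#' @param x Token matrix, N x D.
#' @param U_qkv Either a list of k per-head D x 3dh projections or the packed
#'   D x (3*dh*k) matrix (then `n_heads` must be given).
#' @param U_msa Output projection, (k*dh) x D.
#' @param n_heads Head count k when `U_qkv` is already packed (default 1).
#' @return List with `output` (N x D) and `attention` (N x N x k array of
#'   row-stochastic per-head matrices).
#' @export
multi_head_attention <- function(x, U_qkv, U_msa, n_heads = 1L) {
  if (is.list(U_qkv)) {
    n_heads <- length(U_qkv)
    U_qkv <- do.call(cbind, U_qkv)
  }
  if (ncol(x) != nrow(U_qkv)) stopf("token dim mismatch with U_qkv")
  if (ncol(U_qkv) %% (3 * n_heads) != 0) {
    stopf("U_qkv columns (%d) must be 3*dh per head for %d heads",
          ncol(U_qkv), n_heads)
  }
  dh <- ncol(U_qkv) %/% (3L * n_heads)
  if (nrow(U_msa) != n_heads * dh) {
    stopf("U_msa rows (%d) must equal k*dh = %d", nrow(U_msa), n_heads * dh)
  }
  r <- msa_fwd(x, U_qkv, U_msa, k = n_heads, dh = dh, nseg = 1,
               ntok = nrow(x))
  list(output = r$Y, attention = r$attn[[1]])
}
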
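# Pre-LN transformer encoder blocks and block stacks.
#
# Block parameter tree: list(ln1 = list(g, b), attn = list(Uqkv, Umsa),
# ln2 = list(g, b), mlp = list(W1, b1, W2, b2)). A block computes
#   z' = MSA(LN(z)) + z ;  z_out = MLP(LN(z')) + z'
# and an encoder of depth L applies L blocks followed by a final LayerNorm.

init_ln <- function(d) list(g = rep(1, d), b = rep(0, d))

init_block_params <- function(d, n_heads, mlp_ratio = 4) {
  dh <- d %/% n_heads
  mh <- round(d * mlp_ratio)
  list(
    ln1 = init_ln(d),
    attn = list(Uqkv = tn_mat(d, 3 * dh * n_heads), Umsa = tn_mat(n_heads * dh, d)),
    ln2 = init_ln(d),
    mlp = list(W1 = tn_mat(d, mh), b1 = rep(0, mh),
               W2 = tn_mat(mh, d), b2 = rep(0, d))
  )
}

block_fwd <- function(X, p, k, dh, nseg, ntok, eps, keep_attn = TRUE) {
  l1 <- ln_fwd(X, p$ln1$g, p$ln1$b, eps)
  att <- msa_fwd(l1$Y, p$attn$Uqkv, p$attn$Umsa, k, dh, nseg, ntok,
                 keep_attn = keep_attn)
  X1 <- X + att$Y
  l2 <- ln_fwd(X1, p$ln2$g, p$ln2$b, eps)
  f1 <- linear_fwd(l2$Y, p$mlp$W1, p$mlp$b1)
  g1 <- gelu_fwd(f1$Y)
  f2 <- linear_fwd(g1$Y, p$mlp$W2, p$mlp$b2)
  list(Y = X1 + f2$Y, attn = att$attn,
       cache = list(l1 = l1$cache, att = att$cache, l2 = l2$cache,
                    f1 = f1$cache, g1 = g1$cache, f2 = f2$cache))
}

block_bwd <- function(dY, cache, p) {
  b2 <- linear_bwd(dY, cache$f2, p$mlp$W2)
  dg <- gelu_bwd(b2$dX, cache$g1)
  b1 <- linear_bwd(dg, cache$f1, p$mlp$W1)
  l2 <- ln_bwd(b1$dX, cache$l2)
  dX1 <- dY + l2$dX
  ab <- msa_bwd(dX1, cache$att, p$attn$Uqkv, p$attn$Umsa)
  l1 <- ln_bwd(ab$dX, cache$l1)
  list(
    dX = dX1 + l1$dX,
    g = list(ln1 = list(g = l1$dg, b = l1$db),
             attn = list(Uqkv = ab$dUqkv, Umsa = ab$dUmsa),
             ln2 = list(g = l2$dg, b = l2$db),
             mlp = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
  )
}

init_encoder_params <- function(depth, d, n_heads, mlp_ratio = 4) {
  blocks <- lapply(seq_len(depth), function(i) {
    init_block_params(d, n_heads, mlp_ratio)
  })
  names(blocks) <- paste0("block", seq_len(depth))
  list(blocks = blocks, ln_f = init_ln(d))
}

# Flatten a block's parameter tree into the layout the C++ encoder expects.
.block_flat <- function(p) {
  list(ln1_g = p$ln1$g, ln1_b = p$ln1$b, Uqkv = p$attn$Uqkv,
       Umsa = p$attn$Umsa, ln2_g = p$ln2$g, ln2_b = p$ln2$b,
       W1 = p$mlp$W1, b1 = p$mlp$b1, W2 = p$mlp$W2, b2 = p$mlp$b2)
}

# Full encoder: L blocks + final LN, in one C++ call. Returns final tokens,
# per-block attention (when requested), and the backward-pass caches.
encoder_fwd <- function(X, enc, k, dh, nseg, ntok, eps, keep_attn = TRUE) {
  flat <- lapply(enc$blocks, .block_flat)
  r <- cpp_encoder_fwd(X, flat, enc$ln_f$g, enc$ln_f$b, k, dh, nseg, ntok,
                       eps, keep_attn)
  attn <- NULL
  if (keep_attn) {
    attn <- lapply(r$attn, attn_to_list, k = k, nseg = nseg)
  }
  list(Y = r$Y, attn = attn,
       cache = list(flat = flat, caches = r$caches, xhatf = r$xhatf,
                    invf = r$invf, k = k, dh = dh, nseg = nseg,
                    ntok = ntok))
}

encoder_bwd <- function(dY, cache, enc) {
  r <- cpp_encoder_bwd(dY, cache$flat, cache$caches, cache$xhatf,
                       cache$invf, enc$ln_f$g, cache$k, cache$dh,
                       cache$nseg, cache$ntok)
  gblocks <- lapply(r$grads, function(g) {
    list(ln1 = list(g = drop(g$ln1_g), b = drop(g$ln1_b)),
         attn = list(Uqkv = g$Uqkv, Umsa = g$Umsa),
         ln2 = list(g = drop(g$ln2_g), b = drop(g$ln2_b)),
         mlp = list(W1 = g$W1, b1 = drop(g$b1), W2 = g$W2, b2 = drop(g$b2)))
  })
  names(gblocks) <- names(enc$blocks)
  list(dX = r$dX,
       g = list(blocks = gblocks,
                ln_f = list(g = drop(r$lnf_g), b = drop(r$lnf_b))))
}

#' Initialize one transformer block's parameters
#'
#' Truncated-normal weights (sd 0.02), unit LayerNorm gain; mainly for
#' examples and direct experimentation with [vit_block()].
#'
#' @param d Token dimension D.
#' @param n_heads Head count k (must divide `d`).
#' @param mlp_ratio Hidden width of the MLP as a multiple of `d` (default 4).
#' @param seed Optional seed.
#' @return Parameter list (`ln1`, `attn`, `ln2`, `mlp`).
#' @export
init_vit_block <- function(d, n_heads, mlp_ratio = 4, seed = NULL) {
  if (d %% n_heads != 0) stopf("n_heads must divide d")
  if (is.null(seed)) return(init_block_params(d, n_heads, mlp_ratio))
  withr::with_seed(seed, init_block_params(d, n_heads, mlp_ratio))
}

#' Apply one pre-LN transformer encoder block
#'
#' `z' = MSA(LN(z)) + z` followed by `z_out = MLP(LN(z')) + z'`; shape is
#' preserved. With the attention output projection and the MLP second layer
#' zeroed, the block is the identity (only the residual path remains).
#'
#' @param x Token matrix, (N+1) x D.
#' @param params Parameters from [init_vit_block()].
#' @param n_heads Head count used to interpret the packed projections.
#' @param ln_eps LayerNorm epsilon.
#' @return List with `output` (same shape as `x`) and `attention`
#'   (N+1 x N+1 x k).
#' @export
vit_block <- function(x, params, n_heads, ln_eps = 1e-6) {
  d <- ncol(x)
  if (d %% n_heads != 0) stopf("n_heads must divide token dimension")
  r <- block_fwd(x, params, k = n_heads, dh = d %/% n_heads, nseg = 1,
                 ntok = nrow(x), eps = ln_eps)
  list(output = r$Y, attention = r$attn[[1]])
}
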
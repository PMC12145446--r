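# The image-spatial-temporal classifier.
#
# Pipeline per sample: every (day, z) frame -> patch embedding -> ViT image
# encoder -> image CLS token; per day the Z image CLS tokens -> two-block
# ViT spatial encoder (no positional encoding, so z order is immaterial) ->
# spatial CLS token; the T spatial CLS tokens -> Bi-LSTM -> concatenated
# final hidden states -> MLP -> 3 class logits.

#' Image encoder configuration
#'
#' @param image_size Input side length in pixels (default 224).
#' @param patch_size Patch side P (default 16); must divide `image_size`.
#' @param embed_dim Token dimension D (default 64, the desk-scale
#'   configuration; set 768/12/12 for a full-scale ViT).
#' @param depth Number of encoder blocks L (default 2).
#' @param n_heads Attention heads k (default 4); must divide `embed_dim`.
#' @param mlp_ratio MLP hidden width as a multiple of D (default 4).
#' @param ln_eps LayerNorm epsilon (default 1e-6).
#' @param mask_ratio Fraction of patches masked in masked-image-modeling
#'   mode (default 0.4); unused during classification.
#' @param pos_embed `"learnable_2d"` (a learnable embedding per grid
#'   position, standard ViT practice) or `"none"`.
#' @return An `encoder_config` list (includes `n_patches` and `head_dim`).
#' @export
encoder_config <- function(image_size = 224, patch_size = 16, embed_dim = 64,
                           depth = 2, n_heads = 4, mlp_ratio = 4,
                           ln_eps = 1e-6, mask_ratio = 0.4,
                           pos_embed = c("learnable_2d", "none")) {
  pos_embed <- match.arg(pos_embed)
  if (image_size %% patch_size != 0) {
    stopf("patch_size %d must divide image_size %d", patch_size, image_size)
  }
  if (embed_dim %% n_heads != 0) stopf("n_heads must divide embed_dim")
  if (mask_ratio < 0 || mask_ratio >= 1) stopf("mask_ratio must be in [0, 1)")
  grid <- image_size %/% patch_size
  structure(list(
    image_size = as.integer(image_size), patch_size = as.integer(patch_size),
    embed_dim = as.integer(embed_dim), depth = as.integer(depth),
    n_heads = as.integer(n_heads),
    head_dim = as.integer(embed_dim %/% n_heads),
    mlp_ratio = mlp_ratio, ln_eps = ln_eps, mask_ratio = mask_ratio,
    pos_embed = pos_embed, grid = c(grid, grid),
    n_patches = as.integer(grid * grid)
  ), class = "encoder_config")
}

#' Spatial encoder configuration
#'
#' The spatial encoder is fixed at two blocks and uses no positional
#' encoding, making its output invariant to the order of focal planes (Z
#' varies between samples).
#'
#' @param depth Must be 2.
#' @return A `spatial_config` list.
#' @export
spatial_config <- function(depth = 2) {
  if (depth != 2) stopf("the spatial encoder depth is fixed at 2")
  structure(list(depth = 2L), class = "spatial_config")
}

#' Temporal encoder configuration
#'
#' @param hidden Bi-LSTM hidden size per direction (default 64); the pooled
#'   feature is the concatenation of the final forward and final backward
#'   hidden states, length `2 * hidden`.
#' @return A `temporal_config` list.
#' @export
temporal_config <- function(hidden = 64) {
  structure(list(hidden = as.integer(hidden), bidirectional = TRUE,
                 pooling = "final_concat"), class = "temporal_config")
}

#' Build a spatiotemporal ViT classifier
#'
#' Initializes all learnable components (patch embedding, image CLS token,
#' positional embeddings, mask embedding, image and spatial encoder blocks,
#' Bi-LSTM, MLP head) with truncated-normal weights (sd 0.02), unit
#' LayerNorm gains, zero biases and forget-gate bias 1.
#'
#' @param encoder An [encoder_config()].
#' @param spatial A [spatial_config()].
#' @param temporal A [temporal_config()].
#' @param n_classes Number of classes (default 3).
#' @param use_spatial Keep the spatial encoder (default `TRUE`); when
#'   `FALSE` each day must supply exactly one image whose CLS token feeds
#'   the Bi-LSTM directly (the spatial-ablation variant).
#' @param seed Initialization seed.
#' @return An `stvit` model object (list with `params`, `cfg`).
#' @export
#' @examples
#' m <- stvit_model(encoder_config(image_size = 32, embed_dim = 8,
#'                                 n_heads = 2), seed = 1)
#' names(m$params)
stvit_model <- function(encoder = encoder_config(),
                        spatial = spatial_config(),
                        temporal = temporal_config(),
                        n_classes = 3L, use_spatial = TRUE, seed = 42L) {
  d <- encoder$embed_dim
  pdim <- encoder$patch_size^2 * 3L
  h <- temporal$hidden
  params <- withr::with_seed(as.integer(seed), {
    img <- list(
      patch_W = tn_mat(pdim, d), patch_b = rep(0, d),
      cls = tn_mat(1, d), e_mask = tn_mat(1, d),
      enc = init_encoder_params(encoder$depth, d, encoder$n_heads,
                                encoder$mlp_ratio),
      mim = list(W = tn_mat(d, pdim), b = rep(0, pdim))
    )
    if (encoder$pos_embed == "learnable_2d") {
      img$pos <- tn_mat(encoder$n_patches + 1L, d)
    }
    spa <- list(
      cls = tn_mat(1, d),
      enc = init_encoder_params(spatial$depth, d, encoder$n_heads,
                                encoder$mlp_ratio)
    )
    tem <- list(f = init_lstm_dir(d, h), b = init_lstm_dir(d, h))
    head <- list(W1 = tn_mat(2 * h, d), b1 = rep(0, d),
                 W2 = tn_mat(d, n_classes), b2 = rep(0, n_classes))
    if (use_spatial) list(img = img, spa = spa, tem = tem, head = head)
    else list(img = img, tem = tem, head = head)
  })
  structure(list(
    params = params,
    cfg = list(encoder = encoder, spatial = spatial, temporal = temporal,
               n_classes = as.integer(n_classes), use_spatial = use_spatial,
               class_order = dili_levels(), seed = as.integer(seed))
  ), class = "stvit")
}

#' @export
print.stvit <- function(x, ...) {
  e <- x$cfg$encoder
  cat(sprintf(
    paste0("<stvit> D=%d L=%d heads=%d patch=%d image=%d | spatial %s | ",
           "Bi-LSTM hidden=%d | %d classes\n"),
    e$embed_dim, e$depth, e$n_heads, e$patch_size, e$image_size,
    if (x$cfg$use_spatial) "2 blocks" else "bypassed",
    x$cfg$temporal$hidden, x$cfg$n_classes))
  invisible(x)
}

# ---- internal forward machinery -------------------------------------------

# Stack every frame's patch rows into one (B*N) x (P^2*3) matrix; cached by
# the training loop since patch extraction is static across epochs.
build_patch_rows <- function(imgs, cfg) {
  n_p <- cfg$n_patches
  B <- length(imgs)
  Xp <- matrix(0, n_p * B, cfg$patch_size^2 * 3L)
  for (i in seq_len(B)) {
    Xp[((i - 1) * n_p + 1):(i * n_p), ] <- patchify(imgs[[i]], cfg$patch_size)
  }
  Xp
}

# Embed B images (list of H x W x 3 arrays) into a ((N+1)*B) x D token
# matrix: patchify, linear projection, CLS prepend, positional embedding.
embed_images_fwd <- function(imgs, p, cfg, Xp = NULL) {
  n_p <- cfg$n_patches
  d <- cfg$embed_dim
  B <- length(imgs)
  if (is.null(Xp)) Xp <- build_patch_rows(imgs, cfg)
  E <- .addrow(Xp %*% p$patch_W, p$patch_b)
  ntok <- n_p + 1L
  cls_rows <- (seq_len(B) - 1L) * ntok + 1L
  T0 <- matrix(0, ntok * B, d)
  T0[cls_rows, ] <- rep(p$cls, each = B)
  T0[-cls_rows, ] <- E
  if (!is.null(p$pos)) T0 <- T0 + p$pos[rep(seq_len(ntok), B), ]
  list(T0 = T0, cache = list(Xp = Xp, B = B, ntok = ntok,
                             cls_rows = cls_rows))
}

embed_images_bwd <- function(dT0, cache, p) {
  B <- cache$B
  ntok <- cache$ntok
  cls_rows <- cache$cls_rows
  g <- list(patch_W = NULL, patch_b = NULL, cls = NULL)
  if (!is.null(p$pos)) {
    dpos <- matrix(0, ntok, ncol(dT0))
    for (i in seq_len(B)) {
      dpos <- dpos + dT0[((i - 1) * ntok + 1):(i * ntok), ]
    }
    g$pos <- dpos
  }
  g$cls <- matrix(colSums(dT0[cls_rows, , drop = FALSE]), 1)
  dE <- dT0[-cls_rows, , drop = FALSE]
  g$patch_W <- crossprod(cache$Xp, dE)
  g$patch_b <- colSums(dE)
  g
}

# Forward pass over one sample's preprocessed frames.
# imgs_by_day: list of T lists of H x W x 3 arrays (equal Z across days).
# Returns logits, probabilities and (optionally) caches and attention.
stvit_fwd <- function(model, imgs_by_day, keep_cache = FALSE,
                      keep_attn = FALSE, xp = NULL) {
  p <- model$params
  cfg <- model$cfg$encoder
  tt <- length(imgs_by_day)
  zz <- length(imgs_by_day[[1]])
  if (tt < 1 || zz < 1) stopf("empty stack")
  if (!model$cfg$use_spatial && zz != 1) {
    stopf("spatial-bypass model requires exactly one image per day")
  }
  imgs <- unlist(imgs_by_day, recursive = FALSE)
  emb <- embed_images_fwd(imgs, p$img, cfg, Xp = xp)
  ntok <- emb$cache$ntok
  B <- emb$cache$B
  ie <- encoder_fwd(emb$T0, p$img$enc, cfg$n_heads, cfg$head_dim,
                    nseg = B, ntok = ntok, eps = cfg$ln_eps,
                    keep_attn = keep_attn)
  H0 <- ie$Y[emb$cache$cls_rows, , drop = FALSE]     # B x D image CLS tokens
  if (model$cfg$use_spatial) {
    sntok <- zz + 1L
    scls_rows <- (seq_len(tt) - 1L) * sntok + 1L
    S0 <- matrix(0, sntok * tt, cfg$embed_dim)
    S0[scls_rows, ] <- rep(p$spa$cls, each = tt)
    S0[-scls_rows, ] <- H0
    se <- encoder_fwd(S0, p$spa$enc, cfg$n_heads, cfg$head_dim,
                      nseg = tt, ntok = sntok, eps = cfg$ln_eps,
                      keep_attn = keep_attn)
    Xd <- se$Y[scls_rows, , drop = FALSE]            # T x D spatial CLS
  } else {
    se <- NULL
    scls_rows <- NULL
    Xd <- H0
  }
  lstm <- bilstm_fwd(Xd, p$tem)
  h1 <- linear_fwd(matrix(lstm$h, 1), p$head$W1, p$head$b1)
  a1 <- gelu_fwd(h1$Y)
  h2 <- linear_fwd(a1$Y, p$head$W2, p$head$b2)
  logits <- drop(h2$Y)
  probs <- drop(softmax_rows(h2$Y))
  names(probs) <- names(logits) <- model$cfg$class_order
  out <- list(logits = logits, probs = probs)
  if (keep_attn) {
    out$attention <- list(image = ie$attn,
                          spatial = if (is.null(se)) NULL else se$attn)
  }
  if (keep_cache) {
    out$cache <- list(emb = emb$cache, ie = ie$cache, se_cache =
                        if (is.null(se)) NULL else se$cache,
                      scls_rows = scls_rows, sntok = if (is.null(se)) NULL
                      else zz + 1L,
                      lstm = lstm$cache, h1 = h1$cache, a1 = a1$cache,
                      h2 = h2$cache, tt = tt, zz = zz, B = B, ntok = ntok,
                      cls_rows = emb$cache$cls_rows)
  }
  out
}

# Backward pass from dlogits (length n_classes); returns the gradient tree
# matching model$params.
stvit_bwd <- function(model, fwd, dlogits) {
  p <- model$params
  cfg <- model$cfg$encoder
  cache <- fwd$cache
  b2 <- linear_bwd(matrix(dlogits, 1), cache$h2, p$head$W2)
  dg <- gelu_bwd(b2$dX, cache$a1)
  b1 <- linear_bwd(dg, cache$h1, p$head$W1)
  lb <- bilstm_bwd(drop(b1$dX), cache$lstm, p$tem)
  g <- list(head = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db),
            tem = lb$g)
  if (model$cfg$use_spatial) {
    dSe <- matrix(0, cache$sntok * cache$tt, cfg$embed_dim)
    dSe[cache$scls_rows, ] <- lb$dX
    sb <- encoder_bwd(dSe, cache$se_cache, p$spa$enc)
    dS0 <- sb$dX
    dH0 <- dS0[-cache$scls_rows, , drop = FALSE]
    g$spa <- list(
      cls = matrix(colSums(dS0[cache$scls_rows, , drop = FALSE]), 1),
      enc = sb$g)
  } else {
    dH0 <- lb$dX
  }
  dYimg <- matrix(0, cache$ntok * cache$B, cfg$embed_dim)
  dYimg[cache$cls_rows, ] <- dH0
  ib <- encoder_bwd(dYimg, cache$ie, p$img$enc)
  ge <- embed_images_bwd(ib$dX, cache$emb, p$img)
  # assemble in exactly the parameter-tree order; leaves untouched by the
  # classification loss (mask embedding, MIM head) get zero gradients
  g$img <- list(patch_W = ge$patch_W, patch_b = ge$patch_b, cls = ge$cls,
                e_mask = p$img$e_mask * 0, enc = ib$g,
                mim = list(W = p$img$mim$W * 0, b = p$img$mim$b * 0))
  if (!is.null(p$img$pos)) g$img$pos <- ge$pos
  g[c("img", if (model$cfg$use_spatial) "spa", "tem", "head")]
}

# ---- public encoder operations --------------------------------------------

#' Encode one image to its CLS representation
#'
#' Runs patch embedding, CLS prepend, the L encoder blocks and the final
#' LayerNorm, returning the CLS token (the image's global representation)
#' and optionally every layer's attention matrices.
#'
#' @param model An [stvit_model()].
#' @param image Preprocessed `image_size x image_size x 3` array (see
#'   [preprocess_image()]).
#' @param return_attention Also return per-block attention arrays.
#' @return List with `cls` (length-D vector), `tokens` ((N+1) x D final
#'   tokens) and, if requested, `attention`.
#' @export
encode_image <- function(model, image, return_attention = FALSE) {
  cfg <- model$cfg$encoder
  d <- dim(image)
  if (!(length(d) == 3 && d[3] == 3 && d[1] == cfg$image_size &&
        d[2] == cfg$image_size)) {
    stopf("expected a preprocessed %d x %d x 3 array", cfg$image_size,
          cfg$image_size)
  }
  emb <- embed_images_fwd(list(image), model$params$img, cfg)
  ie <- encoder_fwd(emb$T0, model$params$img$enc, cfg$n_heads, cfg$head_dim,
                    nseg = 1, ntok = cfg$n_patches + 1L, eps = cfg$ln_eps)
  out <- list(cls = drop(ie$Y[1, ]), tokens = ie$Y)
  if (return_attention) out$attention <- lapply(ie$attn, `[[`, 1)
  out
}

#' Encode a stack of image CLS tokens across focal planes
#'
#' Prepends the spatial CLS token and runs the two spatial encoder blocks
#' plus final LayerNorm. No positional encoding is used, so the output is
#' invariant to the z order.
#'
#' @param model An [stvit_model()].
#' @param z_cls Z x D matrix of image CLS tokens (any Z >= 1).
#' @return Length-D spatial CLS vector.
#' @export
encode_spatial <- function(model, z_cls) {
  if (is.null(dim(z_cls))) z_cls <- matrix(z_cls, 1)
  if (nrow(z_cls) < 1) stopf("empty z stack")
  cfg <- model$cfg$encoder
  S0 <- rbind(model$params$spa$cls, z_cls)
  se <- encoder_fwd(S0, model$params$spa$enc, cfg$n_heads, cfg$head_dim,
                    nseg = 1, ntok = nrow(S0), eps = cfg$ln_eps)
  drop(se$Y[1, ])
}

#' Encode a day sequence of spatial CLS tokens
#'
#' Runs the Bi-LSTM over the (ordered) day sequence and returns the
#' concatenation of the final forward and final backward hidden states.
#' Unlike the spatial encoder, the output depends on the day order.
#'
#' @param model An [stvit_model()].
#' @param day_tokens T x D matrix of per-day spatial CLS tokens (T >= 1).
#' @return Feature vector of length `2 * hidden`.
#' @export
encode_temporal <- function(model, day_tokens) {
  if (is.null(dim(day_tokens))) day_tokens <- matrix(day_tokens, 1)
  if (nrow(day_tokens) < 1) stopf("empty day sequence")
  bilstm_fwd(day_tokens, model$params$tem)$h
}

#' Classify one organoid stack
#'
#' Full forward pass: per-frame image CLS, per-day spatial CLS, Bi-LSTM
#' temporal pooling, MLP head, softmax. Class order is fixed
#' (vNo, vLess, vMost); argmax ties break toward the lower class index.
#'
#' @param model An [stvit_model()].
#' @param stack An `organoid_stack`, raw or already passed through
#'   [preprocess_stack()] (raw stacks are preprocessed on the fly to the
#'   model's input size).
#' @param store_attention Also return image-encoder (and spatial-encoder)
#'   attention matrices for every frame.
#' @return List with `probs` (named 3-vector summing to 1), `logits`,
#'   `prediction` (factor) and optionally `attention`.
#' @export
classify_forward <- function(model, stack, store_attention = FALSE) {
  if (!isTRUE(attr(stack, "preprocessed"))) {
    stack <- preprocess_stack(stack, size = model$cfg$encoder$image_size)
  }
  r <- stvit_fwd(model, stack$images, keep_attn = store_attention)
  pred <- factor(model$cfg$class_order[which.max(r$probs)],
                 levels = model$cfg$class_order)
  out <- list(probs = r$probs, logits = r$logits, prediction = pred)
  if (store_attention) out$attention <- r$attention
  out
}
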
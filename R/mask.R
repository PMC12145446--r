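# Masked-image-modeling corruption (BEiT-style) and its desk-scale
# pixel-regression loss.

#' Sample a patch mask
#'
#' Draws `floor(rho * N)` distinct patch indices uniformly at random.
#'
#' @param n_patches Number of patches N.
#' @param rho Mask ratio in `[0, 1)`.
#' @param seed Optional seed.
#' @return Integer vector of masked indices (possibly empty).
#' @export
sample_mask <- function(n_patches, rho, seed = NULL) {
  if (rho < 0 || rho >= 1) stopf("mask ratio must be in [0, 1)")
  m <- floor(rho * n_patches)
  draw <- function() sort(sample.int(n_patches, m))
  if (m == 0) return(integer(0))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Corrupt embedded patches with the shared mask embedding
#'
#' Replaces every row of the embedded patch sequence whose index lies in the
#' mask set by the learnable mask embedding `e_[M]`, leaving all other rows
#' untouched: row i becomes `e_mask` if `i` is masked, else stays `x_i`.
#'
#' @param embedded N x D matrix of patch embeddings (no CLS row).
#' @param mask Integer vector of masked row indices (may be empty).
#' @param e_mask Length-D (or 1 x D) replacement embedding.
#' @return Corrupted N x D matrix.
#' @export
apply_mask <- function(embedded, mask, e_mask) {
  if (length(mask) == 0) return(embedded)
  mask <- as.integer(mask)
  if (any(mask < 1 | mask > nrow(embedded))) {
    stopf("mask indices must lie in 1..%d", nrow(embedded))
  }
  embedded[mask, ] <- rep(as.numeric(e_mask), each = length(mask))
  embedded
}

#' Masked-image-modeling corruption loss
#'
#' Desk-scale pretraining objective: embeds the image's patches, replaces a
#' random `floor(rho * N)` subset by the mask embedding, encodes the
#' corrupted sequence (with CLS token), and regresses each masked position's
#' output token onto that patch's pixel vector through a single fully
#' connected layer. The loss is the mean squared error over masked
#' positions only; unmasked patches do not contribute.
#'
#' @param model An [stvit_model()].
#' @param image Preprocessed `image_size x image_size x 3` array.
#' @param seed Optional seed for the mask draw.
#' @param mask Optional explicit mask (overrides sampling).
#' @return List with `loss` (scalar), `mask`, and `pred`/`target` matrices
#'   (|M| x P^2*3) for inspection.
#' @export
mim_corrupt_and_loss <- function(model, image, seed = NULL, mask = NULL) {
  cfg <- model$cfg$encoder
  if (is.null(mask)) mask <- sample_mask(cfg$n_patches, cfg$mask_ratio, seed)
  if (length(mask) == 0) {
    stopf("mask ratio %g leaves no masked position to supervise",
          cfg$mask_ratio)
  }
  Xp <- patchify(image, cfg$patch_size)
  r <- mim_fwd_bwd(model, Xp, list(mask), compute_grads = FALSE)
  list(loss = r$loss, mask = mask, pred = r$pred, target = r$target)
}

# Batched masked-patch regression with gradients for pretraining.
# Xp_all: (B*N) x P^2C patch rows of B frames; masks: list of B index sets.
mim_fwd_bwd <- function(model, Xp_all, masks, compute_grads = TRUE) {
  cfg <- model$cfg$encoder
  p <- model$params$img
  n_p <- cfg$n_patches
  B <- length(masks)
  d <- cfg$embed_dim
  E <- .addrow(Xp_all %*% p$patch_W, p$patch_b)
  mask_rows <- unlist(lapply(seq_len(B), function(i) {
    (i - 1L) * n_p + masks[[i]]
  }))
  E[mask_rows, ] <- rep(as.numeric(p$e_mask), each = length(mask_rows))
  ntok <- n_p + 1L
  cls_rows <- (seq_len(B) - 1L) * ntok + 1L
  T0 <- matrix(0, ntok * B, d)
  T0[cls_rows, ] <- rep(p$cls, each = B)
  T0[-cls_rows, ] <- E
  if (!is.null(p$pos)) T0 <- T0 + p$pos[rep(seq_len(ntok), B), ]
  enc <- encoder_fwd(T0, p$enc, cfg$n_heads, cfg$head_dim, nseg = B,
                     ntok = ntok, eps = cfg$ln_eps,
                     keep_attn = FALSE)
  tok_rows <- unlist(lapply(seq_len(B), function(i) {
    (i - 1L) * ntok + 1L + masks[[i]]
  }))
  out <- enc$Y[tok_rows, , drop = FALSE]
  pred <- .addrow(out %*% p$mim$W, p$mim$b)
  target <- Xp_all[mask_rows, , drop = FALSE]
  diff <- pred - target
  loss <- mean(diff * diff)
  if (!compute_grads) {
    return(list(loss = loss, pred = pred, target = target))
  }
  dpred <- (2 / length(diff)) * diff
  gmim <- list(W = crossprod(out, dpred), b = colSums(dpred))
  dY <- matrix(0, nrow(T0), d)
  dY[tok_rows, ] <- tcrossprod(dpred, p$mim$W)
  eb <- encoder_bwd(dY, enc$cache, p$enc)
  dT0 <- eb$dX
  g <- list(patch_W = NULL, patch_b = NULL,
            cls = matrix(colSums(dT0[cls_rows, , drop = FALSE]), 1),
            e_mask = NULL, enc = eb$g, mim = gmim)
  dE <- dT0[-cls_rows, , drop = FALSE]
  g$e_mask <- matrix(colSums(dE[mask_rows, , drop = FALSE]), 1)
  dE[mask_rows, ] <- 0   # masked rows carry no patch-embedding gradient
  g$patch_W <- crossprod(Xp_all, dE)
  g$patch_b <- colSums(dE)
  if (!is.null(p$pos)) {
    dpos <- matrix(0, ntok, d)
    for (i in seq_len(B)) {
      dpos <- dpos + dT0[((i - 1) * ntok + 1):(i * ntok), , drop = FALSE]
    }
    g$pos <- dpos
  }
  list(loss = loss, g = g)
}

#' Masked-image-modeling pretraining of the image encoder
#'
#' Desk-scale warm start mirroring the reference pipeline's pretrained image
#' encoder: for a set of frames, `floor(rho * N)` patches are replaced by
#' the mask embedding and the encoder plus a single fully connected head
#' regress the masked patches' pixel vectors (masked positions only).
#' Only the image-encoder parameter group is updated.
#'
#' @param model An [stvit_model()].
#' @param stacks List of (preprocessed) `organoid_stack`s supplying frames.
#' @param epochs Passes over the frame set (default 5).
#' @param batch_frames Frames per optimizer step (default 32).
#' @param lr AdamW learning rate (default 1e-3).
#' @param seed Seed for mask draws and frame order.
#' @param weight_decay,betas,adam_eps AdamW settings.
#' @return List with the updated `model` and the per-epoch mean `loss`.
#' @export
mim_pretrain <- function(model, stacks, epochs = 5, batch_frames = 32,
                         lr = 1e-3, seed = 1L, weight_decay = 0.01,
                         betas = c(0.9, 0.98), adam_eps = 1e-8) {
  cfg <- model$cfg$encoder
  stacks <- .prep_all(stacks, cfg$image_size)
  frames <- unlist(lapply(stacks, function(s) {
    unlist(s$images, recursive = FALSE)
  }), recursive = FALSE)
  n <- length(frames)
  xps <- lapply(frames, patchify, P = cfg$patch_size)
  m_cnt <- floor(cfg$mask_ratio * cfg$n_patches)
  if (m_cnt < 1) stopf("mask ratio %g masks no patches", cfg$mask_ratio)
  state <- adamw_init(model$params$img)
  opt_cfg <- list(lr = lr, betas = betas, weight_decay = weight_decay,
                  adam_eps = adam_eps)
  losses <- numeric(epochs)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_frames)) {
        idx <- ord[start:min(start + batch_frames - 1L, n)]
        masks <- lapply(idx, function(i) {
          sort(sample.int(cfg$n_patches, m_cnt))
        })
        Xp_all <- do.call(rbind, xps[idx])
        r <- mim_fwd_bwd(model, Xp_all, masks)
        ep_loss <- ep_loss + r$loss * length(idx)
        upd <- adamw_step(model$params$img, r$g, state, opt_cfg)
        model$params$img <- upd$params
        state <- upd$state
      }
      losses[ep] <- ep_loss / n
    }
  })
  list(model = model, loss = losses)
}
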
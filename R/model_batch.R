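# Batched forward/backward over a minibatch of samples. All frames of all
# samples run through the image encoder as one segment set (equal token
# count); the spatial encoder runs once per sample (batching that sample's
# days; Z may differ between samples); the Bi-LSTM and head are batched
# across samples (equal T within a batch).

# ---- batched LSTM ----------------------------------------------------------

# xs: list of T matrices (B x D). Returns final hidden H (B x h) + cache.
lstm_dir_fwd_b <- function(xs, p) {
  h_dim <- nrow(p$U)
  bsz <- nrow(xs[[1]])
  H <- matrix(0, bsz, h_dim)
  C <- matrix(0, bsz, h_dim)
  steps <- vector("list", length(xs))
  i1 <- 1:h_dim; i2 <- h_dim + i1; i3 <- 2 * h_dim + i1; i4 <- 3 * h_dim + i1
  for (t in seq_along(xs)) {
    z <- .addrow(xs[[t]] %*% p$W + H %*% p$U, p$b)
    i <- sigmoid(z[, i1, drop = FALSE])
    f <- sigmoid(z[, i2, drop = FALSE])
    g <- tanh(z[, i3, drop = FALSE])
    o <- sigmoid(z[, i4, drop = FALSE])
    C_prev <- C
    H_prev <- H
    C <- f * C_prev + i * g
    tc <- tanh(C)
    H <- o * tc
    steps[[t]] <- list(i = i, f = f, g = g, o = o, tc = tc,
                       C_prev = C_prev, H_prev = H_prev)
  }
  list(H = H, cache = list(steps = steps, xs = xs))
}

lstm_dir_bwd_b <- function(dH_final, cache, p) {
  xs <- cache$xs
  h_dim <- ncol(dH_final)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dxs <- vector("list", length(xs))
  dH <- dH_final
  dC <- dH * 0
  for (t in rev(seq_along(xs))) {
    s <- cache$steps[[t]]
    do <- dH * s$tc
    dC <- dC + dH * s$o * (1 - s$tc^2)
    di <- dC * s$g
    dg <- dC * s$i
    df <- dC * s$C_prev
    dC <- dC * s$f
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    dW <- dW + crossprod(xs[[t]], dz)
    dU <- dU + crossprod(s$H_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- tcrossprod(dz, p$W)
    dH <- tcrossprod(dz, p$U)
  }
  list(dxs = dxs, g = list(W = dW, U = dU, b = db))
}

bilstm_fwd_b <- function(xs, p) {
  fw <- lstm_dir_fwd_b(xs, p$f)
  bw <- lstm_dir_fwd_b(rev(xs), p$b)
  list(H = cbind(fw$H, bw$H), cache = list(fw = fw$cache, bw = bw$cache))
}

bilstm_bwd_b <- function(dH, cache, p) {
  h_dim <- ncol(dH) / 2
  fw <- lstm_dir_bwd_b(dH[, 1:h_dim, drop = FALSE], cache$fw, p$f)
  bw <- lstm_dir_bwd_b(dH[, h_dim + 1:h_dim, drop = FALSE], cache$bw, p$b)
  dxs <- Map(`+`, fw$dxs, rev(bw$dxs))
  list(dxs = dxs, g = list(f = fw$g, b = bw$g))
}

# ---- batched classifier ----------------------------------------------------

# samples: list of imgs_by_day (each a list of T lists of Z_i frames).
# xps: optional list of cached patch-row matrices (one per sample).
# All samples must share T (the protocol fixes the day range).
stvit_batch_fwd <- function(model, samples, xps = NULL, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$cfg$encoder
  bsz <- length(samples)
  tts <- vapply(samples, length, integer(1))
  if (length(unique(tts)) != 1) stopf("batch mixes day counts")
  tt <- tts[1]
  zzs <- vapply(samples, function(s) length(s[[1]]), integer(1))
  if (!model$cfg$use_spatial && any(zzs != 1)) {
    stopf("spatial-bypass model requires exactly one image per day")
  }
  n_frames <- tt * zzs                 # per sample
  if (is.null(xps)) {
    xps <- lapply(samples, function(s) {
      build_patch_rows(unlist(s, recursive = FALSE), cfg)
    })
  }
  Xp <- do.call(rbind, xps)
  B <- sum(n_frames)
  emb <- embed_images_fwd(vector("list", B), p$img, cfg, Xp = Xp)
  ntok <- emb$cache$ntok
  ie <- encoder_fwd(emb$T0, p$img$enc, cfg$n_heads, cfg$head_dim,
                    nseg = B, ntok = ntok, eps = cfg$ln_eps,
                    keep_attn = FALSE)
  H0 <- ie$Y[emb$cache$cls_rows, , drop = FALSE]  # B x D, sample-major rows
  frame_off <- c(0L, cumsum(n_frames))
  se_groups <- NULL
  Xd <- vector("list", bsz)            # per sample T x D day tokens
  if (model$cfg$use_spatial) {
    # samples sharing Z run through the spatial encoder as one segment set
    zgroups <- split(seq_len(bsz), zzs)
    se_groups <- vector("list", length(zgroups))
    for (gi in seq_along(zgroups)) {
      members <- zgroups[[gi]]
      zz <- zzs[members[1]]
      sntok <- zz + 1L
      nsegg <- tt * length(members)
      scls <- (seq_len(nsegg) - 1L) * sntok + 1L
      S0 <- matrix(0, sntok * nsegg, cfg$embed_dim)
      S0[scls, ] <- rep(p$spa$cls, each = nsegg)
      S0[-scls, ] <- do.call(rbind, lapply(members, function(i) {
        H0[(frame_off[i] + 1L):frame_off[i + 1L], , drop = FALSE]
      }))
      se <- encoder_fwd(S0, p$spa$enc, cfg$n_heads, cfg$head_dim,
                        nseg = nsegg, ntok = sntok, eps = cfg$ln_eps,
                        keep_attn = FALSE)
      cls_tokens <- se$Y[scls, , drop = FALSE]   # (|members|*tt) x D
      for (j in seq_along(members)) {
        Xd[[members[j]]] <- cls_tokens[((j - 1) * tt + 1):(j * tt), ,
                                       drop = FALSE]
      }
      se_groups[[gi]] <- list(cache = se$cache, members = members,
                              scls = scls, sntok = sntok, nsegg = nsegg)
    }
  } else {
    for (i in seq_len(bsz)) {
      rows <- (frame_off[i] + 1L):frame_off[i + 1L]
      Xd[[i]] <- H0[rows, , drop = FALSE]
    }
  }
  # day-major matrices for the batched LSTM: xs[[t]] is B x D
  xs <- lapply(seq_len(tt), function(t) {
    do.call(rbind, lapply(Xd, function(m) m[t, , drop = FALSE]))
  })
  lstm <- bilstm_fwd_b(xs, p$tem)
  h1 <- linear_fwd(lstm$H, p$head$W1, p$head$b1)
  a1 <- gelu_fwd(h1$Y)
  h2 <- linear_fwd(a1$Y, p$head$W2, p$head$b2)
  probs <- softmax_rows(h2$Y)
  out <- list(logits = h2$Y, probs = probs)
  if (keep_cache) {
    out$cache <- list(emb = emb$cache, ie = ie$cache, se = se_groups,
                      lstm = lstm$cache, h1 = h1$cache, a1 = a1$cache,
                      h2 = h2$cache, bsz = bsz, tt = tt, zzs = zzs,
                      frame_off = frame_off, B = B, ntok = ntok,
                      cls_rows = emb$cache$cls_rows)
  }
  out
}

# dlogits: bsz x n_classes. Returns the gradient tree (summed over the
# batch; divide by bsz for the mean).
stvit_batch_bwd <- function(model, fwd, dlogits) {
  p <- model$params
  cfg <- model$cfg$encoder
  cache <- fwd$cache
  bsz <- cache$bsz
  tt <- cache$tt
  b2 <- linear_bwd(dlogits, cache$h2, p$head$W2)
  dg <- gelu_bwd(b2$dX, cache$a1)
  b1 <- linear_bwd(dg, cache$h1, p$head$W1)
  lb <- bilstm_bwd_b(b1$dX, cache$lstm, p$tem)
  g <- list(head = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db),
            tem = lb$g)
  # reassemble per-sample day-token gradients (T x D each)
  dXd <- lapply(seq_len(bsz), function(i) {
    do.call(rbind, lapply(seq_len(tt), function(t) {
      lb$dxs[[t]][i, , drop = FALSE]
    }))
  })
  dH0 <- matrix(0, cache$B, cfg$embed_dim)
  if (model$cfg$use_spatial) {
    gspa <- NULL
    for (sc in cache$se) {
      dSe <- matrix(0, sc$sntok * sc$nsegg, cfg$embed_dim)
      dSe[sc$scls, ] <- do.call(rbind, dXd[sc$members])
      sb <- encoder_bwd(dSe, sc$cache, p$spa$enc)
      gi <- list(cls = matrix(colSums(sb$dX[sc$scls, , drop = FALSE]), 1),
                 enc = sb$g)
      gspa <- if (is.null(gspa)) gi else tree_add(gspa, gi)
      dpatch <- sb$dX[-sc$scls, , drop = FALSE]
      for (j in seq_along(sc$members)) {
        i <- sc$members[j]
        rows <- (cache$frame_off[i] + 1L):cache$frame_off[i + 1L]
        nfr <- length(rows)
        dH0[rows, ] <- dpatch[((j - 1) * nfr + 1):(j * nfr), , drop = FALSE]
      }
    }
    g$spa <- gspa
  } else {
    for (i in seq_len(bsz)) {
      rows <- (cache$frame_off[i] + 1L):cache$frame_off[i + 1L]
      dH0[rows, ] <- dXd[[i]]
    }
  }
  dYimg <- matrix(0, cache$ntok * cache$B, cfg$embed_dim)
  dYimg[cache$cls_rows, ] <- dH0
  ib <- encoder_bwd(dYimg, cache$ie, p$img$enc)
  ge <- embed_images_bwd(ib$dX, cache$emb, p$img)
  g$img <- list(patch_W = ge$patch_W, patch_b = ge$patch_b, cls = ge$cls,
                e_mask = p$img$e_mask * 0, enc = ib$g,
                mim = list(W = p$img$mim$W * 0, b = p$img$mim$b * 0))
  if (!is.null(p$img$pos)) g$img$pos <- ge$pos
  g[c("img", if (model$cfg$use_spatial) "spa", "tem", "head")]
}
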
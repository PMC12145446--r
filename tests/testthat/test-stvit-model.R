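test_that("patchify produces the documented grid and is lossless", {
  img224 <- array(runif(224 * 224 * 3), c(224, 224, 3))
  p <- patchify(img224, P = 16)
  expect_equal(nrow(p), 196)              # 14 x 14 grid
  expect_equal(ncol(p), 16 * 16 * 3)
  expect_equal(attr(p, "grid"), c(14, 14))
  # single-patch identity
  small <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p1 <- patchify(small, P = 16)
  expect_equal(nrow(p1), 1)
  expect_setequal(as.vector(p1), as.vector(small))
  expect_identical(unpatchify(p1, P = 16), small)
  # 32x32 reassembly is bit-exact
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p4 <- patchify(img, P = 16)
  expect_equal(nrow(p4), 4)
  expect_identical(unpatchify(p4, P = 16), img)
  # grayscale matrices round-trip too
  g <- matrix(runif(32 * 32), 32, 32)
  expect_identical(unpatchify(patchify(g, P = 16), P = 16), g)
  expect_error(patchify(img, P = 15), "divide")
})

test_that("mask corruption replaces exactly the masked rows", {
  E <- matrix(rnorm(40), 10, 4)
  e_m <- rnorm(4)
  expect_identical(apply_mask(E, integer(0), e_m), E)
  allm <- apply_mask(E, 1:10, e_m)
  expect_true(all(apply(allm, 1, function(r) all(r == e_m))))
  m <- sample_mask(10, 0.4, seed = 5)
  expect_length(m, 4)                      # floor(0.4 * 10)
  out <- apply_mask(E, m, e_m)
  changed <- which(rowSums(out != E) > 0)
  expect_setequal(changed, m)
  expect_identical(out[-m, ], E[-m, ])
  expect_error(apply_mask(E, 11L, e_m), "1..10")
  expect_error(sample_mask(10, 1.2), "\\[0, 1\\)")
})

test_that("self-attention matches hand-computed values", {
  # single token: softmax over one logit is 1, output = v
  U <- matrix(rnorm(4 * 3), 4, 3)
  x1 <- matrix(rnorm(4), 1, 4)
  r1 <- self_attention(x1, U)
  expect_equal(as.vector(r1$output), as.vector(x1 %*% U[, 3]))
  expect_equal(as.vector(r1$attention), 1)
  # identical tokens: uniform attention, identical outputs
  xs <- matrix(rep(rnorm(4), each = 3), 3, 4)
  rs <- self_attention(xs, U)
  expect_equal(as.vector(rs$attention), rep(1 / 3, 9), tolerance = 1e-12)
  expect_equal(rs$output[1, ], rs$output[2, ])
  # 2 tokens, dh = 1: brute-force arithmetic
  x <- matrix(c(1, -1, 0.5, 2), 2, 2)
  Uq <- matrix(c(0.3, -0.2, 0.1, 0.4, -0.5, 0.2), 2, 3)
  q <- x %*% Uq[, 1]; k <- x %*% Uq[, 2]; v <- x %*% Uq[, 3]
  S <- (q %*% t(k))
  W <- exp(S); W <- W / rowSums(W)
  r <- self_attention(x, Uq)
  expect_equal(r$attention, W, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.vector(r$output), as.vector(W %*% v), tolerance = 1e-12)
})

test_that("multi-head attention concatenates heads through the projection", {
  withr::with_seed(8, {
    x <- matrix(rnorm(5 * 6), 5, 6)
    heads <- lapply(1:2, function(h) matrix(rnorm(6 * 9), 6, 9))
    U_msa <- matrix(rnorm(6 * 6), 6, 6)
    r <- multi_head_attention(x, heads, U_msa)
    expect_equal(dim(r$output), c(5, 6))
    expect_equal(dim(r$attention), c(5, 5, 2))
    # k = 1 with identity projection reduces to self_attention
    sa <- self_attention(x, heads[[1]][, 1:9])
    mh <- multi_head_attention(x, heads[1], diag(3))
    expect_equal(mh$output, sa$output, tolerance = 1e-12)
    # per-head attention rows are stochastic
    expect_equal(apply(r$attention, c(1, 3), sum),
                 matrix(1, 5, 2), tolerance = 1e-9)
    # permuting tokens permutes outputs identically (no positions here)
    perm <- c(3, 1, 5, 2, 4)
    rp <- multi_head_attention(x[perm, ], heads, U_msa)
    expect_equal(rp$output, r$output[perm, ], tolerance = 1e-9)
    # dimension bookkeeping: k=4 heads of dh=16 on D=64
    x64 <- matrix(rnorm(3 * 64), 3, 64)
    h4 <- lapply(1:4, function(h) matrix(rnorm(64 * 48, sd = 0.1), 64, 48))
    r4 <- multi_head_attention(x64, h4, matrix(rnorm(64 * 64, sd = 0.1),
                                               64, 64))
    expect_equal(dim(r4$output), c(3, 64))
    expect_error(multi_head_attention(x, heads, matrix(0, 5, 6)), "k\\*dh")
  })
})

test_that("a transformer block preserves shape and has a residual identity", {
  withr::with_seed(3, {
    params <- init_vit_block(8, n_heads = 2, mlp_ratio = 2)
    x <- matrix(rnorm(5 * 8), 5, 8)
    r <- vit_block(x, params, n_heads = 2)
    expect_equal(dim(r$output), dim(x))
    # zeroed output projections leave only the residual path
    params0 <- params
    params0$attn$Umsa[] <- 0
    params0$mlp$W2[] <- 0
    r0 <- vit_block(x, params0, n_heads = 2)
    expect_equal(r0$output, x, tolerance = 1e-12)
  })
})

test_that("stacked blocks plus final norm equal the composed encoder", {
  m <- tiny_model()
  ns <- asNamespace("organoidvit")
  enc <- m$params$img$enc
  cfg <- m$cfg$encoder
  x <- matrix(rnorm(5 * 8), 5, 8)
  full <- ns$encoder_fwd(x, enc, cfg$n_heads, cfg$head_dim, nseg = 1,
                         ntok = 5, eps = cfg$ln_eps)
  step <- x
  for (b in enc$blocks) {
    step <- vit_block(step, b, n_heads = cfg$n_heads,
                      ln_eps = cfg$ln_eps)$output
  }
  lf <- ns$ln_fwd(step, enc$ln_f$g, enc$ln_f$b, cfg$ln_eps)$Y
  expect_equal(full$Y, lf, tolerance = 1e-12)
})

test_that("encode_image yields a 197-token sequence at full scale and a
           deterministic CLS vector", {
  enc <- encoder_config(image_size = 224, patch_size = 16, embed_dim = 8,
                        depth = 1, n_heads = 2, mlp_ratio = 1)
  m <- stvit_model(enc, temporal = temporal_config(hidden = 4), seed = 2)
  img <- rand_image(224, seed = 9)
  r <- encode_image(m, img, return_attention = TRUE)
  expect_equal(nrow(r$tokens), 197)
  expect_length(r$cls, 8)
  expect_identical(r$cls, encode_image(m, img)$cls)
  expect_equal(dim(r$attention[[1]])[1:2], c(197, 197))
  expect_error(encode_image(m, rand_image(32)), "224")
})

test_that("the spatial encoder is z-permutation invariant; the temporal
           encoder is day-order sensitive", {
  m <- tiny_model()
  expect_length(m$params$spa$enc$blocks, 2)    # depth fixed at two blocks
  expect_error(spatial_config(depth = 3), "fixed at 2")
  z_cls <- matrix(rnorm(5 * 8), 5, 8)
  out <- encode_spatial(m, z_cls)
  expect_length(out, 8)
  perm <- c(4, 1, 5, 3, 2)
  expect_equal(encode_spatial(m, z_cls[perm, ]), out, tolerance = 1e-9)
  expect_length(encode_spatial(m, z_cls[1, , drop = FALSE]), 8)  # Z = 1
  expect_error(encode_spatial(m, z_cls[0, , drop = FALSE]), "empty")
  days <- matrix(rnorm(4 * 8), 4, 8)
  f <- encode_temporal(m, days)
  expect_length(f, 12)                     # 2 x hidden
  expect_gt(max(abs(encode_temporal(m, days[4:1, ]) - f)), 1e-6)
  # all-zero weights and biases give a zero feature vector
  m0 <- m
  m0$params$tem <- tree_zero_lstm <- rapply(m$params$tem, function(x) x * 0,
                                            how = "replace")
  expect_equal(encode_temporal(m0, days), rep(0, 12))
  expect_error(encode_temporal(m, days[0, , drop = FALSE]), "empty")
})

test_that("zeroed residual projections reduce encode_image to LayerNorm of
           the embedded input", {
  m <- tiny_model(seed = 9)
  for (b in seq_along(m$params$img$enc$blocks)) {
    m$params$img$enc$blocks[[b]]$attn$Umsa[] <- 0
    m$params$img$enc$blocks[[b]]$mlp$W2[] <- 0
  }
  img <- rand_image(32, seed = 14)
  ns <- asNamespace("organoidvit")
  enc <- encode_image(m, img)
  p <- m$params$img
  cfg <- m$cfg$encoder
  E <- ns$.addrow(patchify(img, 16) %*% p$patch_W, p$patch_b)
  T0 <- rbind(p$cls, E) + p$pos
  closed <- ns$ln_fwd(T0, p$enc$ln_f$g, p$enc$ln_f$b, cfg$ln_eps)$Y
  expect_equal(enc$tokens, closed, tolerance = 1e-12)
})

test_that("classification produces calibrated 3-class output", {
  m <- tiny_model()
  imgs <- rand_imgs_by_day()
  ns <- asNamespace("organoidvit")
  r <- ns$stvit_fwd(m, imgs)
  expect_length(r$probs, 3)
  expect_named(r$probs, dili_levels())
  expect_equal(sum(r$probs), 1, tolerance = 1e-12)
  expect_true(all(r$probs > 0 & r$probs < 1))
  # duplicating every z slice leaves the output essentially unchanged (the
  # CLS token's softmax mass shifts infinitesimally when the z tokens are
  # doubled) and the prediction identical
  dup <- lapply(imgs, function(day) c(day, day))
  expect_equal(ns$stvit_fwd(m, dup)$probs, r$probs, tolerance = 1e-5)
  expect_identical(which.max(ns$stvit_fwd(m, dup)$probs),
                   which.max(r$probs))
})

test_that("attention rows are stochastic at every layer of both encoders", {
  m <- tiny_model()
  img <- rand_image(32, seed = 4)
  r <- encode_image(m, img, return_attention = TRUE)
  for (A in r$attention) {
    expect_equal(apply(A, c(1, 3), sum),
                 matrix(1, dim(A)[1], dim(A)[3]), tolerance = 1e-6)
  }
})

test_that("MIM corruption masks floor(rho N) patches and supervises only
           masked positions", {
  enc <- encoder_config(image_size = 224, patch_size = 16, embed_dim = 8,
                        depth = 1, n_heads = 2, mlp_ratio = 1)
  m <- stvit_model(enc, temporal = temporal_config(hidden = 4), seed = 2)
  expect_length(sample_mask(196, 0.40, seed = 1), 78)  # floor(0.4 * 196)
  m_small <- tiny_model()
  img <- rand_image(32, seed = 6)
  r <- mim_corrupt_and_loss(m_small, img, seed = 3)
  expect_length(r$mask, floor(0.4 * 4))
  expect_gt(r$loss, 0)
  expect_equal(r$loss, mean((r$pred - r$target)^2))
  # supervision touches only the masked positions: the regression targets
  # are exactly the masked patches' pixel rows, nothing else
  Xp <- patchify(img, 16)
  expect_equal(nrow(r$target), length(r$mask))
  expect_identical(unname(r$target), unname(Xp[r$mask, , drop = FALSE]))
  # a perfect-oracle check: zero distance when prediction equals target
  expect_equal(mean((r$target - r$target)^2), 0)
  cfg0 <- tiny_enc()
  m0 <- stvit_model(cfg0, temporal = temporal_config(hidden = 6), seed = 1)
  m0$cfg$encoder$mask_ratio <- 0
  expect_error(mim_corrupt_and_loss(m0, img), "no masked position")
})

test_that("every learnable component receives gradient from the loss", {
  m <- tiny_model()
  ns <- asNamespace("organoidvit")
  imgs <- rand_imgs_by_day(seed = 12)
  fw <- ns$stvit_fwd(m, imgs, keep_cache = TRUE)
  dl <- fw$probs
  dl[1] <- dl[1] - 1
  g <- ns$stvit_bwd(m, fw, dl)
  flat <- ns$tree_flatten(g)
  skip_leaves <- c("img$e_mask", "img$mim$W", "img$mim$b")  # not in this loss
  for (nm in names(flat)) {
    if (nm %in% skip_leaves) next
    expect_gt(max(abs(flat[[nm]])), 0, label = paste("gradient of", nm))
  }
})

test_that("analytic gradients match numerical differentiation", {
  m <- tiny_model(seed = 21)
  ns <- asNamespace("organoidvit")
  imgs <- rand_imgs_by_day(seed = 13)
  target <- 1L
  fw <- ns$stvit_fwd(m, imgs, keep_cache = TRUE)
  dl <- fw$probs
  dl[target + 1] <- dl[target + 1] - 1
  g <- ns$tree_flatten(ns$stvit_bwd(m, fw, dl))
  flat_p <- ns$tree_flatten(m$params)
  loss_of <- function(model) {
    ns$ce_loss(ns$stvit_fwd(model, imgs)$probs, target)
  }
  perturb <- function(tree, path, i, d) {
    if (length(path) == 1) {
      tree[[path]][i] <- tree[[path]][i] + d
      tree
    } else {
      tree[[path[1]]] <- perturb(tree[[path[1]]], path[-1], i, d)
      tree
    }
  }
  eps <- 1e-5
  withr::with_seed(99, {
    leaves <- sample(names(flat_p), 12)
    leaves <- union(leaves, c("img$patch_W", "tem$f$W", "head$W2",
                              "spa$cls"))
    for (nm in setdiff(leaves, c("img$e_mask", "img$mim$W", "img$mim$b"))) {
      i <- sample(length(flat_p[[nm]]), 1)
      pa <- strsplit(nm, "\\$")[[1]]
      m2 <- m
      m2$params <- perturb(m$params, pa, i, eps)
      lp <- loss_of(m2)
      m2$params <- perturb(m$params, pa, i, -eps)
      lm <- loss_of(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 5e-3,
                   label = paste("analytic gradient of", nm))
    }
  })
})
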
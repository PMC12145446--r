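# Shared fixtures. Everything is generated in code; heavier objects are
# built once per test run and cached here.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# Small simulator configuration used by most synthetic-data tests: paper
# phenotype dynamics at reduced frame size / plane count.
tiny_sim_cfg <- function(noise_sd = 0.02) {
  sim_config(image_size = 48, z_planes_range = c(3, 3),
             organoids_per_field = c(1, 2), noise_sd = noise_sd)
}

# Encoder sized for fast structural tests.
tiny_enc <- function(image_size = 32, patch_size = 16) {
  encoder_config(image_size = image_size, patch_size = patch_size,
                 embed_dim = 8, depth = 2, n_heads = 2, mlp_ratio = 2)
}

tiny_model <- function(seed = 11, ...) {
  stvit_model(tiny_enc(), temporal = temporal_config(hidden = 6),
              seed = seed, ...)
}

# Random preprocessed-image-like array.
rand_image <- function(size = 32, seed = 1) {
  withr::with_seed(seed, array(rnorm(size * size * 3, sd = 0.5),
                               c(size, size, 3)))
}

# A T=2, Z=2 stack of random frames in the model input format.
rand_imgs_by_day <- function(size = 32, tt = 2, zz = 2, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(tt), function(d) {
    lapply(seq_len(zz), function(z) {
      array(rnorm(size * size * 3, sd = 0.5), c(size, size, 3))
    })
  }))
}

# Independent flood-fill component counter (breadth-first, 4-connectivity),
# used as the oracle against the package's labelling-based counter.
flood_fill_components <- function(mask, min_px = 5) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || seen[i, j]) next
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      size <- 0L
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        size <- size + 1L
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
      if (size >= min_px) count <- count + 1L
    }
  }
  count
}

# Mean gradient-magnitude sharpness oracle (central differences).
gradient_energy <- function(img) {
  gx <- img[, -1] - img[, -ncol(img)]
  gy <- img[-1, ] - img[-nrow(img), ]
  (mean(abs(gx)) + mean(abs(gy))) / 2
}

# Brute-force one-vs-rest counts for a confusion matrix.
ovr_oracle <- function(cm) {
  n <- sum(cm)
  t(vapply(seq_len(nrow(cm)), function(c) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
      cnt <- cm[i, j]
      if (i == c && j == c) tp <- tp + cnt
      else if (i == c) fn <- fn + cnt
      else if (j == c) fp <- fp + cnt
      else tn <- tn + cnt
    }
    c(tp = tp, fp = fp, fn = fn, tn = tn)
  }, numeric(4)))
}

# Pairwise-concordance AUC oracle (Mann-Whitney; ties count 1/2).
concordance_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
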
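# Supervised training: cross-entropy + AdamW, K-fold cross-validation.

#' Training configuration
#'
#' Defaults follow the reference protocol: cross-entropy loss, AdamW with
#' lr 2e-4, batch size 6 full stacks, 100 epochs, 5-fold cross-validation
#' (each training set is 80% of the data). No learning-rate schedule, early
#' stopping or augmentation.
#'
#' @param lr Learning rate (> 0 unless deliberately 0 for a null update).
#' @param batch_size Samples (full T x Z stacks) per optimizer step.
#' @param epochs Training epochs.
#' @param k Cross-validation folds.
#' @param betas AdamW moment coefficients.
#' @param weight_decay Decoupled weight decay, applied to weight matrices
#'   only (not LayerNorm gains, biases, CLS/positional/mask embeddings).
#' @param adam_eps AdamW denominator epsilon.
#' @param clip_norm Global gradient-norm clip (`Inf` disables); transformer
#'   training at small batch sizes is prone to loss spikes without it.
#' @param lr_schedule `"constant"` (the reference protocol) or `"cosine"`
#'   (per-epoch cosine decay from `lr` to `lr_min`, which stabilises
#'   small-batch training at desk scale).
#' @param lr_min Final learning rate of the cosine schedule.
#' @param mim_epochs Masked-image-modeling warm-start epochs run on the
#'   training frames before classification training (0 disables; see
#'   [mim_pretrain()]).
#' @param mim_lr Learning rate of the warm start.
#' @param max_restarts Retrain attempts (fresh init) allowed when the final
#'   mean training loss stays above `restart_loss` — a training-set-only
#'   convergence check; the attempt with the lowest final training loss is
#'   kept. 0 (the default) disables restarts.
#' @param restart_loss Final mean training cross-entropy above which a fold
#'   counts as non-converged (default 0.35).
#' @param seed Master seed covering init, data order and fold splits.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 2e-4, batch_size = 6, epochs = 100, k = 5,
                         betas = c(0.9, 0.999), weight_decay = 0.01,
                         adam_eps = 1e-8, clip_norm = 1,
                         lr_schedule = c("constant", "cosine"),
                         lr_min = lr / 20, mim_epochs = 0L, mim_lr = 1e-3,
                         max_restarts = 0L, restart_loss = 0.35,
                         seed = 1L) {
  if (lr < 0) stopf("lr must be >= 0")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (k < 2) stopf("k must be >= 2")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), k = as.integer(k),
                 train_fraction = 1 - 1 / k, betas = betas,
                 weight_decay = weight_decay, adam_eps = adam_eps,
                 clip_norm = clip_norm,
                 lr_schedule = match.arg(lr_schedule), lr_min = lr_min,
                 mim_epochs = as.integer(mim_epochs), mim_lr = mim_lr,
                 max_restarts = as.integer(max_restarts),
                 restart_loss = restart_loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Leaves exempt from weight decay (norm gains, biases, learnable tokens).
.no_decay <- c("g", "b", "b1", "b2", "patch_b", "cls", "pos", "e_mask")

adamw_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

# One decoupled-weight-decay Adam step over the whole parameter tree, with
# optional global gradient-norm clipping; the recursion runs in C++.
adamw_step <- function(params, grads, state, cfg, clip_norm = Inf) {
  t <- state$t + 1L
  r <- cpp_adamw_step(params, grads, state$m, state$v, t, cfg$lr,
                      cfg$betas[1], cfg$betas[2], cfg$adam_eps,
                      cfg$weight_decay, .no_decay, clip_norm)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Cross-entropy of one sample from its probability vector.
ce_loss <- function(probs, class_idx) {
  -log(max(probs[class_idx + 1L], 1e-12))
}

#' Mean cross-entropy of a batch of stacks
#'
#' @param model An [stvit_model()].
#' @param stacks List of preprocessed stacks.
#' @param class_idx Integer vector of 0-based true class indices.
#' @return Mean of the per-sample cross-entropies.
#' @export
batch_loss <- function(model, stacks, class_idx) {
  mean(vapply(seq_along(stacks), function(i) {
    ce_loss(stvit_fwd(model, stacks[[i]]$images)$probs, class_idx[i])
  }, numeric(1)))
}

# Ensure stacks are preprocessed to the model's input size.
.prep_all <- function(stacks, size) {
  lapply(stacks, function(s) {
    if (isTRUE(attr(s, "preprocessed"))) s else preprocess_stack(s, size)
  })
}

#' Train the classifier on one training set
#'
#' Minimizes mean cross-entropy with AdamW over shuffled mini-batches of
#' full stacks. Fully seeded: weight init, data order and (in MIM mode)
#' masking all derive from `train_cfg$seed`, so identical inputs reproduce
#' identical weights and losses.
#'
#' @param stacks Named list of `organoid_stack` (raw stacks are
#'   preprocessed to the model input size on entry).
#' @param train_cfg A [train_config()].
#' @param encoder,spatial,temporal Model configurations (ignored when
#'   `model` is supplied).
#' @param use_spatial Keep the spatial encoder (see [stvit_model()]).
#' @param model Optional pre-built [stvit_model()] to train from.
#' @return An `stvit_fit`: list with `model`, `loss_curve` tibble
#'   (epoch, loss) and `train_cfg`.
#' @export
train_fold <- function(stacks, train_cfg = train_config(),
                       encoder = encoder_config(),
                       spatial = spatial_config(),
                       temporal = temporal_config(),
                       use_spatial = TRUE, model = NULL) {
  if (length(stacks) == 0) stopf("no training samples")
  labels <- vapply(stacks, function(s) as.character(s$label), character(1))
  present <- dili_levels() %in% labels
  if (!all(present)) {
    stopf("training set is missing class %s",
          paste(dili_levels()[!present], collapse = ", "))
  }
  cls <- dili_class_index(labels)
  # restart-on-non-convergence: judged on TRAINING loss only, so held-out
  # folds never influence the decision
  n_attempts <- if (is.null(model)) (train_cfg$max_restarts %||% 0L) + 1L
                else 1L
  init_seeds <- derive_seeds(train_cfg$seed, n_attempts)
  mim_seeds <- derive_seeds(train_cfg$seed + 1L, n_attempts)
  best <- NULL
  for (attempt in seq_len(n_attempts)) {
    m_a <- if (is.null(model)) {
      stvit_model(encoder, spatial, temporal, use_spatial = use_spatial,
                  seed = init_seeds[attempt])
    } else {
      model
    }
    stacks <- .prep_all(stacks, m_a$cfg$encoder$image_size)
    if ((train_cfg$mim_epochs %||% 0L) > 0) {
      m_a <- mim_pretrain(m_a, stacks, epochs = train_cfg$mim_epochs,
                          lr = train_cfg$mim_lr,
                          seed = mim_seeds[attempt])$model
    }
    fit <- .train_attempt(stacks, cls, train_cfg, m_a)
    if (is.null(best) ||
        tail(fit$losses, 1) < tail(best$losses, 1)) {
      best <- fit
    }
    if (tail(best$losses, 1) <= (train_cfg$restart_loss %||% Inf)) break
  }
  structure(list(model = best$model,
                 loss_curve = tibble::tibble(
                   epoch = seq_len(train_cfg$epochs), loss = best$losses),
                 train_cfg = train_cfg), class = "stvit_fit")
}

# One optimization run over a fixed initial model.
.train_attempt <- function(stacks, cls, train_cfg, model) {
  n <- length(stacks)
  # patch extraction is static; do it once, not every epoch
  xps <- lapply(stacks, function(s) {
    build_patch_rows(unlist(s$images, recursive = FALSE),
                     model$cfg$encoder)
  })
  state <- adamw_init(model$params)
  losses <- numeric(train_cfg$epochs)
  base_lr <- train_cfg$lr
  withr::with_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      if (identical(train_cfg$lr_schedule, "cosine") && train_cfg$epochs > 1) {
        frac <- (ep - 1) / (train_cfg$epochs - 1)
        train_cfg$lr <- train_cfg$lr_min +
          (base_lr - train_cfg$lr_min) * (1 + cos(pi * frac)) / 2
      }
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
        fw <- stvit_batch_fwd(model, lapply(idx, function(i) {
          stacks[[i]]$images
        }), xps = xps[idx], keep_cache = TRUE)
        ep_loss <- ep_loss +
          sum(-log(pmax(fw$probs[cbind(seq_along(idx), cls[idx] + 1L)],
                        1e-12)))
        dlogits <- fw$probs
        dlogits[cbind(seq_along(idx), cls[idx] + 1L)] <-
          dlogits[cbind(seq_along(idx), cls[idx] + 1L)] - 1
        gmean <- tree_scale(stvit_batch_bwd(model, fw, dlogits),
                            1 / length(idx))
        upd <- adamw_step(model$params, gmean, state, train_cfg,
                          clip_norm = train_cfg$clip_norm)
        model$params <- upd$params
        state <- upd$state
      }
      losses[ep] <- ep_loss / n
    }
  })
  list(model = model, losses = losses)
}

#' Predict a set of stacks
#'
#' @param model An [stvit_model()].
#' @param stacks Named list of stacks.
#' @return Tibble: `sample_id`, `truth`, `pred`, and one probability column
#'   per class (`p_vNo`, `p_vLess`, `p_vMost`).
#' @export
predict_stacks <- function(model, stacks) {
  stacks <- .prep_all(stacks, model$cfg$encoder$image_size)
  rows <- lapply(stacks, function(s) {
    r <- classify_forward(model, s)
    tibble::tibble(sample_id = s$sample_id, truth = as.character(s$label),
                   pred = as.character(r$prediction),
                   p_vNo = r$probs[1], p_vLess = r$probs[2],
                   p_vMost = r$probs[3])
  })
  dplyr::bind_rows(rows)
}

#' K-fold cross-validation of the classifier
#'
#' Splits samples with [split_kfold()], trains one model per fold on its
#' training portion only, scores the held-out fold, and averages the fold
#' metrics (every sample is scored exactly once).
#'
#' @inheritParams train_fold
#' @param stratify Stratify folds by label.
#' @param keep_models Retain the K fitted models (default `FALSE`).
#' @param n_folds_run Train/evaluate only the first `n_folds_run` folds of
#'   the K-fold plan (default all K) — a quick-look option; fold splits and
#'   per-fold seeds are identical to the full run.
#' @return An `stvit_cv`: list with `predictions` (tibble incl. `fold`),
#'   `fold_reports` (list of `metrics_report`), `mean_report`, `folds`, and
#'   optionally `fits`.
#' @export
cross_validate <- function(stacks, train_cfg = train_config(),
                           encoder = encoder_config(),
                           spatial = spatial_config(),
                           temporal = temporal_config(),
                           use_spatial = TRUE, stratify = TRUE,
                           keep_models = FALSE, n_folds_run = NULL) {
  samples <- tibble::tibble(
    sample_id = vapply(stacks, `[[`, character(1), "sample_id"),
    label = vapply(stacks, function(s) as.character(s$label), character(1)))
  names(stacks) <- samples$sample_id
  folds <- split_kfold(samples, k = train_cfg$k, seed = train_cfg$seed,
                       stratify = stratify)
  fold_seeds <- derive_seeds(train_cfg$seed + 1L, length(folds))
  stacks <- .prep_all(stacks, encoder$image_size)
  preds <- list()
  reports <- list()
  fits <- list()
  run_folds <- seq_len(min(n_folds_run %||% length(folds), length(folds)))
  for (f in run_folds) {
    cfg_f <- train_cfg
    cfg_f$seed <- fold_seeds[f]
    fit <- train_fold(stacks[folds[[f]]$train], cfg_f, encoder, spatial,
                      temporal, use_spatial = use_spatial)
    pr <- predict_stacks(fit$model, stacks[folds[[f]]$test])
    pr$fold <- f
    preds[[f]] <- pr
    reports[[f]] <- evaluate_predictions(
      pr$truth, pr$pred, as.matrix(pr[, c("p_vNo", "p_vLess", "p_vMost")]),
      levels = dili_levels())
    if (keep_models) fits[[f]] <- fit
  }
  structure(list(predictions = dplyr::bind_rows(preds),
                 fold_reports = reports,
                 mean_report = mean_metrics_report(reports),
                 folds = folds,
                 fits = if (keep_models) fits else NULL,
                 train_cfg = train_cfg), class = "stvit_cv")
}

#' @export
print.stvit_cv <- function(x, ...) {
  accs <- vapply(x$fold_reports, `[[`, numeric(1), "accuracy")
  cat(sprintf("<stvit_cv> %d folds | fold accuracies: %s | mean %.4f\n",
              length(accs), paste(sprintf("%.3f", accs), collapse = " "),
              x$mean_report$accuracy))
  invisible(x)
}
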
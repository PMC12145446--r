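# Training-machinery tests run on a micro configuration (8-dim encoder,
# 32 px frames) so the whole file stays in seconds.

micro_train_setup <- function(n_per_class = 1, seed = 21) {
  fixture(paste0("train_setup_", n_per_class, "_", seed), function() {
    cfg <- sim_config(image_size = 32, z_planes_range = c(2, 2),
                      organoids_per_field = c(1, 1))
    generate_stacks(n_per_class, cfg, seed = seed)
  })
}

micro_enc <- function() tiny_enc(image_size = 32, patch_size = 8)

test_that("three samples are memorized within a few epochs", {
  gen <- micro_train_setup()
  # wide-but-shallow configuration: 5 tokens per frame, D = 64
  fit <- train_fold(gen$stacks,
                    train_config(lr = 1e-3, epochs = 50, batch_size = 3,
                                 betas = c(0.9, 0.98), seed = 5),
                    encoder = encoder_config(image_size = 32,
                                             patch_size = 16,
                                             embed_dim = 64, depth = 2,
                                             n_heads = 4, mlp_ratio = 2),
                    temporal = temporal_config(hidden = 16))
  expect_lt(tail(fit$loss_curve$loss, 1), head(fit$loss_curve$loss, 1))
  pr <- predict_stacks(fit$model, gen$stacks)
  expect_equal(pr$pred, pr$truth)
})

test_that("zero learning rate leaves the weights untouched", {
  gen <- micro_train_setup()
  ns <- asNamespace("organoidvit")
  cfgt <- train_config(lr = 0, epochs = 2, batch_size = 3, seed = 5)
  m0 <- stvit_model(micro_enc(), temporal = temporal_config(hidden = 8),
                    seed = ns$derive_seeds(cfgt$seed, 1))
  fit <- train_fold(gen$stacks, cfgt, model = m0)
  expect_equal(ns$tree_flatten(m0$params), ns$tree_flatten(fit$model$params),
               tolerance = 1e-15)
})

test_that("training is deterministic under a fixed seed", {
  gen <- micro_train_setup()
  cfgt <- train_config(lr = 5e-4, epochs = 4, batch_size = 2,
                       betas = c(0.9, 0.98), seed = 9)
  f1 <- train_fold(gen$stacks, cfgt, encoder = micro_enc(),
                   temporal = temporal_config(hidden = 8))
  f2 <- train_fold(gen$stacks, cfgt, encoder = micro_enc(),
                   temporal = temporal_config(hidden = 8))
  expect_equal(tail(f1$loss_curve$loss, 1), tail(f2$loss_curve$loss, 1),
               tolerance = 1e-9)
  expect_identical(f1$loss_curve, f2$loss_curve)
})

test_that("a class missing from the training set is a stratification error", {
  gen <- micro_train_setup()
  two <- gen$stacks[gen$samples$label != "vMost-DILI-Concern"]
  expect_error(train_fold(two, train_config(epochs = 1)), "missing class")
})

test_that("batch loss equals the mean of per-sample cross-entropies", {
  gen <- micro_train_setup(n_per_class = 2, seed = 33)
  m <- stvit_model(micro_enc(), temporal = temporal_config(hidden = 8),
                   seed = 4)
  stacks <- lapply(gen$stacks, preprocess_stack, size = 32)
  cls <- dili_class_index(gen$samples$label)
  ns <- asNamespace("organoidvit")
  per_sample <- vapply(seq_along(stacks), function(i) {
    ns$ce_loss(ns$stvit_fwd(m, stacks[[i]]$images)$probs, cls[i])
  }, numeric(1))
  expect_equal(batch_loss(m, stacks, cls), mean(per_sample),
               tolerance = 1e-12)
  # the batched training path computes the same losses
  bf <- ns$stvit_batch_fwd(m, lapply(stacks, `[[`, "images"))
  batched <- -log(bf$probs[cbind(seq_along(cls), cls + 1L)])
  expect_equal(unname(batched), unname(per_sample), tolerance = 1e-9)
})

test_that("MIM pretraining reduces reconstruction loss and changes only the
           image branch", {
  gen <- micro_train_setup(n_per_class = 1, seed = 44)
  m <- stvit_model(micro_enc(), temporal = temporal_config(hidden = 8),
                   seed = 4)
  # fixed-mask reconstruction error on a training frame drops after
  # pretraining (per-epoch losses themselves are noisy: fresh masks)
  frame <- preprocess_image(gen$stacks[[1]]$images[[1]][[1]], size = 32)
  mask <- sample_mask(16, 0.4, seed = 9)
  before <- mim_corrupt_and_loss(m, frame, mask = mask)$loss
  pre <- mim_pretrain(m, gen$stacks, epochs = 8, batch_frames = 8,
                      lr = 1e-3, seed = 2)
  after <- mim_corrupt_and_loss(pre$model, frame, mask = mask)$loss
  expect_lt(after, before)
  expect_identical(pre$model$params$head, m$params$head)
  expect_identical(pre$model$params$tem, m$params$tem)
  expect_false(identical(pre$model$params$img$patch_W, m$params$img$patch_W))
  expect_false(identical(pre$model$params$img$e_mask, m$params$img$e_mask))
})

test_that("cross-validation scores every sample exactly once", {
  gen <- micro_train_setup(n_per_class = 4, seed = 55)
  cv <- cross_validate(gen$stacks,
                       train_config(lr = 1e-3, epochs = 2, batch_size = 4,
                                    k = 4, seed = 3),
                       encoder = micro_enc(),
                       temporal = temporal_config(hidden = 8))
  expect_length(cv$fold_reports, 4)
  expect_setequal(cv$predictions$sample_id, gen$samples$sample_id)
  expect_equal(anyDuplicated(cv$predictions$sample_id), 0)
  # no test sample appears in its own fold's training ids
  for (f in seq_along(cv$folds)) {
    expect_length(intersect(cv$folds[[f]]$train, cv$folds[[f]]$test), 0)
  }
  # averaged accuracy is the arithmetic mean of fold accuracies
  accs <- vapply(cv$fold_reports, `[[`, numeric(1), "accuracy")
  expect_equal(cv$mean_report$accuracy, mean(accs))
  td <- tidy(cv)
  expect_true(all(c("class", "metric", "value", "fold") %in% names(td)))
  gl <- glance(cv)
  expect_equal(gl$accuracy, cv$mean_report$accuracy)
  expect_equal(gl$k, 4)
})

test_that("the spatial-bypass variant trains and predicts on fused stacks", {
  gen <- micro_train_setup(n_per_class = 2, seed = 66)
  cv <- run_ablation(gen$stacks,
                     train_config(lr = 1e-3, epochs = 2, batch_size = 3,
                                  k = 2, seed = 2),
                     encoder = micro_enc(),
                     temporal = temporal_config(hidden = 8),
                     mode = "no_spatial", n_folds_run = 1)
  expect_length(cv$fold_reports, 1)
  expect_equal(nrow(cv$predictions), 3)
  # one fused image per day reaches the bypass model
  st <- ablate_stack(gen$stacks[[1]], "no_spatial")
  m <- stvit_model(micro_enc(), temporal = temporal_config(hidden = 8),
                   use_spatial = FALSE, seed = 3)
  r <- classify_forward(m, st)
  expect_equal(sum(r$probs), 1, tolerance = 1e-12)
  expect_false("spa" %in% names(m$params))
  # a multi-plane stack is rejected by the bypass model
  expect_error(classify_forward(m, gen$stacks[[1]]), "one image per day")
})

test_that("loss curves plot and tidy", {
  gen <- micro_train_setup()
  fit <- train_fold(gen$stacks,
                    train_config(lr = 1e-3, epochs = 3, batch_size = 3,
                                 seed = 5),
                    encoder = micro_enc(),
                    temporal = temporal_config(hidden = 8))
  expect_equal(nrow(tidy(fit)), 3)
  expect_s3_class(autoplot(fit), "ggplot")
})
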
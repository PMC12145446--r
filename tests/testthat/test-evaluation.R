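test_that("confusion matrices tally predictions against truth", {
  lv <- dili_levels()
  perfect <- compute_confusion(lv[c(1, 2, 3, 1)], lv[c(1, 2, 3, 1)])
  expect_equal(diag(perfect), c(2, 1, 1), ignore_attr = TRUE)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  all_vno <- compute_confusion(lv[c(1, 2, 3)], rep(lv[1], 3))
  expect_equal(colSums(all_vno), c(3, 0, 0), ignore_attr = TRUE)
  withr::with_seed(6, {
    truth <- sample(lv, 20, TRUE)
    pred <- sample(lv, 20, TRUE)
    cm <- compute_confusion(truth, pred)
    for (i in 1:3) for (j in 1:3) {
      expect_equal(cm[i, j], sum(truth == lv[i] & pred == lv[j]))
    }
  })
  expect_error(compute_confusion(lv[1:2], lv[1]), "length")
})

test_that("per-class metrics reproduce the printed F1 identities", {
  # published F1s are computed from integer counts, so F1 from the rounded
  # rates agrees to ~1 unit in the 4th decimal ...
  expect_equal(f1_score(0.7971, 0.9016), 0.8462, tolerance = 1e-4)
  expect_equal(f1_score(0.7500, 0.7500), 0.7500, tolerance = 1e-12)
  expect_equal(f1_score(0.8769, 0.7808), 0.8261, tolerance = 1e-4)
  # ... and exactly once the underlying counts are recovered
  vno <- reconstruct_ovr_counts(0.9016, 0.7971)
  expect_equal(vno$tp, 55)
  expect_equal(round(vno$f1, 4), 0.8462)
  vmost <- reconstruct_ovr_counts(0.7808, 0.8769)
  expect_equal(round(vmost$f1, 4), 0.8261)
  expect_equal(round(reconstruct_ovr_counts(0.75, 0.75)$f1, 4), 0.75)
  expect_equal(f1_score(0, 0), 0)
})

test_that("metric families match a brute-force one-vs-rest oracle", {
  cm <- matrix(c(5, 1, 0, 1, 3, 1, 0, 1, 6), 3, 3, byrow = TRUE,
               dimnames = list(dili_levels(), dili_levels()))
  rep <- compute_metrics(cm)
  oracle <- ovr_oracle(cm)
  for (c in 1:3) {
    tp <- unname(oracle[c, "tp"]); fp <- unname(oracle[c, "fp"])
    fn <- unname(oracle[c, "fn"]); tn <- unname(oracle[c, "tn"])
    expect_equal(rep$per_class$recall[c], tp / (tp + fn))
    expect_equal(rep$per_class$specificity[c], tn / (tn + fp))
    expect_equal(rep$per_class$precision[c], tp / (tp + fp))
    expect_equal(rep$per_class$f1[c],
                 f1_score(tp / (tp + fp), tp / (tp + fn)))
  }
  expect_equal(rep$accuracy, sum(diag(cm)) / sum(cm))
  # identity confusion: every metric is 1
  eye <- diag(c(4L, 5L, 6L))
  dimnames(eye) <- list(dili_levels(), dili_levels())
  rep1 <- compute_metrics(eye)
  expect_true(all(abs(as.matrix(rep1$per_class[, 2:5]) - 1) < 1e-12))
  expect_equal(rep1$accuracy, 1)
  # zero-denominator classes are flagged and reported as 0
  degen <- matrix(c(3L, 0L, 0L, 2L), 2, 2)
  repd <- compute_metrics(degen)
  expect_true(any(repd$per_class$degenerate) || all(!repd$per_class$degenerate))
  expect_error(compute_metrics(matrix(0L, 3, 3)), "empty")
})

test_that("ROC/AUC agrees with trivial cases and the concordance oracle", {
  lv <- dili_levels()
  truth <- lv[c(1, 1, 2, 2, 3, 3)]
  onehot <- diag(3)[dili_class_index(truth) + 1, ]
  r <- roc_curves(truth, onehot)
  expect_equal(unname(r$auc), rep(1, 3))
  const <- matrix(1 / 3, 6, 3)
  rc <- roc_curves(truth, const)
  expect_equal(unname(rc$auc), rep(0.5, 3))
  # 8-sample hand-built table vs exhaustive pairwise concordance
  withr::with_seed(11, {
    for (rep in 1:6) {
      n <- sample(5:12, 1)
      truth_i <- sample(lv, n, TRUE)
      if (length(unique(truth_i)) < 2) truth_i[1:2] <- lv[1:2]
      p <- matrix(runif(n * 3), n, 3)
      p <- p / rowSums(p)
      ra <- suppressWarnings(roc_curves(truth_i, p))
      for (ci in 1:3) {
        expect_equal(unname(ra$auc[ci]),
                     concordance_auc(p[, ci], truth_i == lv[ci]),
                     tolerance = 1e-12)
      }
    }
  })
  # degenerate class is flagged, AUC undefined
  expect_warning(rd <- roc_curves(lv[c(1, 1, 2)], matrix(1 / 3, 3, 3)),
                 "degenerate")
  expect_true(is.na(rd$auc[3]))
  expect_error(roc_curves(lv[1:2], matrix(c(1, 1, 1, 1), 2, 2)), "sum to 1")
})

test_that("focus stacking picks the sharpest plane per pixel", {
  cfg <- sim_config(image_size = 48, noise_sd = 0)
  # Z = 1 identity
  st1 <- generate_sample("vLess-DILI-Concern",
                         sim_config(image_size = 48,
                                    z_planes_range = c(1, 1),
                                    organoids_per_field = c(1, 1),
                                    noise_sd = 0), seed = 3)
  f1 <- fuse_zstack(st1)
  expect_identical(f1$images[[1]][[1]], st1$images[[1]][[1]])
  # a globally sharpest plane dominates the fusion
  sharp <- matrix(0.5, 48, 48)
  sharp[20:28, 20:28] <- matrix(runif(81), 9, 9)
  flat <- matrix(0.5, 48, 48)
  st <- structure(list(sample_id = "x", label = dili_label(dili_levels()[1]),
                       compound = "c", platform = "HLO",
                       images = list(list(flat, sharp)),
                       z_positions = c(0, 1), day_indices = 0L),
                  class = "organoid_stack")
  fused <- fuse_zstack(st)$images[[1]][[1]]
  expect_equal(fused[20:28, 20:28], sharp[20:28, 20:28])
  # two organoids sharp in different planes: fused at least as sharp as both
  cfg2 <- sim_config(image_size = 64, z_planes_range = c(6, 6),
                     organoids_per_field = c(2, 2), noise_sd = 0)
  st2 <- generate_sample("vLess-DILI-Concern", cfg2, seed = 8)
  fu <- fuse_zstack(st2)$images[[1]][[1]]
  ge <- vapply(st2$images[[1]], gradient_energy, numeric(1))
  expect_gte(gradient_energy(fu), max(ge) * 0.999)
})

test_that("ablation transforms truncate days or fuse planes", {
  cfg <- sim_config(image_size = 32, z_planes_range = c(3, 3),
                    organoids_per_field = c(1, 1))
  st <- generate_sample("vNo-DILI-Concern", cfg, seed = 5)
  tr <- ablate_stack(st, "temporal_D0D1")
  expect_equal(tr$day_indices, 0:1)
  expect_length(tr$images, 2)
  expect_length(tr$images[[1]], 3)         # z untouched
  sp <- ablate_stack(st, "no_spatial")
  expect_length(sp$images, 4)
  expect_length(sp$images[[1]], 1)         # one fused image per day
  expect_error(ablate_stack(st, "bogus"))
})

test_that("ablation deltas are reported in percentage points", {
  r1 <- ablation_report(0.8234, 0.7025)
  expect_equal(r1$accuracy_decrease_pp, 12.09, tolerance = 1e-9)
  r2 <- ablation_report(0.8234, 0.7610)
  expect_equal(r2$accuracy_decrease_pp, 6.24, tolerance = 1e-9)
  cm <- diag(c(5L, 5L, 5L))
  dimnames(cm) <- list(dili_levels(), dili_levels())
  rep <- compute_metrics(cm)
  r3 <- ablation_report(rep, rep)
  expect_equal(r3$accuracy_decrease_pp, 0)
  expect_true(all(as.matrix(r3$per_class[, -1]) == 0))
})

test_that("tidiers expose reports as tables", {
  cm <- matrix(c(5L, 1L, 0L, 1L, 3L, 1L, 0L, 1L, 6L), 3, 3, byrow = TRUE,
               dimnames = list(dili_levels(), dili_levels()))
  rep <- compute_metrics(cm)
  td <- tidy(rep)
  expect_true(all(c("class", "metric", "value") %in% names(td)))
  expect_equal(nrow(td), 12)               # 3 classes x 4 defined metrics
  gl <- glance(rep)
  expect_equal(gl$accuracy, rep$accuracy)
  expect_equal(gl$n, 18)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
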
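test_that("a generated index round-trips through load_index", {
  cfg <- sim_config(image_size = 32, z_planes_range = c(2, 2),
                    organoids_per_field = c(1, 1))
  dir <- withr::local_tempdir()
  idx <- generate_dataset(1, cfg, seed = 2, out_dir = dir)
  loaded <- load_index(file.path(dir, "index.csv"))
  expect_equal(nrow(loaded), nrow(idx))
  expect_equal(loaded$sample_id, idx$sample_id)
  expect_equal(loaded$label, idx$label)
  expect_equal(loaded$day, idx$day)
  expect_equal(loaded$z, idx$z)
  # stacks read back match the in-memory render to 16-bit quantisation
  st_mem <- generate_stacks(1, cfg, seed = 2)$stacks[[1]]
  st_disk <- load_stack(loaded, st_mem$sample_id)
  expect_equal(as.character(st_disk$label), as.character(st_mem$label))
  expect_lt(max(abs(st_disk$images[[1]][[1]] - st_mem$images[[1]][[1]])),
            1.5 / 65535)
})

test_that("ambiguous labels and malformed stacks are rejected", {
  cfg <- sim_config(image_size = 32, z_planes_range = c(2, 2),
                    organoids_per_field = c(1, 1))
  dir <- withr::local_tempdir()
  generate_dataset(1, cfg, seed = 2, out_dir = dir)
  path <- file.path(dir, "index.csv")
  idx <- readr::read_csv(path, show_col_types = FALSE)
  bad <- idx
  bad$label[1] <- "Ambiguous DILI-concern"
  readr::write_csv(bad, file.path(dir, "bad1.csv"))
  expect_error(load_index(file.path(dir, "bad1.csv")), "excluded")
  # 2 z rows on day 0 but 1 on day 1 for one sample
  bad2 <- idx[!(idx$sample_id == idx$sample_id[1] & idx$day == 1 &
                  idx$z == 1), ]
  readr::write_csv(bad2, file.path(dir, "bad2.csv"))
  expect_error(load_index(file.path(dir, "bad2.csv")), "focal-plane")
  bad3 <- idx
  bad3$path[1] <- "does_not_exist.tif"
  readr::write_csv(bad3, file.path(dir, "bad3.csv"))
  expect_error(load_index(file.path(dir, "bad3.csv")), "missing image")
  expect_error(load_index(file.path(dir, "nope.csv")), "exist")
})

test_that("preprocessing resizes, replicates channels and standardizes", {
  big <- matrix(runif(448 * 448), 448, 448)
  out <- preprocess_image(big, size = 224)
  expect_equal(dim(out), c(224, 224, 3))
  expect_identical(out[, , 1], out[, , 2])
  # constant image: resize leaves values unchanged before standardization
  const <- matrix(0.25, 64, 64)
  outc <- preprocess_image(const, size = 32)
  expect_equal(unique(as.vector(outc)), (0.25 - 0.5) / 0.5, tolerance = 1e-12)
  # the affine transform is recomputable directly
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(preprocess_image(x, size = 32, mean = 0.3, sd = 0.2)[, , 1],
               (x - 0.3) / 0.2, tolerance = 1e-12)
  # 8-bit style input is rescaled to [0,1] first
  x8 <- matrix(as.numeric(sample(0:255, 64, TRUE)), 8, 8)
  out8 <- preprocess_image(x8, size = 8)
  expect_equal(out8[, , 1], (x8 / 255 - 0.5) / 0.5, tolerance = 1e-12)
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "empty")
  expect_error(preprocess_image(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("k-fold splits partition samples with balanced stratified folds", {
  s <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                      label = rep(dili_levels(), length.out = 10))
  folds <- suppressWarnings(split_kfold(s, k = 5, seed = 3))
  expect_length(folds, 5)
  test_sets <- lapply(folds, `[[`, "test")
  expect_equal(lengths(test_sets), rep(2L, 5))
  expect_setequal(unlist(test_sets), s$sample_id)
  expect_equal(anyDuplicated(unlist(test_sets)), 0)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), s$sample_id)
  }
  # identical folds for identical seed
  expect_identical(folds, suppressWarnings(split_kfold(s, k = 5, seed = 3)))
  expect_false(identical(folds,
                         suppressWarnings(split_kfold(s, k = 5, seed = 4))))
})

test_that("fold partition properties hold over random sizes", {
  withr::with_seed(42, {
    for (rep in 1:8) {
      n <- sample(6:40, 1)
      kmax <- min(5, n %/% 3)
      k <- sample.int(kmax - 1L, 1) + 1L
      s <- tibble::tibble(
        sample_id = sprintf("S%03d", seq_len(n)),
        label = sample(dili_levels(), n, TRUE))
      # guarantee >= k per class for stratification
      s$label[seq_len(3 * k)] <- rep(dili_levels(), k)
      folds <- split_kfold(s, k = k, seed = rep)
      sizes <- lengths(lapply(folds, `[[`, "test"))
      expect_setequal(unlist(lapply(folds, `[[`, "test")), s$sample_id)
      expect_lte(max(sizes) - min(sizes), 1)
      expect_true(all(vapply(folds, function(f)

        length(f$train) + length(f$test) == n, logical(1))))
    }
  })
})

test_that("train fraction matches the 80:20 protocol at k = 5", {
  s <- tibble::tibble(sample_id = sprintf("S%03d", 1:30),
                      label = rep(dili_levels(), 10))
  folds <- split_kfold(s, k = 5, seed = 1)
  for (f in folds) expect_equal(length(f$train) / 30, 0.8)
})

test_that("group-disjoint folds keep a compound in one fold", {
  s <- tibble::tibble(sample_id = sprintf("S%02d", 1:12),
                      label = rep(dili_levels(), 4),
                      compound = rep(sprintf("C%d", 1:6), each = 2))
  folds <- split_kfold(s, k = 3, seed = 2, group_by = "compound")
  for (f in folds) {
    test_compounds <- s$compound[s$sample_id %in% f$test]
    train_compounds <- s$compound[s$sample_id %in% f$train]
    expect_length(intersect(test_compounds, train_compounds), 0)
  }
  expect_error(split_kfold(s, k = 20, seed = 1), "exceeds")
})
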
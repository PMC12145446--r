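# Sample- and dataset-level synthetic data generation.

.class_short <- c("NO", "LESS", "MOST")

# Place n_target organoid centres with minimum separation by rejection
# sampling; returns possibly fewer centres when the field is crowded.
.place_centres <- function(n_target, image_size, min_sep, margin) {
  cx <- cy <- numeric(0)
  tries <- 0L
  lo <- margin
  hi <- image_size - margin
  if (hi <= lo) {
    lo <- image_size * 0.25
    hi <- image_size * 0.75
  }
  while (length(cx) < n_target && tries < 400L) {
    tries <- tries + 1L
    x <- runif(1, lo, hi)
    y <- runif(1, lo, hi)
    if (length(cx) == 0 || all(sqrt((cx - x)^2 + (cy - y)^2) >= min_sep)) {
      cx <- c(cx, x)
      cy <- c(cy, y)
    }
  }
  data.frame(cx = cx, cy = cy)
}

# Fragment geometry for one disintegrating organoid: k debris blobs
# scattered around the former centre, kept mutually separated.
.sample_fragments <- function(st, k, image_size) {
  fr <- data.frame(cx = numeric(0), cy = numeric(0), radius = numeric(0))
  tries <- 0L
  while (nrow(fr) < k && tries < 600L) {
    tries <- tries + 1L
    ang <- runif(1, 0, 2 * pi)
    dist <- runif(1, 0.5, 3.0) * st$radius
    x <- min(max(st$cx + dist * cos(ang), 3), image_size - 3)
    y <- min(max(st$cy + dist * sin(ang), 3), image_size - 3)
    r <- max(st$radius * runif(1, 0.30, 0.45), 1.5)
    ok <- nrow(fr) == 0 ||
      all(sqrt((fr$cx - x)^2 + (fr$cy - y)^2) >= 1.2 * (fr$radius + r) + 1)
    if (ok) fr <- rbind(fr, data.frame(cx = x, cy = y, radius = r))
  }
  fr
}

# Per-day organoid states for one sample; geometry is sampled once, then
# evolved deterministically by class.
.sample_states <- function(label_idx, cfg) {
  g <- cfg$growth_rate_per_day[[c("vNo", "vLess", "vMost")[label_idx + 1]]]
  n_org <- if (cfg$organoids_per_field[1] == cfg$organoids_per_field[2]) {
    cfg$organoids_per_field[1]
  } else {
    sample(cfg$organoids_per_field[1]:cfg$organoids_per_field[2], 1)
  }
  r_final <- max(cfg$init_radius_px) * (1 + max(cfg$growth_rate_per_day))^
    (cfg$n_days - 1)
  centres <- .place_centres(n_org, cfg$image_size,
                            min_sep = 2.3 * r_final, margin = 1.2 * r_final)
  states0 <- lapply(seq_len(nrow(centres)), function(i) {
    r0 <- runif(1, cfg$init_radius_px[1], cfg$init_radius_px[2])
    list(cx = centres$cx[i], cy = centres$cy[i], radius = r0,
         ring = 0.35 * r0, focal_depth = runif(1, 0.05, 0.95),
         fragments = NULL)
  })
  days <- seq_len(cfg$n_days) - 1L
  onset <- cfg$disintegration_onset_day
  # evolve radii; for vMost sample the fragment geometry once at onset
  frag_sets <- NULL
  if (label_idx == 2L && cfg$n_days > onset) {
    frag_sets <- lapply(states0, function(st) {
      st_on <- st
      st_on$radius <- st$radius * (1 + g)^onset
      k <- if (cfg$fragment_count_range[1] == cfg$fragment_count_range[2]) {
        cfg$fragment_count_range[1]
      } else {
        sample(cfg$fragment_count_range[1]:cfg$fragment_count_range[2], 1)
      }
      .sample_fragments(st_on, k, cfg$image_size)
    })
  }
  lapply(days, function(d) {
    lapply(seq_along(states0), function(i) {
      st <- states0[[i]]
      st$radius <- st$radius * (1 + g)^d
      st$ring <- 0.35 * st$radius
      if (label_idx == 2L && d >= onset && !is.null(frag_sets)) {
        fr <- frag_sets[[i]]
        fr$radius <- fr$radius * 0.85^(d - onset)
        st$fragments <- fr
      }
      st
    })
  })
}

#' Generate one synthetic organoid sample
#'
#' Produces a T-day by Z-plane brightfield stack whose morphology follows the
#' phenotype of `label`: hollow-sphere growth (`vNo`), growth arrest with an
#' intact sphere (`vLess`), or disintegration into debris from the onset day
#' (`vMost`). Bit-identical output for identical `(label, cfg, seed)`.
#'
#' @param label One of [dili_levels()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @param sample_id Identifier recorded in the stack (default derived from
#'   the seed).
#' @param platform `"HLO"` or `"HepG2"` metadata tag.
#' @return An `organoid_stack`: list with `sample_id`, `label`, `compound`,
#'   `platform`, `images` (list of `n_days` lists of Z intensity matrices),
#'   `z_positions` (normalized depths in `[0, 1]`) and `day_indices`.
#' @export
#' @examples
#' cfg <- sim_config(image_size = 48, z_planes_range = c(3, 3), noise_sd = 0)
#' st <- generate_sample("vNo-DILI-Concern", cfg, seed = 1)
#' length(st$images)          # days
#' dim(st$images[[1]][[1]])   # one frame
generate_sample <- function(label, cfg, seed = cfg$seed,
                            sample_id = NULL, platform = "HLO") {
  label <- dili_label(label)
  if (length(label) != 1) stopf("generate_sample takes a single label")
  idx <- as.integer(label) - 1L
  if (!platform %in% c("HLO", "HepG2")) stopf("platform must be HLO or HepG2")
  withr::with_seed(as.integer(seed), {
    z_n <- if (cfg$z_planes_range[1] == cfg$z_planes_range[2]) {
      cfg$z_planes_range[1]
    } else {
      sample(cfg$z_planes_range[1]:cfg$z_planes_range[2], 1)
    }
    z_pos <- if (z_n == 1) 0.5 else seq(0, 1, length.out = z_n)
    states_by_day <- .sample_states(idx, cfg)
    compound <- paste0("SIM-", .class_short[idx + 1], "-",
                       sprintf("%03d", sample.int(999L, 1)))
    images <- lapply(seq_len(cfg$n_days), function(d) {
      lapply(seq_len(z_n), function(z) {
        render_field(d - 1L, z_pos[z], states_by_day[[d]], cfg)
      })
    })
    structure(list(
      sample_id = sample_id %||% sprintf("SIM%09d", as.integer(seed)),
      label = label, compound = compound, platform = platform,
      images = images, z_positions = z_pos,
      day_indices = seq_len(cfg$n_days) - 1L
    ), class = "organoid_stack")
  })
}

#' @export
print.organoid_stack <- function(x, ...) {
  cat(sprintf(
    "<organoid_stack> %s  label=%s  platform=%s  T=%d days x Z=%d planes of %dx%d\n",
    x$sample_id, as.character(x$label), x$platform, length(x$images),
    length(x$images[[1]]), nrow(x$images[[1]][[1]]), ncol(x$images[[1]][[1]])))
  invisible(x)
}

#' Generate a balanced in-memory synthetic dataset
#'
#' Convenience wrapper producing `n_per_class` stacks for each of the three
#' classes without touching the filesystem.
#'
#' @inheritParams generate_dataset
#' @return List with `stacks` (named list of `organoid_stack`) and `samples`
#'   (tibble of `sample_id`, `label`, `compound`, `platform`).
#' @export
generate_stacks <- function(n_per_class, cfg, seed = cfg$seed,
                            platform = "HLO") {
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  labels <- rep(dili_levels(), each = n_per_class)
  seeds <- derive_seeds(seed, length(labels))
  ids <- sprintf("S%03d", seq_along(labels))
  stacks <- purrr::map(seq_along(labels), function(i) {
    generate_sample(labels[i], cfg, seed = seeds[i], sample_id = ids[i],
                    platform = platform)
  })
  names(stacks) <- ids
  samples <- tibble::tibble(
    sample_id = ids,
    label = labels,
    compound = purrr::map_chr(stacks, "compound"),
    platform = platform
  )
  list(stacks = stacks, samples = samples)
}

#' Generate a synthetic dataset on disk
#'
#' Writes one 16-bit grayscale TIFF per (day, z) frame, named
#' `<sample_id>_d<day>_z<zz>.tif`, plus a CSV index with one row per image
#' and columns `sample_id,label,compound,platform,day,z,path`. The CSV
#' carries no timestamps, so identical `(n_per_class, cfg, seed)` reproduce
#' it byte for byte.
#'
#' @param n_per_class Samples per class (>= 1).
#' @param cfg A [sim_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if missing).
#' @param platform Platform tag recorded in the index.
#' @return The index as a tibble (invisibly written to
#'   `file.path(out_dir, "index.csv")`).
#' @export
generate_dataset <- function(n_per_class, cfg, seed = cfg$seed, out_dir,
                             platform = "HLO") {
  gen <- generate_stacks(n_per_class, cfg, seed, platform)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  rows <- purrr::map(gen$stacks, function(st) {
    grid <- expand.grid(z = seq_along(st$z_positions) - 1L,
                        day = st$day_indices)
    grid <- grid[order(grid$day, grid$z), ]
    paths <- sprintf("%s_d%d_z%02d.tif", st$sample_id, grid$day, grid$z)
    for (i in seq_len(nrow(grid))) {
      img <- st$images[[grid$day[i] + 1L]][[grid$z[i] + 1L]]
      EBImage::writeImage(EBImage::Image(img), file.path(out_dir, paths[i]),
                          type = "tiff", bits.per.sample = 16L)
    }
    tibble::tibble(sample_id = st$sample_id, label = as.character(st$label),
                   compound = st$compound, platform = st$platform,
                   day = grid$day, z = grid$z, path = paths)
  })
  index <- dplyr::bind_rows(rows)
  readr::write_csv(index, file.path(out_dir, "index.csv"))
  invisible(index)
}
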
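# Index and image stack I/O.

.index_cols <- c("sample_id", "label", "compound", "platform", "day", "z",
                 "path")

#' Load and validate a dataset index
#'
#' Reads the CSV index (`sample_id,label,compound,platform,day,z,path`; one
#' row per image), parses labels strictly via [dili_label()] (ambiguous
#' labels are an error, not a silent drop), and validates the stack
#' structure: within a sample every day must carry the same number of focal
#' planes, days must form a contiguous 0-based range shared by z indices,
#' and (optionally) every referenced image file must exist.
#'
#' @param path Path to the index CSV. Relative image paths are resolved
#'   against its directory.
#' @param check_paths Verify that every referenced image exists
#'   (default `TRUE`).
#' @return A `dataset_index` tibble (one row per image) with an absolute
#'   `path` column.
#' @export
load_index <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stopf("index file '%s' does not exist", path)
  idx <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", label = "c", compound = "c", platform = "c",
    day = "i", z = "i", path = "c"))
  missing_cols <- setdiff(.index_cols, names(idx))
  if (length(missing_cols)) {
    stopf("index is missing required columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  idx$label <- as.character(dili_label(idx$label))
  root <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", idx$path), idx$path,
                file.path(root, idx$path))
  idx$path <- abs
  validate_index(idx, check_paths = check_paths)
}

#' Validate an in-memory dataset index
#'
#' @param idx Tibble with the index columns (see [load_index()]).
#' @param check_paths Verify image files exist.
#' @return The validated index, classed `dataset_index`.
#' @export
validate_index <- function(idx, check_paths = FALSE) {
  for (sid in unique(idx$sample_id)) {
    sub <- idx[idx$sample_id == sid, ]
    days <- sort(unique(sub$day))
    if (!identical(days, seq(0L, max(days)))) {
      stopf("sample %s: days are not a contiguous 0-based range", sid)
    }
    z_per_day <- table(sub$day)
    if (length(unique(as.integer(z_per_day))) != 1) {
      stopf("sample %s: focal-plane count differs across days (%s)",
            sid, paste(as.integer(z_per_day), collapse = ", "))
    }
    if (length(unique(sub$label)) != 1) {
      stopf("sample %s: conflicting labels", sid)
    }
  }
  if (check_paths) {
    gone <- !file.exists(idx$path)
    if (any(gone)) stopf("missing image file: %s", idx$path[which(gone)[1]])
  }
  class(idx) <- unique(c("dataset_index", class(idx)))
  idx
}

#' One-row-per-sample view of an index
#'
#' @param idx A `dataset_index`.
#' @return Tibble with `sample_id`, `label`, `compound`, `platform`,
#'   `n_days`, `n_z`.
#' @export
index_samples <- function(idx) {
  idx |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      label = dplyr::first(.data$label),
      compound = dplyr::first(.data$compound),
      platform = dplyr::first(.data$platform),
      n_days = dplyr::n_distinct(.data$day),
      n_z = dplyr::n_distinct(.data$z),
      .groups = "drop")
}

# Read one image file as a [0,1] grayscale matrix (mean over channels for
# RGB input).
.read_gray <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  a
}

#' Load one sample's image stack from an index
#'
#' @param idx A `dataset_index`.
#' @param sample_id Sample to load.
#' @return An `organoid_stack` with raw `[0, 1]` grayscale frames.
#' @export
load_stack <- function(idx, sample_id) {
  sub <- idx[idx$sample_id == sample_id, ]
  if (nrow(sub) == 0) stopf("sample %s not in index", sample_id)
  days <- sort(unique(sub$day))
  images <- lapply(days, function(d) {
    rows <- sub[sub$day == d, ]
    rows <- rows[order(rows$z), ]
    lapply(rows$path, .read_gray)
  })
  n_z <- length(images[[1]])
  structure(list(
    sample_id = sample_id, label = dili_label(sub$label[1]),
    compound = sub$compound[1], platform = sub$platform[1],
    images = images,
    z_positions = if (n_z == 1) 0.5 else seq(0, 1, length.out = n_z),
    day_indices = days
  ), class = "organoid_stack")
}

#' Load every sample of an index
#'
#' @inheritParams load_stack
#' @return Named list of `organoid_stack`.
#' @export
load_stacks <- function(idx) {
  ids <- unique(idx$sample_id)
  setNames(lapply(ids, function(s) load_stack(idx, s)), ids)
}
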
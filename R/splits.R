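# K-fold cross-validation splits.

#' Stratified K-fold split of samples
#'
#' Partitions sample ids into K folds for cross-validation; with K = 5 each
#' training set comprises 80% of the data. Splitting operates on the SAMPLE
#' (every image of a sample follows it into its fold). With `stratify` the
#' folds balance class labels; with `group_by = "compound"` all samples of a
#' compound land in the same fold (compound-disjoint validation).
#'
#' @param samples A `dataset_index`, an [index_samples()] view, or any tibble
#'   with `sample_id` and `label` columns (plus the grouping column if used).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; identical inputs give identical folds.
#' @param stratify Balance labels across folds (default `TRUE`).
#' @param group_by Optional column name whose groups must not straddle folds.
#' @return List of K elements, each `list(train = ids, test = ids)`; the test
#'   sets partition the sample ids.
#' @export
#' @examples
#' s <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
#'                     label = rep(dili_levels(), length.out = 10))
#' f <- split_kfold(s, k = 5, seed = 1)
#' lengths(purrr::map(f, "test"))
split_kfold <- function(samples, k, seed, stratify = TRUE, group_by = NULL) {
  if (k < 2) stopf("k must be >= 2")
  if (!all(c("sample_id", "label") %in% names(samples))) {
    stopf("samples needs sample_id and label columns")
  }
  tab <- dplyr::distinct(tibble::as_tibble(samples)[,
    unique(c("sample_id", "label", group_by))])
  n <- nrow(tab)
  if (k > n) stopf("k = %d exceeds the %d available samples", k, n)
  unit <- if (is.null(group_by)) "sample_id" else group_by
  units <- dplyr::distinct(tab[, c(unit, "label")])
  if (anyDuplicated(units[[unit]])) {
    units <- units |>
      dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  if (stratify) {
    counts <- table(units$label)
    if (any(counts < k) && is.null(group_by)) {
      warning(sprintf(
        "a class has fewer samples (%d) than folds (%d); stratification is best-effort",
        min(counts), k))
    }
  }
  fold_of <- withr::with_seed(as.integer(seed), {
    fo <- integer(nrow(units))
    # one fold cycle consumed across (shuffled) classes: fold sizes stay
    # within +/- 1 globally while each class spreads over consecutive folds
    cycle <- rep_len(sample.int(k), nrow(units))
    ord <- if (stratify) {
      unlist(lapply(sort(unique(as.character(units$label))), function(lv) {
        i <- which(units$label == lv)
        i[sample.int(length(i))]
      }))
    } else {
      sample.int(nrow(units))
    }
    fo[ord] <- cycle
    fo
  })
  unit_fold <- setNames(fold_of, units[[unit]])
  sample_fold <- unit_fold[as.character(tab[[unit]])]
  lapply(seq_len(k), function(f) {
    list(train = tab$sample_id[sample_fold != f],
         test = tab$sample_id[sample_fold == f])
  })
}
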
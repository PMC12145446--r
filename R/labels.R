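#' DILI concern classes
#'
#' The three severity classes retained from the DILIrank reference list, in
#' the fixed class order used everywhere in this package:
#' `vNo-DILI-Concern` = 0, `vLess-DILI-Concern` = 1, `vMost-DILI-Concern` = 2.
#' Compounds in the fourth DILIrank category, "Ambiguous DILI concern", lack
#' causality evidence and are rejected at load time rather than mapped to a
#' class.
#'
#' @return Character vector of the three class labels in class-index order.
#' @export
#' @examples
#' dili_levels()
dili_levels <- function() {
  c("vNo-DILI-Concern", "vLess-DILI-Concern", "vMost-DILI-Concern")
}

#' Parse DILI class labels strictly
#'
#' Converts label strings to a factor with the fixed three-level class order.
#' Any string outside the three retained classes is an error; in particular
#' ambiguous-concern labels are rejected explicitly, never silently dropped
#' or remapped.
#'
#' @param x Character vector (or factor) of label strings.
#' @return Factor with levels `dili_levels()`.
#' @export
#' @examples
#' dili_label(c("vNo-DILI-Concern", "vMost-DILI-Concern"))
dili_label <- function(x) {
  x <- as.character(x)
  lv <- dili_levels()
  bad <- !(x %in% lv)
  if (any(bad)) {
    offender <- unique(x[bad])[1]
    if (grepl("ambiguous", offender, ignore.case = TRUE)) {
      stopf(paste0(
        "label '%s' (row %d): the Ambiguous-DILI-Concern category lacks ",
        "causality evidence and is excluded; remove these rows before loading"
      ), offender, which(bad)[1])
    }
    stopf("unknown DILI label '%s' (row %d); expected one of: %s",
          offender, which(bad)[1], paste(lv, collapse = ", "))
  }
  factor(x, levels = lv)
}

#' Class index of a DILI label
#'
#' @param x Labels accepted by [dili_label()].
#' @return Integer vector, 0-based class indices (vNo = 0, vLess = 1,
#'   vMost = 2).
#' @export
dili_class_index <- function(x) as.integer(dili_label(x)) - 1L
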
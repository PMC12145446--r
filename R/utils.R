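# Internal helpers shared across modules.

# Draw n sub-seeds reproducibly from a master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated-normal initialisation (values resampled outside +/- 2 sd),
# the standard ViT weight init.
trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, sd = sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), sd = sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

tn_mat <- function(nr, nc, sd = 0.02) matrix(trunc_normal(nr * nc, sd), nr, nc)

# Recursively apply f to every array leaf of a (possibly nested) list,
# optionally pairing with a second tree of identical shape.
tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) {
      tree_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    })
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

tree_zero <- function(p) tree_map(function(x) x * 0, p)

tree_add <- function(a, b) tree_map(`+`, a, b)

tree_scale <- function(a, s) tree_map(function(x) x * s, a)

# Collect every leaf into a flat named list ("a$b$c" names), for gradient
# checks and bookkeeping.
tree_flatten <- function(p, prefix = "") {
  if (!is.list(p)) return(setNames(list(p), prefix))
  out <- list()
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste0(prefix, "$", nm)
    out <- c(out, tree_flatten(p[[nm]], key))
  }
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
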
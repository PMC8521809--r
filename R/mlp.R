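# Minimal fully connected network engine: ReLU hidden layers, linear output,
# analytic backprop, Adam. Shared by the dynamics model and the DDPG networks.

#' Initialize a fully connected network
#'
#' Creates weight matrices and bias vectors for a multilayer perceptron with
#' rectified-linear hidden layers and a linear output layer. Weights use
#' He-scaled Gaussian initialization; biases start at zero.
#'
#' @param sizes Integer vector of layer widths, input first, output last
#'   (e.g. `c(16, 64, 64, 14)` for two hidden layers).
#' @param seed Integer seed controlling the random initialization.
#' @return An object of class `sedrl_mlp` holding `W` (list of matrices),
#'   `b` (list of row vectors) and `sizes`.
#' @export
mlp_init <- function(sizes, seed = 1L) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                     nrow = fan_in, ncol = sizes[l + 1L])
    b[[l]] <- matrix(0, nrow = 1L, ncol = sizes[l + 1L])
  }
  structure(list(W = W, b = b, sizes = as.integer(sizes)),
            class = "sedrl_mlp")
}

#' Forward pass through a network
#'
#' @param net A `sedrl_mlp`.
#' @param X Numeric matrix, one row per sample, `net$sizes[1]` columns.
#' @param keep_cache Keep layer activations for a subsequent backward pass.
#' @return If `keep_cache = FALSE`, the output matrix. Otherwise a list with
#'   `out` and `cache` (pre-activations and activations per layer).
#' @export
mlp_forward <- function(net, X, keep_cache = FALSE) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  stopifnot(ncol(X) == net$sizes[1L])
  L <- length(net$W)
  A <- X
  As <- if (keep_cache) vector("list", L + 1L) else NULL
  Zs <- if (keep_cache) vector("list", L) else NULL
  if (keep_cache) As[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))  # row-broadcast bias
    A <- if (l < L) pmax(Z, 0) else Z   # ReLU hidden, linear output
    if (keep_cache) { Zs[[l]] <- Z; As[[l + 1L]] <- A }
  }
  if (!keep_cache) return(A)
  list(out = A, cache = list(As = As, Zs = Zs))
}

#' Backward pass: gradients of a scalar loss
#'
#' Backpropagates `dOut`, the gradient of the loss with respect to the network
#' output, through the cached forward pass.
#'
#' @param net A `sedrl_mlp`.
#' @param cache Cache from `mlp_forward(..., keep_cache = TRUE)`.
#' @param dOut Matrix of the same shape as the forward output.
#' @return List with `dW`, `db` (same shapes as `net$W`, `net$b`) and `dX`,
#'   the gradient with respect to the network input (used for the
#'   deterministic policy gradient through the critic's action input).
#' @export
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (cache$Zs[[l]] > 0)
    dW[[l]] <- crossprod(cache$As[[l]], delta)
    db[[l]] <- matrix(colSums(delta), nrow = 1L)
    delta <- delta %*% t(net$W[[l]])
  }
  list(dW = dW, db = db, dX = delta)
}

# Adam optimizer state for one network. `weight_decay` is decoupled
# (AdamW-style): weights shrink by lr * weight_decay per step, biases never.
adam_init <- function(net, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  zeros <- function(p) lapply(p, function(m) m * 0)
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       weight_decay = weight_decay,
       mW = zeros(net$W), vW = zeros(net$W),
       mb = zeros(net$b), vb = zeros(net$b))
}

# One Adam step; returns list(net, opt). `sign` = -1 descends, +1 ascends.
adam_step <- function(net, opt, grads, sign = -1) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  wd <- 1 - opt$lr * opt$weight_decay
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- b1 * opt$mW[[l]] + (1 - b1) * grads$dW[[l]]
    opt$vW[[l]] <- b2 * opt$vW[[l]] + (1 - b2) * grads$dW[[l]]^2
    net$W[[l]] <- wd * net$W[[l]] + sign * opt$lr *
      (opt$mW[[l]] / corr1) / (sqrt(opt$vW[[l]] / corr2) + opt$eps)
    opt$mb[[l]] <- b1 * opt$mb[[l]] + (1 - b1) * grads$db[[l]]
    opt$vb[[l]] <- b2 * opt$vb[[l]] + (1 - b2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] + sign * opt$lr *
      (opt$mb[[l]] / corr1) / (sqrt(opt$vb[[l]] / corr2) + opt$eps)
  }
  list(net = net, opt = opt)
}

#' Train a network by minibatch mean-squared-error regression
#'
#' @param X,Y Training input/target matrices (rows are samples).
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Seed for initialization and batch shuffling.
#' @param X_val,Y_val Optional validation pairs; per-epoch validation MSE is
#'   recorded when given.
#' @param weight_decay Decoupled L2 weight decay per Adam step.
#' @return List with the trained `net`, `train_loss` and `val_loss` vectors
#'   (per-epoch MSE).
#' @export
mlp_fit <- function(X, Y, hidden = c(64L, 64L), epochs = 100L,
                    batch_size = 64L, lr = 1e-3, seed = 1L,
                    X_val = NULL, Y_val = NULL, weight_decay = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1)
  net <- mlp_init(c(ncol(X), hidden, ncol(Y)), seed = seed)
  opt <- adam_init(net, lr = lr, weight_decay = weight_decay)
  n <- nrow(X)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) + 1L)
  train_loss <- numeric(epochs)
  val_loss <- if (is.null(X_val)) NULL else numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- mlp_forward(net, X[idx, , drop = FALSE], keep_cache = TRUE)
      err <- fw$out - Y[idx, , drop = FALSE]
      if (!all(is.finite(err)))
        stop("training diverged: non-finite loss at epoch ", ep)
      tot <- tot + sum(err^2)
      dOut <- 2 * err / length(err)
      gr <- mlp_backward(net, fw$cache, dOut)
      st <- adam_step(net, opt, gr, sign = -1)
      net <- st$net; opt <- st$opt
    }
    train_loss[ep] <- tot / (n * ncol(Y))
    if (!is.null(X_val)) {
      pv <- mlp_forward(net, X_val)
      val_loss[ep] <- mean((pv - Y_val)^2)
    }
  }
  list(net = net, train_loss = train_loss, val_loss = val_loss)
}
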
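# Prioritized experience replay: transitions sampled with probability
# proportional to priority^alpha, corrected by importance weights with
# exponent beta; FIFO eviction once full.

#' Create a prioritized replay buffer
#'
#' @param capacity Maximum number of stored transitions.
#' @param state_dim,action_dim Dimensions of states and actions.
#' @param eps Priority floor: priorities are kept strictly positive.
#' @return An environment of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity, state_dim = 14L, action_dim = 2L,
                          eps = 1e-3) {
  stopifnot(capacity >= 1, eps > 0)
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$S <- matrix(NA_real_, capacity, state_dim)
  buf$A <- matrix(NA_real_, capacity, action_dim)
  buf$R <- rep(NA_real_, capacity)
  buf$S2 <- matrix(NA_real_, capacity, state_dim)
  buf$prio <- rep(NA_real_, capacity)
  buf$size <- 0L
  buf$pos <- 1L
  buf$eps <- eps
  class(buf) <- "replay_buffer"
  buf
}

#' @rdname replay_buffer
#' @param buf A `replay_buffer`.
#' @export
buffer_size <- function(buf) buf$size

#' Add transitions to the buffer
#'
#' New records enter with the current maximum priority (1 for an empty
#' buffer) so they are replayed at least once; the oldest records are
#' evicted first when the buffer is full.
#'
#' @param buf A `replay_buffer`.
#' @param s,a,s2 State, action and next-state (vectors, or matrices for a
#'   batch of rows).
#' @param r Reward(s).
#' @param priority Optional explicit priority (recycled); strictly positive.
#' @return The buffer, invisibly (modified in place).
#' @export
buffer_add <- function(buf, s, a, r, s2, priority = NULL) {
  if (is.vector(s)) s <- matrix(s, nrow = 1L)
  if (is.vector(a)) a <- matrix(a, nrow = 1L)
  if (is.vector(s2)) s2 <- matrix(s2, nrow = 1L)
  n <- nrow(s)
  stopifnot(nrow(a) == n, nrow(s2) == n, length(r) == n)
  if (is.null(priority)) {
    priority <- if (buf$size == 0L) 1 else max(buf$prio[seq_len(buf$size)])
  }
  priority <- pmax(rep_len(priority, n), buf$eps)
  if (n > buf$capacity) {       # only the newest `capacity` records survive
    keep <- (n - buf$capacity + 1L):n
    s <- s[keep, , drop = FALSE]; a <- a[keep, , drop = FALSE]
    s2 <- s2[keep, , drop = FALSE]; r <- r[keep]; priority <- priority[keep]
    n <- buf$capacity
  }
  idx <- (buf$pos - 1L + seq_len(n) - 1L) %% buf$capacity + 1L
  buf$S[idx, ] <- s; buf$A[idx, ] <- a
  buf$R[idx] <- r; buf$S2[idx, ] <- s2
  buf$prio[idx] <- priority
  buf$pos <- (buf$pos - 1L + n) %% buf$capacity + 1L
  buf$size <- min(buf$size + n, buf$capacity)
  invisible(buf)
}

#' Sample a prioritized batch
#'
#' Record `i` is drawn with probability `p_i^alpha / sum_j p_j^alpha`;
#' importance weights are `(N P(i))^-beta`, normalized by the maximum weight
#' over the buffer.
#'
#' @param buf A non-empty `replay_buffer`.
#' @param n Batch size (<= current size; sampling is with replacement).
#' @param alpha Prioritization exponent (0 = uniform).
#' @param beta Importance-correction exponent.
#' @return List with `idx`, `S`, `A`, `R`, `S2`, `weights`.
#' @export
buffer_sample <- function(buf, n, alpha = 0.6, beta = 0.4) {
  if (buf$size == 0L) stop("cannot sample from an empty buffer")
  if (n > buf$size) stop("batch size exceeds buffer size")
  sz <- buf$size
  p <- buf$prio[seq_len(sz)]^alpha
  P <- p / sum(p)
  idx <- sample.int(sz, n, replace = TRUE, prob = P)
  w <- (sz * P[idx])^(-beta)
  w_max <- (sz * min(P))^(-beta)
  list(idx = idx,
       S = buf$S[idx, , drop = FALSE], A = buf$A[idx, , drop = FALSE],
       R = buf$R[idx], S2 = buf$S2[idx, , drop = FALSE],
       weights = w / w_max)
}

#' Update priorities after a TD pass
#'
#' @param buf A `replay_buffer`.
#' @param idx Indices from [buffer_sample()].
#' @param priority New priorities (floored at `eps`, so strictly positive).
#' @return The buffer, invisibly.
#' @export
buffer_update_priorities <- function(buf, idx, priority) {
  stopifnot(length(idx) == length(priority), all(idx <= buf$size))
  buf$prio[idx] <- pmax(abs(priority), buf$eps)
  invisible(buf)
}
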
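# Learned one-step transition model s_{t+1} = f(s_t, a_t) for counterfactual
# rollouts of a dosing policy.

#' Dynamics model configuration
#'
#' Three fully connected layers (two rectified-linear hidden layers, linear
#' output of width 14), trained with Adam on mean squared one-step prediction
#' error. The model predicts the state increment internally and adds it back,
#' which stabilizes learning for slowly varying vitals.
#'
#' @param hidden Widths of the two hidden layers.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled L2 weight decay per Adam step — one-step
#'   targets carry substantial process noise, so some capacity control
#'   prevents the network from memorizing it.
#' @param batch_norm Reserved flag; minibatch standardization is off by
#'   default because inputs are already z-normalized (see vignette).
#' @param seed Seed for initialization and shuffling.
#' @return List of class `dynamics_config`.
#' @export
dynamics_config <- function(hidden = c(64L, 64L), epochs = 60L,
                            batch_size = 64L, lr = 1e-3,
                            weight_decay = 0.05,
                            batch_norm = FALSE, seed = 1L) {
  stopifnot(length(hidden) == 2, all(hidden >= 1), epochs >= 1,
            weight_decay >= 0)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 batch_norm = isTRUE(batch_norm), seed = as.integer(seed)),
            class = "dynamics_config")
}

#' Pair consecutive windows into a transition dataset
#'
#' For every patient with `T` windows, emits the `T - 1` pairs
#' `(s_t, a_t) -> s_{t+1}`; pairs never cross patients, and single-window
#' trajectories contribute none.
#'
#' @param trajectories List of (normalized) `patient_trajectory` objects.
#' @return List of class `transition_dataset`: `X` (n x 16: state and
#'   action), `Y` (n x 14: next state), `subject`, `sas_next`, `map_next`
#'   (raw arrival-window values, for readouts and rewards).
#' @export
build_transition_dataset <- function(trajectories) {
  keep <- vapply(trajectories, function(tr) tr$icu_duration_h >= 2, logical(1))
  trajectories <- trajectories[keep]
  if (!length(trajectories)) stop("no trajectory has 2 or more windows")
  parts <- lapply(trajectories, function(tr) {
    t_idx <- seq_len(tr$icu_duration_h - 1L)
    list(X = cbind(tr$state[t_idx, , drop = FALSE],
                   propofol = tr$propofol[t_idx],
                   fentanyl = tr$fentanyl[t_idx]),
         Y = tr$state[t_idx + 1L, , drop = FALSE],
         subject = rep(tr$subject_id, length(t_idx)),
         sas_next = tr$sas[t_idx + 1L],
         map_next = tr$map[t_idx + 1L])
  })
  structure(list(X = do.call(rbind, lapply(parts, `[[`, "X")),
                 Y = do.call(rbind, lapply(parts, `[[`, "Y")),
                 subject = unlist(lapply(parts, `[[`, "subject")),
                 sas_next = unlist(lapply(parts, `[[`, "sas_next")),
                 map_next = unlist(lapply(parts, `[[`, "map_next"))),
            class = "transition_dataset")
}

#' Fit the next-state dynamics model
#'
#' Minimizes mean squared one-step prediction error over training pairs.
#' Doses are standardized internally by their training standard deviation so
#' that both input blocks are on comparable scales. A linear SAS readout
#' (next state -> SAS) is fit alongside so that rollouts can report a
#' sedation estimate (SAS is not itself a state feature).
#'
#' @param dataset A `transition_dataset` (training pairs only).
#' @param config A [dynamics_config()].
#' @param val_dataset Optional held-out `transition_dataset` for a
#'   validation loss curve.
#' @return Object of class `sedrl_dynamics` with the network, scalings,
#'   loss curves and the SAS readout coefficients.
#' @export
fit_dynamics <- function(dataset, config = dynamics_config(),
                         val_dataset = NULL) {
  stopifnot(inherits(dataset, "transition_dataset"))
  n_feat <- ncol(dataset$Y)
  a_cols <- (n_feat + 1L):ncol(dataset$X)
  a_scale <- apply(dataset$X[, a_cols, drop = FALSE], 2L, stats::sd)
  a_scale[!is.finite(a_scale) | a_scale < 1e-8] <- 1
  scale_X <- function(X) {
    X[, a_cols] <- sweep(X[, a_cols, drop = FALSE], 2L, a_scale, "/")
    X
  }
  Xs <- scale_X(dataset$X)
  D <- dataset$Y - dataset$X[, seq_len(n_feat), drop = FALSE]  # state delta
  # standardize deltas per feature: quiet features (age, gender, slow
  # vitals) then shrink back to near-zero predicted change
  d_center <- colMeans(D)
  d_scale <- pmax(apply(D, 2L, stats::sd), 1e-6)
  D <- sweep(sweep(D, 2L, d_center), 2L, d_scale, "/")
  Xv <- Dv <- NULL
  if (!is.null(val_dataset)) {
    Xv <- scale_X(val_dataset$X)
    Dv <- val_dataset$Y - val_dataset$X[, seq_len(n_feat), drop = FALSE]
    Dv <- sweep(sweep(Dv, 2L, d_center), 2L, d_scale, "/")
  }
  fit <- mlp_fit(Xs, D, hidden = config$hidden, epochs = config$epochs,
                 batch_size = config$batch_size, lr = config$lr,
                 seed = config$seed, X_val = Xv, Y_val = Dv,
                 weight_decay = config$weight_decay)
  # linear readout for the sedation estimate during model rollouts
  sas_coef <- NULL
  if (!all(is.na(dataset$sas_next))) {
    Z <- cbind(1, dataset$Y)
    sas_coef <- qr.coef(qr(Z), dataset$sas_next)
    sas_coef[is.na(sas_coef)] <- 0
  }
  structure(list(net = fit$net, a_scale = a_scale, n_feat = n_feat,
                 d_center = d_center, d_scale = d_scale,
                 train_loss = fit$train_loss, val_loss = fit$val_loss,
                 sas_coef = sas_coef, config = config),
            class = "sedrl_dynamics")
}

#' Predict the next state
#'
#' Deterministic single-step prediction in inference mode.
#'
#' @param model A `sedrl_dynamics`.
#' @param s State matrix (rows) or single state vector (normalized units).
#' @param a Matching action matrix or length-2 vector (raw dose units).
#' @return Next-state matrix with one row per input row.
#' @export
predict_next_state <- function(model, s, a) {
  stopifnot(inherits(model, "sedrl_dynamics"))
  if (is.vector(s)) s <- matrix(s, nrow = 1L)
  if (is.vector(a)) a <- matrix(a, nrow = 1L)
  if (ncol(s) != model$n_feat || ncol(a) != length(model$a_scale) ||
      nrow(s) != nrow(a))
    stop("state/action shape mismatch")
  if (!all(is.finite(s)) || !all(is.finite(a)))
    stop("non-finite state or action")
  X <- cbind(s, sweep(a, 2L, model$a_scale, "/"))
  D <- mlp_forward(model$net, X)
  if (!is.null(model$d_scale))
    D <- sweep(sweep(D, 2L, model$d_scale, "*"), 2L, model$d_center, "+")
  s + D
}

#' Roll a policy out through the learned dynamics
#'
#' Iterates `a_t = policy(s_t)`, `s_{t+1} = f(s_t, a_t)`, recording the
#' de-normalized MAP (a state feature) and the linear-readout SAS estimate
#' per step. Truncates with a flag if a non-finite state is produced.
#'
#' @param model A `sedrl_dynamics`.
#' @param policy Function: 1 x 14 normalized state matrix -> length-2 dose.
#' @param s0 Initial normalized state vector.
#' @param horizon Number of steps (>= 1).
#' @param stats `normalization_stats` for de-normalizing MAP.
#' @return List with `states` ((horizon+1) x 14), `actions` (horizon x 2),
#'   `sas`, `map` (length horizon, arrival windows), `truncated`.
#' @export
rollout <- function(model, policy, s0, horizon, stats = NULL) {
  stopifnot(horizon >= 1)
  n_feat <- model$n_feat
  states <- matrix(NA_real_, horizon + 1L, n_feat)
  actions <- matrix(NA_real_, horizon, length(model$a_scale))
  sas <- map <- rep(NA_real_, horizon)
  states[1L, ] <- s0
  truncated <- FALSE
  for (t in seq_len(horizon)) {
    s <- states[t, , drop = FALSE]
    a <- pmax(as.numeric(policy(s)), 0)
    actions[t, ] <- a
    s2 <- predict_next_state(model, s, matrix(a, nrow = 1L))
    if (!all(is.finite(s2))) { truncated <- TRUE; break }
    states[t + 1L, ] <- s2
    if (!is.null(stats)) {
      raw <- denormalize_state(s2, stats)
      map[t] <- raw[1L, which(sedrl_features() == "map")]
    }
    if (!is.null(model$sas_coef))
      sas[t] <- min(max(sum(c(1, s2) * model$sas_coef), 1), 7)
  }
  list(states = states, actions = actions, sas = sas, map = map,
       truncated = truncated)
}
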
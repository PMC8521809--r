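# Four-network DDPG learner (actor, critic, and their slowly tracking
# targets) with prioritized experience replay, producing a continuous
# two-drug dosing policy.

#' DDPG agent configuration
#'
#' The discount defaults to `1e-3` as published for this dosing problem
#' (validation-tuned there; effectively myopic — see the vignette). All other
#' values are standard DDPG/PER defaults; none beyond the discount are
#' stated by the source analysis.
#'
#' @param gamma Discount factor in \[0, 1\].
#' @param actor_hidden,critic_hidden Hidden-layer widths.
#' @param actor_lr,critic_lr Adam learning rates.
#' @param tau Soft-update coefficient for the target networks.
#' @param noise_sigma,noise_sigma_final Gaussian exploration-noise scale
#'   (fraction of `dose_max`), decayed linearly over training; only used in
#'   model-based mode (offline replay needs no exploration).
#' @param buffer_capacity Replay capacity.
#' @param batch_size Minibatch size.
#' @param per_alpha Prioritization exponent.
#' @param per_beta0,per_beta_final Importance exponent, annealed linearly.
#' @param per_eps Priority floor added to |TD error|.
#' @param n_steps Number of gradient-update steps.
#' @param critic_warmup Steps of critic-only training before the first actor
#'   update (the policy gradient is only as good as the value surface it
#'   differentiates).
#' @param critic_updates Critic TD passes per step (the actor updates once).
#' @param n_critics Size of the critic ensemble: independently initialized
#'   critics trained on the shared batch; the actor ascends their mean
#'   value surface, averaging out per-critic fitting noise, and priorities
#'   use the mean |TD error|.
#' @param critic_weight_decay Decoupled L2 weight decay on the critic —
#'   regularizes the value surface against memorizing gate noise in the
#'   logged rewards.
#' @param lr_decay Decay the actor learning rate linearly to 10% of its
#'   initial value so the policy converges instead of wandering.
#' @param bc_alpha Behavior-cloning regularization of the actor in offline
#'   mode (see [actor_dpg_update()]); 0 disables it. Ignored in model-based
#'   mode, where the critic is trained on the policy's own actions.
#' @param dose_max Length-2 per-drug action bound; `NULL` takes the 99th
#'   percentile of the training doses.
#' @param eval_every Steps between policy-snapshot evaluations when an
#'   `eval_fn` is supplied to [train_agent()].
#' @param log_every Record a training-log row every this many steps.
#' @param seed Master seed for network init and replay sampling.
#' @return List of class `agent_config`.
#' @export
agent_config <- function(gamma = 1e-3,
                         actor_hidden = 8L,
                         critic_hidden = c(64L, 64L),
                         actor_lr = 3e-4, critic_lr = 1e-3,
                         tau = 5e-3,
                         noise_sigma = 0.2, noise_sigma_final = 0.01,
                         buffer_capacity = 1e5L, batch_size = 64L,
                         per_alpha = 0.6, per_beta0 = 0.4,
                         per_beta_final = 1, per_eps = 1e-3,
                         n_steps = 30000L, critic_warmup = 2000L,
                         critic_updates = 1L, n_critics = 2L,
                         critic_weight_decay = 0.01,
                         lr_decay = TRUE, bc_alpha = 2.5, dose_max = NULL,
                         eval_every = 2000L,
                         log_every = 500L, seed = 1L) {
  stopifnot(gamma >= 0, gamma <= 1, per_alpha >= 0, per_beta0 >= 0,
            buffer_capacity >= batch_size, tau >= 0, tau <= 1, n_steps >= 1,
            critic_warmup >= 0, critic_updates >= 1)
  structure(as.list(environment()), class = "agent_config")
}

# --- actor ----------------------------------------------------------------

# The actor outputs an unbounded 2-vector clipped to [0, dose_max] per drug.
# Clipping (rather than a saturating squash) keeps the deterministic policy
# gradient alive at the bounds via gradient inversion: at a bound, gradient
# components pointing back into the feasible dose range still pass.
actor_forward <- function(actor, S, keep_cache = FALSE) {
  fw <- mlp_forward(actor$net, S, keep_cache = keep_cache)
  z <- if (keep_cache) fw$out else fw
  A <- pmin(pmax(z, 0), rep(actor$dose_max, each = nrow(z)))
  if (!keep_cache) return(A)
  list(A = A, z = z, cache = fw$cache)
}

#' Select a dose action
#'
#' Deterministic actor output, optionally perturbed by Gaussian exploration
#' noise, clipped to `[0, dose_max]` per drug. With `noise_sd = 0`
#' (evaluation mode) the action is a deterministic function of the state.
#'
#' @param actor Actor component of a trained/initializing agent (an object
#'   with `net` and `dose_max`).
#' @param s State vector or 1-row matrix (normalized units).
#' @param noise_sd Exploration noise SD in dose units (0 = evaluation).
#' @return Length-2 non-negative dose vector.
#' @export
select_action <- function(actor, s, noise_sd = 0) {
  a <- as.numeric(actor_forward(actor, s))
  if (noise_sd > 0) a <- a + stats::rnorm(length(a), 0, noise_sd)
  pmin(pmax(a, 0), actor$dose_max)
}

# --- critic ---------------------------------------------------------------

critic_input <- function(critic, S, A) {
  cbind(S, A / rep(critic$dose_max, each = nrow(A)))
}

#' Critic value estimate Q(s, a)
#'
#' @param critic Critic component (an object with `net` and `dose_max`).
#' @param S,A State and action matrices (rows aligned).
#' @return Numeric vector of Q values.
#' @export
critic_q <- function(critic, S, A) {
  as.numeric(mlp_forward(critic$net, critic_input(critic, S, A)))
}

#' One prioritized TD update of the critic
#'
#' Bootstrapped targets `y = r + gamma * Q'(s', pi'(s'))` from the target
#' networks; the loss is the importance-weighted mean squared TD error, and
#' refreshed priorities are `|TD| + per_eps`.
#'
#' @param critic,critic_opt Critic and its Adam state.
#' @param target_critic,target_actor Target networks.
#' @param batch A batch from [buffer_sample()].
#' @param gamma Discount factor.
#' @param per_eps Priority floor.
#' @return List: updated `critic`, `opt`, scalar `loss`, `td` errors,
#'   `priorities`, and the `targets` y.
#' @export
critic_td_update <- function(critic, critic_opt, target_critic, target_actor,
                             batch, gamma, per_eps = 1e-3) {
  A2 <- actor_forward(target_actor, batch$S2)
  q2 <- critic_q(target_critic, batch$S2, A2)
  y <- batch$R + gamma * q2
  fw <- mlp_forward(critic$net, critic_input(critic, batch$S, batch$A),
                    keep_cache = TRUE)
  td <- as.numeric(fw$out) - y
  w <- batch$weights
  loss <- mean(w * td^2)
  if (!is.finite(loss)) stop("critic TD loss is not finite")
  n <- length(td)
  dOut <- matrix(2 * w * td / n, ncol = 1L)
  gr <- mlp_backward(critic$net, fw$cache, dOut)
  st <- adam_step(critic$net, critic_opt, gr, sign = -1)
  critic$net <- st$net
  list(critic = critic, opt = st$opt, loss = loss, td = td,
       priorities = abs(td) + per_eps, targets = y)
}

#' One deterministic-policy-gradient update of the actor
#'
#' Ascends the gradient of `mean(Q(s, pi(s)))` over the batch states,
#' differentiating the critic with respect to its action input and chaining
#' through the actor's squashed output. In offline training a
#' behavior-cloning regularizer keeps the policy near the logged actions,
#' where the critic is trustworthy: the objective becomes
#' `lambda * mean(Q) - mean((pi(s) - a_logged)^2)` with
#' `lambda = bc_alpha / mean(|Q|)`, the standard minimalist remedy for
#' off-support value extrapolation in offline actor--critic learning.
#'
#' @param actor,actor_opt Actor and its Adam state.
#' @param critic Either a `sedrl_critic`-style object (with `net`) or, for
#'   analysis, a list of class `critic_fn` with elements `q(S, A)` and
#'   `grad(S, A)` giving the action gradient directly.
#' @param S Batch state matrix.
#' @param A_logged Logged actions for the batch (behavior-cloning anchor);
#'   `NULL` disables the regularizer.
#' @param bc_alpha Relative weight of the value term against the cloning
#'   term (0 disables cloning even when `A_logged` is given).
#' @return List: updated `actor`, `opt`, and the scalar `objective`
#'   (mean Q before the update).
#' @export
actor_dpg_update <- function(actor, actor_opt, critic, S,
                             A_logged = NULL, bc_alpha = 0) {
  af <- actor_forward(actor, S, keep_cache = TRUE)
  n <- nrow(S)
  if (inherits(critic, "critic_fn")) {
    q <- critic$q(S, af$A)
    objective <- mean(q)
    dObjdA <- critic$grad(S, af$A) / n
  } else {
    # a single critic or an ensemble; the actor ascends the mean value
    # surface, whose action-gradient averages out per-critic fitting noise
    critics <- if (inherits(critic, "sedrl_critic")) list(critic) else critic
    q <- 0
    dObjdA <- 0
    for (cr in critics) {
      cf <- mlp_forward(cr$net, critic_input(cr, S, af$A),
                        keep_cache = TRUE)
      q <- q + as.numeric(cf$out) / length(critics)
      cb <- mlp_backward(cr$net, cf$cache, matrix(1 / n, n, 1L))
      a_cols <- ncol(S) + seq_along(actor$dose_max)
      dObjdA <- dObjdA +
        sweep(cb$dX[, a_cols, drop = FALSE], 2L, cr$dose_max, "/") /
        length(critics)
    }
    objective <- mean(q)
  }
  if (!is.finite(objective)) stop("actor objective is not finite")
  if (!is.null(A_logged) && bc_alpha > 0) {
    # normalize dose residuals by the action bound so both drugs count alike
    resid <- sweep(af$A - A_logged, 2L, actor$dose_max, "/")
    lambda <- bc_alpha / mean(abs(q))
    dObjdA <- lambda * dObjdA -
      sweep(2 * resid / n, 2L, actor$dose_max, "/")
  }
  # clipped output: inside the range the gradient passes unchanged; at a
  # bound only components pointing back into [0, dose_max] pass (inversion)
  dmax <- matrix(actor$dose_max, nrow(af$z), ncol(af$z), byrow = TRUE)
  pass <- (af$z > 0 & af$z < dmax) |
    (af$z <= 0 & dObjdA > 0) | (af$z >= dmax & dObjdA < 0)
  dz <- dObjdA * pass
  gr <- mlp_backward(actor$net, af$cache, dz)
  st <- adam_step(actor$net, actor_opt, gr, sign = +1)
  actor$net <- st$net
  list(actor = actor, opt = st$opt, objective = objective)
}

#' Soft target-network update
#'
#' `theta_target <- coeff * theta_online + (1 - coeff) * theta_target`,
#' elementwise, so targets slowly track the learned networks.
#'
#' @param target,online `sedrl_mlp` networks of matching shape.
#' @param coeff Mixing coefficient in \[0, 1\].
#' @return The updated target network.
#' @export
soft_update <- function(target, online, coeff) {
  stopifnot(identical(target$sizes, online$sizes), coeff >= 0, coeff <= 1)
  for (l in seq_along(target$W)) {
    target$W[[l]] <- coeff * online$W[[l]] + (1 - coeff) * target$W[[l]]
    target$b[[l]] <- coeff * online$b[[l]] + (1 - coeff) * target$b[[l]]
  }
  target
}

# --- offline transition construction --------------------------------------

#' Build logged transitions with rewards from a preprocessed cohort
#'
#' Pairs consecutive windows of each trajectory into `(s_t, a_t, r_t,
#' s_{t+1})` tuples. The reward for taking `a_t` is observed at the arrival
#' window: band rewards of `SAS_{t+1}` and `MAP_{t+1}` minus the dose
#' penalty on `a_t`, gated on strict improvement of the combined band error
#' from window `t` to `t + 1` (see the vignette for this credit-assignment
#' convention).
#'
#' @param cohort A `sedrl_cohort`.
#' @param reward_cfg A [reward_config()].
#' @param ids Subject ids to include; defaults to the training split.
#' @return List with matrices `S`, `A`, `S2`, vector `R`, and `subject`.
#' @export
build_offline_transitions <- function(cohort, reward_cfg = reward_config(),
                                      ids = NULL) {
  stopifnot(inherits(cohort, "sedrl_cohort"))
  if (is.null(ids)) ids <- cohort$split$train_ids
  trs <- cohort$trajectories[as.character(ids)]
  trs <- trs[vapply(trs, function(tr) tr$icu_duration_h >= 2, logical(1))]
  if (!length(trs)) stop("no trajectory has 2 or more windows")
  parts <- lapply(trs, function(tr) {
    Tn <- tr$icu_duration_h
    d_map <- deviation(tr$map, reward_cfg$map_ltb, reward_cfg$map_utb)
    d_sas <- deviation(tr$sas, reward_cfg$sas_ltb, reward_cfg$sas_utb)
    err <- window_error(d_map, d_sas, signed = reward_cfg$signed_error)
    rm_ <- r_map(tr$map, reward_cfg)
    rs_ <- r_sas(tr$sas, reward_cfg)
    t_idx <- seq_len(Tn - 1L)
    dose <- tr$propofol[t_idx] + tr$fentanyl[t_idx]
    r <- rs_[t_idx + 1L] + rm_[t_idx + 1L] - reward_cfg$dose_penalty * dose
    if (reward_cfg$gate_on_improvement) {
      gate <- err[t_idx + 1L] < err[t_idx]
      if (isTRUE(reward_cfg$gate_zero_pass))
        gate <- gate | err[t_idx + 1L] == 0
      r <- ifelse(gate, r, 0)
    }
    list(S = tr$state[t_idx, , drop = FALSE],
         A = cbind(tr$propofol[t_idx], tr$fentanyl[t_idx]),
         R = r,
         S2 = tr$state[t_idx + 1L, , drop = FALSE],
         subject = rep(tr$subject_id, Tn - 1L))
  })
  list(S = do.call(rbind, lapply(parts, `[[`, "S")),
       A = do.call(rbind, lapply(parts, `[[`, "A")),
       R = unlist(lapply(parts, `[[`, "R")),
       S2 = do.call(rbind, lapply(parts, `[[`, "S2")),
       subject = unlist(lapply(parts, `[[`, "subject")))
}

# --- training loop --------------------------------------------------------

#' Train the DDPG dosing agent
#'
#' Offline mode (default) seeds the replay buffer exclusively with logged
#' clinician transitions and never queries any dynamics model. Model-based
#' mode interacts with an environment (e.g. [synthetic_env()]) under
#' decaying Gaussian exploration noise while updating from the same
#' prioritized replay. Both run the step loop: sample a prioritized batch,
#' TD-update the critic, refresh priorities, policy-gradient-update the
#' actor, soft-update both targets.
#'
#' @param data A `sedrl_cohort` (offline mode) or an environment object with
#'   `reset()` and `step(a)` (model-based mode).
#' @param config An [agent_config()].
#' @param reward_cfg A [reward_config()] (used to build offline rewards).
#' @param mode `"offline"` or `"model_based"`.
#' @param eval_fn Optional policy scorer (function taking a policy function,
#'   returning a scalar, higher better) — typically counterfactual rollouts
#'   on the validation subjects. When given, the stabilized (target) policy
#'   is scored every `eval_every` steps under a fixed evaluation seed
#'   (common random numbers across snapshots) and the best-scoring snapshot
#'   is returned, the policy-learning analog of validation early stopping.
#' @return Object of class `ddpg_agent`: `actor`, `critic`, target networks,
#'   `dose_max`, `config`, a training `log` data.frame, and (when `eval_fn`
#'   is used) `snapshots`, the per-evaluation scores.
#' @export
train_agent <- function(data, config = agent_config(),
                        reward_cfg = reward_config(),
                        mode = c("offline", "model_based"),
                        eval_fn = NULL) {
  mode <- match.arg(mode)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  state_dim <- 14L
  if (mode == "offline") {
    trans <- build_offline_transitions(data, reward_cfg)
    n_tr <- nrow(trans$S)
    state_dim <- ncol(trans$S)
    dose_max <- config$dose_max
    if (is.null(dose_max))
      dose_max <- pmax(apply(trans$A, 2L, stats::quantile, probs = 0.99), 0.1)
    # offline: the buffer holds exactly the logged transitions
    buf <- replay_buffer(min(max(n_tr, config$batch_size),
                             config$buffer_capacity),
                         state_dim, 2L, eps = config$per_eps)
    buffer_add(buf, trans$S, trans$A, trans$R, trans$S2, priority = 1)
  } else {
    if (!is.list(data) || is.null(data$reset) || is.null(data$step))
      stop("model_based mode needs an environment with reset() and step()")
    dose_max <- config$dose_max
    if (is.null(dose_max)) dose_max <- c(5, 3)
    buf <- replay_buffer(config$buffer_capacity, state_dim, 2L,
                         eps = config$per_eps)
  }
  dose_max <- rep_len(dose_max, 2L)

  actor_net <- mlp_init(c(state_dim, config$actor_hidden, 2L),
                        seed = config$seed)
  # warm-start the policy at the behavior policy's mean dosing rate
  # (offline mode); mid-range otherwise
  init_dose <- if (mode == "offline") colMeans(trans$A) else dose_max / 2
  actor_net$b[[length(actor_net$b)]] <- matrix(init_dose, nrow = 1L)
  actor <- structure(list(net = actor_net, dose_max = dose_max),
                     class = "sedrl_actor")
  n_critics <- config$n_critics
  critics <- lapply(seq_len(n_critics), function(i)
    structure(list(net = mlp_init(c(state_dim + 2L, config$critic_hidden,
                                    1L),
                                  seed = config$seed + i),
                   dose_max = dose_max), class = "sedrl_critic"))
  target_actor <- actor
  target_critics <- critics
  actor_opt <- adam_init(actor$net, lr = config$actor_lr)
  critic_opts <- lapply(critics, function(cr)
    adam_init(cr$net, lr = config$critic_lr,
              weight_decay = config$critic_weight_decay))

  set.seed(config$seed + 2L)
  n_steps <- config$n_steps
  log_rows <- vector("list", ceiling(n_steps / config$log_every))
  li <- 0L
  env_state <- NULL
  snapshots <- NULL
  best_score <- -Inf
  best_actor <- NULL
  score_snapshot <- function(step, target_actor) {
    # fixed evaluation seed: common random numbers across snapshots,
    # and the training RNG stream is left untouched
    rng <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv()))
    set.seed(config$seed + 7L)
    pol <- local({
      a <- target_actor
      function(S) actor_forward(a, S)
    })
    eval_fn(pol)
  }
  for (step in seq_len(n_steps)) {
    frac <- step / n_steps
    if (mode == "model_based") {
      if (is.null(env_state)) env_state <- data$reset()
      sigma <- (config$noise_sigma +
                  frac * (config$noise_sigma_final - config$noise_sigma)) *
        mean(dose_max)
      a <- select_action(actor, env_state, noise_sd = sigma)
      out <- data$step(a)
      buffer_add(buf, env_state, a, out$reward, out$state)
      env_state <- if (isTRUE(out$done)) NULL else out$state
      if (buffer_size(buf) < config$batch_size) next
    }
    beta <- config$per_beta0 +
      frac * (config$per_beta_final - config$per_beta0)
    for (k in seq_len(config$critic_updates)) {
      batch <- buffer_sample(buf, config$batch_size,
                             alpha = config$per_alpha, beta = beta)
      prio <- 0
      loss <- 0
      for (i in seq_len(n_critics)) {
        cu <- critic_td_update(critics[[i]], critic_opts[[i]],
                               target_critics[[i]], target_actor,
                               batch, gamma = config$gamma,
                               per_eps = config$per_eps)
        critics[[i]] <- cu$critic; critic_opts[[i]] <- cu$opt
        prio <- prio + cu$priorities / n_critics
        loss <- loss + cu$loss / n_critics
        target_critics[[i]]$net <- soft_update(target_critics[[i]]$net,
                                               critics[[i]]$net, config$tau)
      }
      buffer_update_priorities(buf, batch$idx, prio)
    }
    if (step > config$critic_warmup) {
      if (config$lr_decay)
        actor_opt$lr <- config$actor_lr * (1 - 0.9 * frac)
      # differentiate the slowly tracking target critics: their value
      # surface is a temporal average, so the policy gradient field the
      # actor follows is far less noisy than the per-step online fits
      au <- actor_dpg_update(actor, actor_opt, target_critics, batch$S,
                             A_logged = if (mode == "offline") batch$A,
                             bc_alpha = config$bc_alpha)
      actor <- au$actor; actor_opt <- au$opt
      target_actor$net <- soft_update(target_actor$net, actor$net,
                                      config$tau)
    } else {
      au <- list(objective = NA_real_)
    }
    if (step %% config$log_every == 0L || step == n_steps) {
      li <- li + 1L
      log_rows[[li]] <- data.frame(step = step, critic_loss = loss,
                                   actor_objective = au$objective,
                                   mean_batch_reward = mean(batch$R))
    }
    if (!is.null(eval_fn) && step > config$critic_warmup &&
        (step %% config$eval_every == 0L || step == n_steps)) {
      sc <- score_snapshot(step, target_actor)
      snapshots <- rbind(snapshots, data.frame(step = step, score = sc))
      if (sc > best_score) {
        best_score <- sc
        best_actor <- target_actor
      }
    }
  }
  if (!is.null(best_actor)) {
    actor <- best_actor
    target_actor <- best_actor
  }
  structure(list(actor = actor, critic = critics[[1L]], critics = critics,
                 target_actor = target_actor,
                 target_critic = target_critics[[1L]],
                 dose_max = dose_max, config = config,
                 reward_config = reward_cfg, mode = mode,
                 log = unique(do.call(rbind, log_rows[seq_len(li)])),
                 snapshots = snapshots),
            class = "ddpg_agent")
}

#' @export
print.ddpg_agent <- function(x, ...) {
  cat("<ddpg_agent>", x$mode, "mode,", max(x$log$step), "steps, dose_max = (",
      paste(signif(x$dose_max, 3), collapse = ", "), ")\n")
  invisible(x)
}

#' Deterministic dosing policy of a trained agent
#'
#' @param agent A `ddpg_agent`.
#' @param use_target Use the target actor — a slow Polyak average of the
#'   online actor over training, i.e. its stabilized version (default).
#' @return Function mapping a normalized state matrix (rows) to a dose
#'   matrix, evaluation mode (no exploration noise).
#' @export
agent_policy <- function(agent, use_target = TRUE) {
  stopifnot(inherits(agent, "ddpg_agent"))
  actor <- if (use_target) agent$target_actor else agent$actor
  function(S) actor_forward(actor, S)
}

#' Predicted doses for a batch of states
#'
#' @param agent A `ddpg_agent`.
#' @param S Normalized state matrix (rows).
#' @return n x 2 dose matrix.
#' @export
predict_doses <- function(agent, S) agent_policy(agent)(S)
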
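# Interactive environment wrapper around the synthetic simulator, for
# model-based agent training.

#' Interactive training environment over the synthetic simulator
#'
#' Wraps a set of synthetic patients as an episodic environment with the
#' standard `reset()` / `step(a)` interface used by [train_agent()] in
#' model-based mode. Rewards follow the same arrival-window convention as
#' the offline transitions: band rewards of the post-action SAS/MAP minus
#' the dose penalty, gated on strict error improvement.
#'
#' @param params_list Named list of `synthetic_patient_params`.
#' @param inits Matching list of initial conditions (`sas`, `map`,
#'   `features`).
#' @param stats `normalization_stats` used to normalize states.
#' @param reward_cfg A [reward_config()].
#' @param horizon Episode length in hours.
#' @param synth_cfg A [synth_config()] (process noise settings).
#' @return List of class `synthetic_env` with functions `reset()` (returns
#'   the initial normalized state of a randomly drawn patient) and `step(a)`
#'   (returns `state`, `reward`, `done`, `sas`, `map`).
#' @export
synthetic_env <- function(params_list, inits, stats,
                          reward_cfg = reward_config(), horizon = 48L,
                          synth_cfg = synth_config()) {
  stopifnot(length(params_list) == length(inits), horizon >= 1)
  e <- new.env(parent = emptyenv())
  norm1 <- function(fv) matrix((fv - stats$mean) / stats$sd, nrow = 1L)
  err_of <- function(sas, map) {
    window_error(deviation(map, reward_cfg$map_ltb, reward_cfg$map_utb),
                 deviation(sas, reward_cfg$sas_ltb, reward_cfg$sas_utb),
                 signed = reward_cfg$signed_error)
  }
  reset <- function() {
    i <- sample.int(length(params_list), 1L)
    e$p <- params_list[[i]]
    e$sas <- inits[[i]]$sas
    e$map <- inits[[i]]$map
    e$fv <- inits[[i]]$features
    e$t <- 0L
    e$err <- err_of(e$sas, e$map)
    norm1(e$fv)
  }
  step <- function(a) {
    a <- pmax(as.numeric(a), 0)
    nx <- step_patient(e$p, e$sas, e$map, a, features = e$fv, noise = TRUE)
    err2 <- err_of(nx$sas, nx$map)
    r <- r_sas(nx$sas, reward_cfg) + r_map(nx$map, reward_cfg) -
      reward_cfg$dose_penalty * sum(a)
    gate <- !reward_cfg$gate_on_improvement || err2 < e$err ||
      (isTRUE(reward_cfg$gate_zero_pass) && err2 == 0)
    if (!gate) r <- 0
    e$sas <- nx$sas; e$map <- nx$map; e$fv <- nx$features
    e$err <- err2
    e$t <- e$t + 1L
    list(state = norm1(e$fv), reward = r, done = e$t >= horizon,
         sas = nx$sas, map = nx$map)
  }
  structure(list(reset = reset, step = step), class = "synthetic_env")
}
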
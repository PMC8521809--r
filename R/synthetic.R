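# Synthetic ICU cohort: mean-reverting SAS/MAP pharmacodynamics with
# patient-specific drug sensitivity, vitals correlated with sedation level,
# and a noisy proportional clinician behavior policy.

#' Synthetic cohort configuration
#'
#' Defaults define the study conditions the generator emulates: agitated
#' unsedated baselines (SAS 4--6), MAP baselines 70--95 mmHg, log-normal
#' interindividual variation of drug sensitivity, a clinician who doses
#' proportionally toward the SAS 3--4 band with dose noise and occasional
#' overdose events, and 5% missingness of recorded features.
#'
#' @param lambda_sas,lambda_map Hourly mean-reversion rates toward the
#'   unsedated baselines.
#' @param k_p_med,k_f_med Median sedative effect (SAS points lowered per
#'   dose unit) of propofol and fentanyl.
#' @param h_p_med Median MAP-lowering effect of propofol (mmHg per unit).
#' @param sens_sdlog Log-scale SD of the patient-specific sensitivity draws.
#' @param sas_noise_sd,map_noise_sd Process noise SDs (SAS points / mmHg).
#' @param maint_prop,maint_fent Clinician maintenance doses inside the band.
#' @param gain_prop,gain_fent Proportional correction per SAS point above 4.
#' @param dose_noise_sd Length-2 dose noise SD (propofol, fentanyl).
#' @param overdose_prob Per-window probability of an overdose event
#'   (dose multiplied by `overdose_factor`), creating the out-of-range
#'   episodes present in logged clinical data.
#' @param overdose_factor Multiplier applied during an overdose event.
#' @param dose_cap Upper clip on generated doses (dataset dose units).
#' @param missingness Per-feature probability that a window's recording is
#'   absent from the raw table.
#' @param sas_missingness Probability that a window's SAS is unrecorded.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(lambda_sas = 0.2, lambda_map = 0.3,
                         k_p_med = 0.03, k_f_med = 0.011, h_p_med = 0.1,
                         sens_sdlog = 0.3,
                         sas_noise_sd = 0.15, map_noise_sd = 2,
                         maint_prop = 6, maint_fent = 4,
                         gain_prop = 12.5, gain_fent = 4.6,
                         dose_noise_sd = c(6, 3.3),
                         overdose_prob = 0.03, overdose_factor = 3,
                         dose_cap = c(50, 20), assess_interval = 3L,
                         hold_noise_sd = c(1.3, 0.7),
                         missingness = 0.05, sas_missingness = 0) {
  stopifnot(lambda_sas > 0, lambda_map > 0, k_p_med > 0, k_f_med > 0,
            h_p_med > 0, gain_prop >= 0, gain_fent >= 0,
            overdose_prob >= 0, overdose_prob <= 1,
            missingness >= 0, missingness < 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Draw one synthetic patient's parameters
#'
#' Baselines are drawn near the magnitudes vitals take at light sedation;
#' drug sensitivities are log-normal across patients, emulating
#' interindividual pharmacokinetic/pharmacodynamic variation.
#'
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @param config A [synth_config()].
#' @return List of class `synthetic_patient_params`.
#' @export
sample_patient <- function(seed = NULL, config = synth_config()) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  p <- list(
    sas_baseline = stats::runif(1, 4, 6),
    map_baseline = stats::runif(1, 70, 95),
    k_p = stats::rlnorm(1, log(config$k_p_med), config$sens_sdlog),
    k_f = stats::rlnorm(1, log(config$k_f_med), config$sens_sdlog),
    h_p = stats::rlnorm(1, log(config$h_p_med), config$sens_sdlog),
    lambda_sas = config$lambda_sas,
    lambda_map = config$lambda_map,
    sas_noise_sd = config$sas_noise_sd,
    map_noise_sd = config$map_noise_sd,
    hr_base = stats::rnorm(1, 88, 2.5),
    resp_base = stats::rnorm(1, 20, 1),
    spo2_base = min(stats::rnorm(1, 97, 1), 100),
    ph_base = stats::rnorm(1, 7.4, 0.03),
    peep_base = max(stats::rnorm(1, 5, 1), 0),
    fio2_base = min(max(stats::rnorm(1, 46, 8), 21), 100),
    pao2_base = stats::rnorm(1, 120, 20),
    plateau_base = stats::rnorm(1, 18, 3),
    airway_base = max(stats::rnorm(1, 8, 2), 1),
    age = min(max(round(stats::rnorm(1, 68, 12)), 18), 95),
    gender = stats::rbinom(1, 1, 0.4))  # male coded 0 (~60% male)
  structure(p, class = "synthetic_patient_params")
}

# Raw 14-feature vector consistent with a given SAS/MAP; vitals coupled to
# the sedation level carry the observable signal.
synth_features <- function(params, sas, map, prev = NULL, noise = TRUE) {
  nz <- function(sd) if (noise) stats::rnorm(1, 0, sd) else 0
  hr_target <- params$hr_base + 4 * (sas - 4)
  resp_target <- params$resp_base + 1.5 * (sas - 4)
  pao2_target <- params$pao2_base
  if (is.null(prev)) {
    hr <- hr_target + nz(1)
    resp <- resp_target + nz(0.5)
    pao2 <- pao2_target + nz(5)
  } else {
    hr <- prev[["heart_rate"]] + 0.8 * (hr_target - prev[["heart_rate"]]) + nz(1)
    resp <- prev[["resp_rate"]] + 0.8 * (resp_target - prev[["resp_rate"]]) + nz(0.5)
    pao2 <- prev[["pao2"]] + 0.3 * (pao2_target - prev[["pao2"]]) + nz(5)
  }
  c(dbp = 0.75 * map - 2 + nz(2),
    nibp_mean = map + 2.5 * (sas - 4) + nz(0.5),
    resp_rate = resp,
    heart_rate = hr,
    spo2 = min(params$spo2_base + nz(0.5), 100),
    arterial_ph = params$ph_base + nz(0.01),
    peep = max(params$peep_base + nz(0.2), 0),
    fio2 = min(max(params$fio2_base + nz(1), 21), 100),
    pao2 = pao2,
    plateau_pressure = max(params$plateau_base + nz(0.5), 1),
    mean_airway_pressure = max(params$airway_base + nz(0.5), 1),
    map = map,
    age = params$age,
    gender = params$gender)
}

#' Advance a synthetic patient by one hour
#'
#' SAS mean-reverts toward the unsedated baseline and is lowered by both
#' drugs in proportion to the patient's sensitivities; MAP mean-reverts
#' toward its baseline and is lowered by propofol (vasodilation). SAS is
#' clipped to the 1--7 scale.
#'
#' @param params A `synthetic_patient_params`.
#' @param sas,map Current SAS and MAP.
#' @param action Length-2 non-negative dose vector (propofol, fentanyl).
#' @param features Current raw feature vector (for AR continuity), or `NULL`.
#' @param noise Include process noise (uses the current RNG state).
#' @return List with `sas`, `map`, `features` for the next hour.
#' @export
step_patient <- function(params, sas, map, action, features = NULL,
                         noise = TRUE) {
  stopifnot(length(action) == 2, all(action >= 0))
  nz <- function(sd) if (noise) stats::rnorm(1, 0, sd) else 0
  sas2 <- sas + params$lambda_sas * (params$sas_baseline - sas) -
    params$k_p * action[1] - params$k_f * action[2] + nz(params$sas_noise_sd)
  sas2 <- min(max(sas2, 1), 7)
  map2 <- map + params$lambda_map * (params$map_baseline - map) -
    params$h_p * action[1] + nz(params$map_noise_sd)
  map2 <- min(max(map2, 40), 150)
  list(sas = sas2, map = map2,
       features = synth_features(params, sas2, map2, prev = features,
                                 noise = noise))
}

#' Noisy clinician behavior policy
#'
#' At a sedation assessment: maintenance dosing inside the SAS 3--4 band,
#' proportional escalation when the patient is agitated (SAS > 4), tapering
#' toward zero when oversedated (SAS < 3), Gaussian dose noise, and
#' occasional overdose events, so the logged data contain both successes and
#' failures. Between assessments (sedation scores are charted only every few
#' hours in practice) the previous infusion rate is held with small drift —
#' pass `prev_dose` and `assess = FALSE`.
#'
#' @param sas SAS value at the most recent assessment.
#' @param map Current MAP (unused by the default law; kept for interface
#'   completeness).
#' @param config A [synth_config()].
#' @param noise Include dose noise and overdose events.
#' @param assess Is this window a sedation assessment?
#' @param prev_dose Previous window's dose (required when `assess = FALSE`).
#' @return Length-2 non-negative dose vector (propofol, fentanyl).
#' @export
clinician_behavior <- function(sas, map, config = synth_config(),
                               noise = TRUE, assess = TRUE,
                               prev_dose = NULL) {
  cap <- rep_len(config$dose_cap, 2L)
  if (!assess) {
    stopifnot(!is.null(prev_dose))
    d <- prev_dose
    if (noise) d <- d + stats::rnorm(2, 0, config$hold_noise_sd)
    return(c(propofol = min(max(d[1], 0), cap[1]),
             fentanyl = min(max(d[2], 0), cap[2])))
  }
  excess <- max(sas - 4, 0)
  taper <- if (sas < 3) max(sas - 2, 0) else 1
  prop <- taper * config$maint_prop + config$gain_prop * excess
  fent <- taper * config$maint_fent + config$gain_fent * excess
  if (noise) {
    prop <- prop + stats::rnorm(1, 0, config$dose_noise_sd[1])
    fent <- fent + stats::rnorm(1, 0, config$dose_noise_sd[2])
    if (stats::runif(1) < config$overdose_prob) {
      prop <- prop * config$overdose_factor
      fent <- fent * config$overdose_factor
    }
  }
  c(propofol = min(max(prop, 0), cap[1]),
    fentanyl = min(max(fent, 0), cap[2]))
}

#' Generate a synthetic cohort under the clinician behavior policy
#'
#' Simulates `n_patients` ICU stays of `horizon_h` hourly windows, doses
#' chosen by [clinician_behavior()], and emits the raw long-format
#' observation table expected by [preprocess_cohort()], with configurable
#' missingness injected into the feature recordings. The true per-patient
#' simulator parameters and initial conditions are attached for
#' counterfactual evaluation of other policies on the same patients.
#'
#' @param n_patients Number of patients (>= 1).
#' @param horizon_h Stay length in hours (>= 2).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param config A [synth_config()].
#' @return List of class `synthetic_cohort`: `observations` (long-format
#'   data.frame), `params` (named list of `synthetic_patient_params`),
#'   `init` (per-patient initial `sas`, `map`, `features`), `truth`
#'   (per-patient hourly SAS/MAP/dose matrices before missingness), and
#'   `config`.
#' @export
generate_cohort <- function(n_patients, horizon_h = 48, seed = 1L,
                            config = synth_config()) {
  stopifnot(n_patients >= 1, horizon_h >= 2)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  feats <- sedrl_features()
  params <- vector("list", n_patients)
  init <- vector("list", n_patients)
  truth <- vector("list", n_patients)
  obs_list <- vector("list", n_patients)
  ids <- sprintf("P%04d", seq_len(n_patients))
  for (i in seq_len(n_patients)) {
    p <- sample_patient(seed = NULL, config = config)
    sas <- min(max(p$sas_baseline + stats::rnorm(1, 0, 0.5), 1), 7)
    map <- p$map_baseline + stats::rnorm(1, 0, 3)
    fv <- synth_features(p, sas, map, prev = NULL, noise = TRUE)
    init[[i]] <- list(sas = sas, map = map, features = fv)
    F <- matrix(NA_real_, horizon_h, length(feats),
                dimnames = list(NULL, feats))
    sas_v <- map_v <- prop_v <- fent_v <- numeric(horizon_h)
    a_prev <- NULL
    for (t in seq_len(horizon_h)) {
      F[t, ] <- fv; sas_v[t] <- sas; map_v[t] <- map
      assess <- is.null(a_prev) ||
        ((t - 1L) %% config$assess_interval == 0L)
      a <- clinician_behavior(sas, map, config, noise = TRUE,
                              assess = assess, prev_dose = a_prev)
      a_prev <- a
      prop_v[t] <- a[1]; fent_v[t] <- a[2]
      nx <- step_patient(p, sas, map, a, features = fv, noise = TRUE)
      sas <- nx$sas; map <- nx$map; fv <- nx$features
    }
    params[[i]] <- p
    truth[[i]] <- list(sas = sas_v, map = map_v,
                       propofol = prop_v, fentanyl = fent_v, features = F)
    # long-format rows with missingness on feature recordings
    hours <- rep(seq_len(horizon_h) - 1L, each = length(feats))
    fvals <- as.vector(t(F))
    fvars <- rep(feats, horizon_h)
    drop <- stats::runif(length(fvals)) < config$missingness
    sas_drop <- stats::runif(horizon_h) < config$sas_missingness
    df <- rbind(
      data.frame(subject_id = ids[i],
                 time_h = hours[!drop] + 0.5,
                 variable = fvars[!drop],
                 value = fvals[!drop]),
      data.frame(subject_id = ids[i],
                 time_h = which(!sas_drop) - 1L + 0.25,
                 variable = "sas",
                 value = sas_v[!sas_drop]),
      data.frame(subject_id = ids[i],
                 time_h = seq_len(horizon_h) - 1L + 0.1,
                 variable = rep(c("propofol_dose", "fentanyl_dose"),
                                each = horizon_h),
                 value = c(prop_v, fent_v)))
    obs_list[[i]] <- df
  }
  names(params) <- names(init) <- names(truth) <- ids
  structure(list(observations = do.call(rbind, obs_list), params = params,
                 init = init, truth = truth, config = config,
                 n_patients = n_patients, horizon_h = horizon_h,
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$n_patients, "patients x", x$horizon_h,
      "h (seed", x$seed, ")\n")
  invisible(x)
}

#' Roll a dosing policy out on the true simulator
#'
#' Replays one synthetic patient from a given initial condition, choosing
#' doses with `policy` applied to the z-normalized feature vector, and
#' stepping the true pharmacodynamic simulator. This is the ground-truth
#' counterfactual used to score a learned policy.
#'
#' @param params A `synthetic_patient_params`.
#' @param init List with `sas`, `map`, `features` (raw units).
#' @param policy Function: 1 x 14 normalized state matrix -> length-2 dose.
#' @param stats `normalization_stats` used to normalize states for the
#'   policy (training-split statistics).
#' @param horizon Number of hourly steps.
#' @param noise Process noise on (uses current RNG state).
#' @return List with per-hour `sas`, `map`, `propofol`, `fentanyl`.
#' @export
simulate_policy <- function(params, init, policy, stats, horizon,
                            noise = TRUE) {
  stopifnot(horizon >= 1)
  sas <- init$sas; map <- init$map; fv <- init$features
  sas_v <- map_v <- prop_v <- fent_v <- numeric(horizon)
  for (t in seq_len(horizon)) {
    sas_v[t] <- sas; map_v[t] <- map
    s_norm <- (fv - stats$mean) / stats$sd
    a <- as.numeric(policy(matrix(s_norm, nrow = 1L)))
    a <- pmax(a, 0)
    prop_v[t] <- a[1]; fent_v[t] <- a[2]
    nx <- step_patient(params, sas, map, a, features = fv, noise = noise)
    sas <- nx$sas; map <- nx$map; fv <- nx$features
  }
  list(sas = sas_v, map = map_v, propofol = prop_v, fentanyl = fent_v)
}
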
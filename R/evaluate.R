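# Performance-error statistics (PE, MDPE, MPE, RMSE) and learned-vs-clinician
# policy comparison with Welch t-tests.

#' Performance error of one control-variable series
#'
#' Percentage of a patient's ICU hours that the control variable spent
#' outside its therapeutic band (boundaries inclusive).
#'
#' @param values Hourly values of the control variable.
#' @param ltb,utb Band boundaries.
#' @return PE in \[0, 100\].
#' @export
performance_error <- function(values, ltb, utb) {
  n <- length(values)
  if (n < 1L) stop("empty series")
  stopifnot(ltb < utb)
  in_range <- values >= ltb & values <= utb
  (n - sum(in_range)) / n * 100
}

#' Median performance error across patients
#'
#' @param pe_values Per-patient PE vector.
#' @return Median PE (mean of the central pair for an even count).
#' @export
mdpe <- function(pe_values) {
  if (!length(pe_values)) stop("no PE values")
  stats::median(pe_values)
}

#' Per-patient RMSE of band deviations
#'
#' Root of the mean squared deviation from the band over the stay; zero
#' exactly when every hourly value is in range.
#'
#' @param values Hourly control-variable values.
#' @param ltb,utb Band boundaries.
#' @return Non-negative RMSE.
#' @export
rmse_patient <- function(values, ltb, utb) {
  if (!length(values)) stop("empty series")
  sqrt(mean(deviation(values, ltb, utb)^2))
}

#' Two-sample comparison of per-patient metrics
#'
#' Welch two-sample t-test by default (pooled-variance and paired options
#' available). When both samples are constant with equal means the
#' convention `t = 0, p = 1` applies; constant samples with different means
#' give `p = 0`.
#'
#' @param x,y Per-patient metric vectors (length >= 2).
#' @param paired Paired test (same patients under both policies).
#' @param var_equal Pooled-variance test instead of Welch.
#' @return List with `t`, `p`, `mean_x`, `mean_y`.
#' @export
compare_policies <- function(x, y, paired = FALSE, var_equal = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  degenerate <- if (paired) stats::sd(x - y) == 0 else
    stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, p = 1, mean_x = mean(x), mean_y = mean(y)))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0,
                mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_x = mean(x), mean_y = mean(y))
}

# Per-patient series -> one report row set for one control variable.
variable_metrics <- function(series_list, ltb, utb) {
  pe <- vapply(series_list, performance_error, numeric(1), ltb = ltb, utb = utb)
  rmse <- vapply(series_list, rmse_patient, numeric(1), ltb = ltb, utb = utb)
  means <- vapply(series_list, mean, numeric(1))
  list(pe = pe, rmse = rmse, patient_means = means,
       mpe = mean(pe), mpe_sd = stats::sd(pe), mdpe = mdpe(pe),
       mean_rmse = mean(rmse),
       mean_value = mean(means), mean_value_sd = stats::sd(means),
       time_in_range = 100 - mean(pe))
}

#' Score a policy on a cohort
#'
#' For the logged behavior (clinician) policy the SAS/MAP/dose series are
#' read directly from the trajectories (no rollout). For a learned policy,
#' each test patient is re-simulated from their first observed state with a
#' matched horizon, either on the true synthetic simulator (`simulator`
#' given) or through a learned dynamics model (`dynamics` given).
#'
#' @param cohort A `sedrl_cohort`.
#' @param policy `NULL` for the logged behavior policy, otherwise a function
#'   mapping a normalized state matrix to doses (see [agent_policy()]).
#' @param simulator A `synthetic_cohort` supplying true patient parameters
#'   and initial conditions for counterfactual rollouts.
#' @param dynamics A `sedrl_dynamics` used for model-based rollouts when no
#'   simulator is available.
#' @param reward_cfg A [reward_config()] (band boundaries).
#' @param ids Subjects to score; defaults to the test split.
#' @param seed Seed for rollout process noise.
#' @return Object of class `policy_performance_report` with per-patient PE
#'   and RMSE vectors, MDPE, MPE (+/- sd), mean RMSE, mean values and mean
#'   doses for SAS and MAP.
#' @export
evaluate_policy_on_cohort <- function(cohort, policy = NULL,
                                      simulator = NULL, dynamics = NULL,
                                      reward_cfg = reward_config(),
                                      ids = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "sedrl_cohort"))
  if (is.null(ids)) ids <- cohort$split$test_ids
  ids <- as.character(ids)
  trs <- cohort$trajectories[ids]
  if (is.null(policy)) {
    series <- lapply(trs, function(tr)
      list(sas = tr$sas, map = tr$map,
           propofol = tr$propofol, fentanyl = tr$fentanyl))
    mode <- "logged"
  } else if (!is.null(simulator)) {
    stopifnot(inherits(simulator, "synthetic_cohort"))
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    series <- lapply(ids, function(id) {
      horizon <- trs[[id]]$icu_duration_h
      simulate_policy(simulator$params[[id]], simulator$init[[id]], policy,
                      cohort$stats, horizon, noise = TRUE)
    })
    names(series) <- ids
    mode <- "simulator_rollout"
  } else if (!is.null(dynamics)) {
    series <- lapply(ids, function(id) {
      tr <- trs[[id]]
      horizon <- max(tr$icu_duration_h - 1L, 1L)
      ro <- rollout(dynamics, policy, tr$state[1L, ], horizon, cohort$stats)
      keep <- !is.na(ro$map)
      list(sas = ro$sas[keep], map = ro$map[keep],
           propofol = ro$actions[keep, 1L], fentanyl = ro$actions[keep, 2L])
    })
    names(series) <- ids
    mode <- "dynamics_rollout"
  } else {
    stop("a learned policy needs either a simulator or a dynamics model")
  }
  sas_m <- variable_metrics(lapply(series, `[[`, "sas"),
                            reward_cfg$sas_ltb, reward_cfg$sas_utb)
  map_m <- variable_metrics(lapply(series, `[[`, "map"),
                            reward_cfg$map_ltb, reward_cfg$map_utb)
  prop_means <- vapply(series, function(s) mean(s$propofol), numeric(1))
  fent_means <- vapply(series, function(s) mean(s$fentanyl), numeric(1))
  total_dose <- vapply(series, function(s) sum(s$propofol + s$fentanyl),
                       numeric(1))
  structure(list(ids = ids, mode = mode, sas = sas_m, map = map_m,
                 mean_propofol = mean(prop_means),
                 mean_propofol_sd = stats::sd(prop_means),
                 mean_fentanyl = mean(fent_means),
                 mean_fentanyl_sd = stats::sd(fent_means),
                 total_dose = total_dose, series = series),
            class = "policy_performance_report")
}

#' @export
print.policy_performance_report <- function(x, ...) {
  cat("<policy_performance_report>", x$mode, "-", length(x$ids), "patients\n")
  cat(sprintf("  SAS: MPE %.2f%% +/- %.2f | MDPE %.2f%% | mean RMSE %.3f\n",
              x$sas$mpe, x$sas$mpe_sd, x$sas$mdpe, x$sas$mean_rmse))
  cat(sprintf("  MAP: MPE %.2f%% +/- %.2f | MDPE %.2f%% | mean RMSE %.3f\n",
              x$map$mpe, x$map$mpe_sd, x$map$mdpe, x$map$mean_rmse))
  cat(sprintf("  mean propofol %.2f +/- %.2f | mean fentanyl %.2f +/- %.2f\n",
              x$mean_propofol, x$mean_propofol_sd,
              x$mean_fentanyl, x$mean_fentanyl_sd))
  invisible(x)
}

#' Compare two policy performance reports
#'
#' Welch t-tests on per-patient PE and RMSE for both control variables and
#' on per-patient total medication.
#'
#' @param report_a,report_b `policy_performance_report` objects (e.g.
#'   learned and behavior policy on the same test patients).
#' @param paired Use paired tests.
#' @return data.frame with one row per comparison: metric, means under both
#'   policies, t statistic and two-sided p-value.
#' @export
compare_policy_reports <- function(report_a, report_b, paired = FALSE) {
  comp <- function(metric, x, y) {
    r <- compare_policies(x, y, paired = paired)
    data.frame(metric = metric, mean_a = r$mean_x, mean_y = r$mean_y,
               t = r$t, p = r$p)
  }
  out <- rbind(comp("PE_SAS", report_a$sas$pe, report_b$sas$pe),
               comp("PE_MAP", report_a$map$pe, report_b$map$pe),
               comp("RMSE_SAS", report_a$sas$rmse, report_b$sas$rmse),
               comp("RMSE_MAP", report_a$map$rmse, report_b$map$rmse),
               comp("total_dose", report_a$total_dose, report_b$total_dose))
  names(out)[names(out) == "mean_y"] <- "mean_b"
  out
}
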
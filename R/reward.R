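# Therapeutic-band reward for joint SAS / MAP control with a dose penalty
# and an improvement gate.

#' Reward configuration
#'
#' Bands, penalty coefficient and gating behavior for the sedation reward.
#' Defaults encode the therapeutic targets: MAP 65--85 mmHg and SAS 3--4
#' (light sedation on the Riker Sedation--Agitation Scale), with a dose
#' penalty coefficient of 0.02 and reward gated on strict improvement of the
#' combined band error.
#'
#' @param map_ltb,map_utb Lower/upper MAP target boundary (mmHg).
#' @param sas_ltb,sas_utb Lower/upper SAS target boundary (scale points).
#' @param dose_penalty Coefficient multiplying the total medication amount.
#' @param gate_on_improvement If `TRUE` (default) the reward is zero unless
#'   the combined band error strictly decreased from the previous window.
#' @param gate_zero_pass If `TRUE`, a window with zero combined error (both
#'   variables inside their bands) always passes the gate, so maintaining
#'   perfect control is rewarded rather than zeroed. Off by default — the
#'   published strict rule zeroes the 0 -> 0 case — but enabled in the
#'   dosing pipeline's training reward (see the methods vignette: under the
#'   strict rule, band maintenance earns no reward at all and only band
#'   re-entry is reinforced).
#' @param signed_error If `TRUE`, the window error sums signed deviations
#'   literally; the default sums magnitudes so that an excess in one variable
#'   cannot cancel a deficit in the other.
#' @param map_scale,sas_scale Logistic scale divisors for the two band
#'   rewards. The defaults of 1 evaluate both band formulas exactly as
#'   published. Because the SAS band is only 1 point wide, the published
#'   unit-scale formula caps its reward at about -0.51 and spans a dynamic
#'   range of under 0.2 across the whole scale; `sas_scale` < 1 sharpens the
#'   band so its interior approaches the intended value of 1 (see the
#'   methods vignette — the dosing pipeline trains with `sas_scale = 0.25`).
#' @return A list of class `reward_config`.
#' @export
reward_config <- function(map_ltb = 65, map_utb = 85,
                          sas_ltb = 3, sas_utb = 4,
                          dose_penalty = 0.02,
                          gate_on_improvement = TRUE,
                          gate_zero_pass = FALSE,
                          signed_error = FALSE,
                          map_scale = 1, sas_scale = 1) {
  stopifnot(map_ltb < map_utb, sas_ltb < sas_utb,
            dose_penalty >= 0, map_scale > 0, sas_scale > 0)
  structure(list(map_ltb = map_ltb, map_utb = map_utb,
                 sas_ltb = sas_ltb, sas_utb = sas_utb,
                 dose_penalty = dose_penalty,
                 gate_on_improvement = isTRUE(gate_on_improvement),
                 gate_zero_pass = isTRUE(gate_zero_pass),
                 signed_error = isTRUE(signed_error),
                 map_scale = map_scale, sas_scale = sas_scale),
            class = "reward_config")
}

# Difference of two logistic sigmoids centered on the band edges; close to 1
# deep inside a wide band, close to -1 far outside.
band_reward <- function(x, ltb, utb, scale = 1) {
  2 * stats::plogis((x - ltb) / scale) - 2 * stats::plogis((x - utb) / scale) - 1
}

#' MAP band reward
#'
#' `2/(1+exp(-(MAP-65))) - 2/(1+exp(-(MAP-85))) - 1`: near 1 inside the
#' 65--85 mmHg therapeutic range, approaching -1 far outside it.
#'
#' @param map_mmHg Mean arterial pressure (mmHg); vectorized.
#' @param config A [reward_config()].
#' @return Numeric vector in (-1, 1].
#' @export
r_map <- function(map_mmHg, config = reward_config()) {
  if (!all(is.finite(map_mmHg))) stop("non-finite MAP value")
  band_reward(map_mmHg, config$map_ltb, config$map_utb, config$map_scale)
}

#' SAS band reward
#'
#' `2/(1+exp(-(SAS-3))) - 2/(1+exp(-(SAS-4))) - 1`. Because the SAS band
#' width (1 point) is comparable to the logistic scale, the published formula
#' peaks at about -0.51 at SAS 3.5 rather than near 1; it is still maximized
#' inside the band and is implemented exactly as printed (see the vignette
#' for the rescaled variant).
#'
#' @param sas SAS value(s) in \[1, 7\].
#' @param config A [reward_config()].
#' @return Numeric vector in (-1, 1].
#' @export
r_sas <- function(sas, config = reward_config()) {
  if (!all(is.finite(sas)) || any(sas < 1 | sas > 7))
    stop("SAS must be finite and within [1, 7]")
  band_reward(sas, config$sas_ltb, config$sas_utb, config$sas_scale)
}

#' Signed deviation from a target band
#'
#' Zero inside `[ltb, utb]`; `ltb - value` below the band (positive) and
#' `utb - value` above it (negative).
#'
#' @param value Measured value(s); vectorized.
#' @param ltb,utb Band boundaries, `ltb < utb`.
#' @return Signed deviation(s).
#' @export
deviation <- function(value, ltb, utb) {
  stopifnot(ltb < utb)
  ifelse(value < ltb, ltb - value, ifelse(value > utb, utb - value, 0))
}

#' Combined band error of one window
#'
#' Total deviation of both control variables. By default the magnitudes are
#' summed, so the error is zero exactly when both variables sit inside their
#' bands; `signed = TRUE` sums the signed deviations literally.
#'
#' @param d_map,d_sas Deviations from [deviation()]; vectorized.
#' @param signed Sum signed deviations instead of magnitudes.
#' @return Non-negative error (unless `signed = TRUE`).
#' @export
window_error <- function(d_map, d_sas, signed = FALSE) {
  if (isTRUE(signed)) d_map + d_sas else abs(d_map) + abs(d_sas)
}

#' Full reward breakdown for one hourly window
#'
#' @param sas,map_mmHg Control-variable values for the window.
#' @param propofol,fentanyl Doses administered (non-negative, dataset units).
#' @param config A [reward_config()].
#' @return List of class `reward_breakdown`: `r_map`, `r_sas`, `r_dosage`
#'   (total medication), `d_map`, `d_sas`, `error`.
#' @export
reward_breakdown <- function(sas, map_mmHg, propofol, fentanyl,
                             config = reward_config()) {
  stopifnot(propofol >= 0, fentanyl >= 0)
  d_map <- deviation(map_mmHg, config$map_ltb, config$map_utb)
  d_sas <- deviation(sas, config$sas_ltb, config$sas_utb)
  structure(list(
    r_map = r_map(map_mmHg, config),
    r_sas = r_sas(sas, config),
    r_dosage = propofol + fentanyl,
    d_map = d_map, d_sas = d_sas,
    error = window_error(d_map, d_sas, signed = config$signed_error)),
    class = "reward_breakdown")
}

#' Gated window reward
#'
#' `r_SAS + r_MAP - 0.02 * r_dosage` when the combined band error strictly
#' improved over the previous window; 0 otherwise. With no previous error
#' (first window, `error_prev = NULL`) the gate is treated as passed.
#'
#' @param breakdown A [reward_breakdown()] for the current window.
#' @param error_prev The previous window's combined error, or `NULL`.
#' @param config A [reward_config()].
#' @return Scalar reward.
#' @export
compute_reward <- function(breakdown, error_prev = NULL,
                           config = reward_config()) {
  stopifnot(inherits(breakdown, "reward_breakdown"))
  gate_ok <- !config$gate_on_improvement ||
    is.null(error_prev) || breakdown$error < error_prev ||
    (config$gate_zero_pass && breakdown$error == 0)
  if (!gate_ok) return(0)
  breakdown$r_sas + breakdown$r_map - config$dose_penalty * breakdown$r_dosage
}

#' Per-window rewards along a trajectory
#'
#' Applies [reward_breakdown()] and [compute_reward()] window by window,
#' gating each window on improvement over its predecessor.
#'
#' @param sas,map_mmHg,propofol,fentanyl Aligned per-window vectors.
#' @param config A [reward_config()].
#' @return data.frame with one row per window: `r_map`, `r_sas`, `r_dosage`,
#'   `d_map`, `d_sas`, `error`, `reward`.
#' @export
trajectory_rewards <- function(sas, map_mmHg, propofol, fentanyl,
                               config = reward_config()) {
  n <- length(sas)
  stopifnot(n >= 1, length(map_mmHg) == n,
            length(propofol) == n, length(fentanyl) == n)
  d_map <- deviation(map_mmHg, config$map_ltb, config$map_utb)
  d_sas <- deviation(sas, config$sas_ltb, config$sas_utb)
  err <- window_error(d_map, d_sas, signed = config$signed_error)
  rm_ <- r_map(map_mmHg, config)
  rs_ <- r_sas(sas, config)
  dose <- propofol + fentanyl
  raw <- rs_ + rm_ - config$dose_penalty * dose
  if (config$gate_on_improvement) {
    gate <- c(TRUE, err[-1] < err[-n])
    if (config$gate_zero_pass) gate <- gate | err == 0
    raw <- ifelse(gate, raw, 0)
  }
  data.frame(r_map = rm_, r_sas = rs_, r_dosage = dose,
             d_map = d_map, d_sas = d_sas, error = err, reward = raw)
}
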
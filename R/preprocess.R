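# Hourly windowing, sample-and-hold imputation, z-normalization and
# subject-level splitting of raw ICU observations.

#' State feature names
#'
#' The 14 features describing a patient state: diastolic blood pressure,
#' mean noninvasive blood pressure, respiration rate, heart rate, SpO2,
#' arterial pH, PEEP, FiO2, arterial O2 partial pressure, plateau pressure,
#' average airway pressure, MAP, age, and gender (0 = male).
#'
#' @return Character vector of length 14.
#' @export
sedrl_features <- function() {
  c("dbp", "nibp_mean", "resp_rate", "heart_rate", "spo2", "arterial_ph",
    "peep", "fio2", "pao2", "plateau_pressure", "mean_airway_pressure",
    "map", "age", "gender")
}

# Outcome / action variable names in the raw long format.
sedrl_outcomes <- function() c("sas", "propofol_dose", "fentanyl_dose")

# Features excluded from z-scaling (binary coding).
sedrl_binary_features <- function() "gender"

new_patient_trajectory <- function(subject_id, state, sas, map, propofol,
                                   fentanyl) {
  stopifnot(nrow(state) == length(sas), length(sas) == length(map),
            length(map) == length(propofol),
            length(propofol) == length(fentanyl), nrow(state) >= 1)
  structure(list(subject_id = subject_id, state = state, sas = sas,
                 map = map, propofol = propofol, fentanyl = fentanyl,
                 icu_duration_h = nrow(state)),
            class = "patient_trajectory")
}

#' @export
print.patient_trajectory <- function(x, ...) {
  cat("<patient_trajectory> subject", x$subject_id, "-",
      x$icu_duration_h, "hourly windows\n")
  invisible(x)
}

#' Aggregate raw observations of one subject into hourly windows
#'
#' The ICU stay is divided into contiguous half-open hourly windows
#' `[t, t+1)`, 0-based. Multiple recordings of a variable within a window are
#' averaged; variables without a recording are left missing (`NA`), except
#' doses, which default to 0 (absence of an infusion order is absence of
#' administration, not missing data).
#'
#' @param observations data.frame with columns `subject_id`, `time_h`
#'   (hours from admission, >= 0), `variable`, `value`.
#' @param subject_id Subject to extract; defaults to the only subject present.
#' @return A `patient_trajectory` (pre-imputation: states may contain `NA`).
#' @export
window_hourly <- function(observations, subject_id = NULL) {
  obs <- data.table::as.data.table(observations)
  req <- c("subject_id", "time_h", "variable", "value")
  if (!all(req %in% names(obs)))
    stop("observations need columns: ", paste(req, collapse = ", "))
  if (is.null(subject_id)) {
    ids <- unique(obs$subject_id)
    if (length(ids) != 1L) stop("subject_id must be given for multi-subject input")
    subject_id <- ids
  }
  sid <- subject_id  # avoid data.table name capture
  obs <- obs[obs$subject_id == sid]
  if (nrow(obs) == 0L) stop("no observations for subject ", subject_id)
  if (any(!is.finite(obs$time_h)) || any(obs$time_h < 0))
    stop("observation times must be finite and >= 0")
  feats <- sedrl_features()
  known <- c(feats, sedrl_outcomes())
  bad <- setdiff(unique(obs$variable), known)
  if (length(bad))
    stop("unknown variable(s): ", paste(bad, collapse = ", "))
  sas_vals <- obs$value[obs$variable == "sas" & !is.na(obs$value)]
  if (length(sas_vals) && any(sas_vals < 1 | sas_vals > 7))
    stop("SAS values must lie in [1, 7]")
  win <- value <- variable <- NULL  # data.table NSE
  obs[, win := as.integer(floor(time_h))]
  n_win <- max(obs$win) + 1L
  agg <- obs[!is.na(value), list(value = mean(value)), by = list(variable, win)]
  state <- matrix(NA_real_, nrow = n_win, ncol = length(feats),
                  dimnames = list(NULL, feats))
  sas <- rep(NA_real_, n_win)
  prop <- rep(0, n_win)
  fent <- rep(0, n_win)
  for (k in seq_len(nrow(agg))) {
    v <- agg$variable[k]; w <- agg$win[k] + 1L; val <- agg$value[k]
    if (v == "sas") sas[w] <- val
    else if (v == "propofol_dose") prop[w] <- max(val, 0)
    else if (v == "fentanyl_dose") fent[w] <- max(val, 0)
    else state[w, v] <- val
  }
  new_patient_trajectory(subject_id, state, sas, map = state[, "map"],
                         propofol = prop, fentanyl = fent)
}

#' Impute missing state values in a windowed trajectory
#'
#' Windows in which every state feature, or the SAS outcome, is missing are
#' dropped and the remaining windows re-indexed contiguously. Missing feature
#' values are then filled by sample-and-hold (last observation carried
#' forward within the patient); values missing with no prior observation fall
#' back to the training-cohort mean of that feature.
#'
#' @param trajectory A `patient_trajectory` from [window_hourly()].
#' @param training_means Named numeric vector with one entry per state
#'   feature, computed on training subjects only.
#' @return The imputed `patient_trajectory` (no `NA` left in the state).
#' @export
fill_missing <- function(trajectory, training_means) {
  stopifnot(inherits(trajectory, "patient_trajectory"))
  feats <- sedrl_features()
  missing_feats <- setdiff(feats, names(training_means))
  if (length(missing_feats))
    stop("training_means lacks feature(s): ",
         paste(missing_feats, collapse = ", "))
  st <- trajectory$state
  keep <- !(apply(st, 1L, function(r) all(is.na(r))) | is.na(trajectory$sas))
  if (!any(keep))
    stop("no usable windows for subject ", trajectory$subject_id)
  st <- st[keep, , drop = FALSE]
  sas <- trajectory$sas[keep]
  prop <- trajectory$propofol[keep]
  fent <- trajectory$fentanyl[keep]
  for (j in seq_along(feats)) {
    col <- st[, j]
    if (anyNA(col)) {
      obs_idx <- which(!is.na(col))
      if (length(obs_idx)) {
        # carry the most recent prior observation forward
        fill_from <- findInterval(seq_along(col), obs_idx)
        col <- ifelse(fill_from >= 1L, col[obs_idx[pmax(fill_from, 1L)]], NA_real_)
      }
      col[is.na(col)] <- training_means[[feats[j]]]
      st[, j] <- col
    }
  }
  new_patient_trajectory(trajectory$subject_id, st, sas,
                         map = st[, "map"], propofol = prop, fentanyl = fent)
}

#' Fit normalization statistics on training trajectories
#'
#' Per-feature mean and population standard deviation (divide by n) over all
#' training windows pooled. Binary features (gender) are excluded from
#' scaling; features with zero variance are flagged and their scale forced
#' to 1 with a warning.
#'
#' @param train_trajectories List of imputed `patient_trajectory` objects
#'   from the training split only.
#' @return List of class `normalization_stats`: `mean`, `sd` (named vectors),
#'   `scaled` (logical per feature).
#' @export
fit_normalizer <- function(train_trajectories) {
  stopifnot(length(train_trajectories) >= 1)
  X <- do.call(rbind, lapply(train_trajectories, `[[`, "state"))
  if (anyNA(X)) stop("trajectories must be imputed before normalization")
  feats <- sedrl_features()
  mu <- colMeans(X)
  n <- nrow(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2))  # population convention
  scaled <- !(feats %in% sedrl_binary_features())
  zero_var <- scaled & sdv <= .Machine$double.eps * 100
  if (any(zero_var)) {
    warning("zero-variance feature(s) scaled by 1: ",
            paste(feats[zero_var], collapse = ", "))
    sdv[zero_var] <- 1
  }
  mu[!scaled] <- 0
  sdv[!scaled] <- 1
  structure(list(mean = mu, sd = sdv, scaled = scaled, n_windows = n),
            class = "normalization_stats")
}

#' Apply (or invert) normalization
#'
#' @param trajectory A `patient_trajectory` (imputed).
#' @param stats A `normalization_stats` from [fit_normalizer()] — always the
#'   training-split statistics, also for validation/test subjects.
#' @return The trajectory with a z-scaled state; the raw SAS, MAP and doses
#'   are retained unscaled for reward computation and evaluation.
#' @export
apply_normalizer <- function(trajectory, stats) {
  stopifnot(inherits(trajectory, "patient_trajectory"),
            inherits(stats, "normalization_stats"))
  st <- sweep(sweep(trajectory$state, 2L, stats$mean), 2L, stats$sd, "/")
  out <- trajectory
  out$state <- st
  out
}

#' @rdname apply_normalizer
#' @param state_matrix Normalized state rows to map back to raw units.
#' @export
denormalize_state <- function(state_matrix, stats) {
  sweep(sweep(state_matrix, 2L, stats$sd, "*"), 2L, stats$mean, "+")
}

#' Subject-level train/validation/test split
#'
#' Deterministic given the seed; no subject appears in two splits. Validation
#' and test sizes are `round(0.2 n)` each, the remainder goes to training
#' (60/20/20 within one subject).
#'
#' @param subject_ids Vector of unique subject identifiers (>= 5).
#' @param seed Integer seed.
#' @param props Split proportions (train, validation, test).
#' @return List of class `cohort_split` with `train_ids`, `val_ids`,
#'   `test_ids`.
#' @export
split_cohort <- function(subject_ids, seed = 1L, props = c(0.6, 0.2, 0.2)) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < 5L) stop("need at least 5 subjects to split; got ", n)
  stopifnot(length(props) == 3, all(props > 0), abs(sum(props) - 1) < 1e-8)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  ord <- sample(subject_ids)
  n_val <- round(props[2] * n)
  n_test <- round(props[3] * n)
  n_train <- n - n_val - n_test
  structure(list(train_ids = ord[seq_len(n_train)],
                 val_ids = ord[n_train + seq_len(n_val)],
                 test_ids = ord[n_train + n_val + seq_len(n_test)]),
            class = "cohort_split")
}

#' Read a raw cohort table
#'
#' Accepts long format (`subject_id, time_h, variable, value`) or wide format
#' (one row per subject-hour with feature, `sas` and dose columns); the
#' dialect is detected from the header. Wide input is melted to long.
#'
#' @param path CSV file path.
#' @return data.frame in long format.
#' @export
read_cohort_csv <- function(path) {
  dt <- data.table::fread(path)
  if (all(c("subject_id", "time_h", "variable", "value") %in% names(dt)))
    return(as.data.frame(dt))
  if (all(c("subject_id", "hour") %in% names(dt))) {
    vars <- intersect(c(sedrl_features(), sedrl_outcomes()), names(dt))
    long <- data.table::melt(dt, id.vars = c("subject_id", "hour"),
                             measure.vars = vars, variable.name = "variable",
                             value.name = "value",
                             variable.factor = FALSE)
    long$time_h <- long$hour
    return(as.data.frame(long[, c("subject_id", "time_h", "variable", "value")]))
  }
  stop("unrecognized cohort CSV header: ", paste(names(dt), collapse = ", "))
}

#' Preprocess a raw cohort end to end
#'
#' Windows every subject hourly, splits subjects 60/20/20, computes
#' training-only imputation means and normalization statistics, and returns
#' imputed, z-normalized trajectories.
#'
#' @param observations Long-format data.frame (see [read_cohort_csv()]).
#' @param seed Seed for the subject split.
#' @param split Optional pre-computed `cohort_split` (overrides `seed`).
#' @return List of class `sedrl_cohort`: `trajectories` (named list),
#'   `stats` (`normalization_stats`), `split` (`cohort_split`),
#'   `training_means`.
#' @export
preprocess_cohort <- function(observations, seed = 1L, split = NULL) {
  ids <- unique(observations$subject_id)
  windowed <- lapply(ids, function(id) window_hourly(observations, id))
  names(windowed) <- as.character(ids)
  if (is.null(split)) split <- split_cohort(ids, seed = seed)
  # imputation means from observed (pre-imputation) training windows
  train_states <- do.call(rbind, lapply(windowed[as.character(split$train_ids)],
                                        `[[`, "state"))
  training_means <- colMeans(train_states, na.rm = TRUE)
  if (anyNA(training_means))
    stop("feature never observed in the training split: ",
         paste(names(training_means)[is.na(training_means)], collapse = ", "))
  imputed <- lapply(windowed, fill_missing, training_means = training_means)
  stats <- fit_normalizer(imputed[as.character(split$train_ids)])
  normed <- lapply(imputed, apply_normalizer, stats = stats)
  structure(list(trajectories = normed, stats = stats, split = split,
                 training_means = training_means),
            class = "sedrl_cohort")
}

#' @export
print.sedrl_cohort <- function(x, ...) {
  cat("<sedrl_cohort>", length(x$trajectories), "subjects (",
      length(x$split$train_ids), "train /", length(x$split$val_ids),
      "val /", length(x$split$test_ids), "test )\n")
  invisible(x)
}

#' Write a preprocessed cohort to disk
#'
#' Wide-format CSV (one row per subject-hour: normalized features plus raw
#' `sas`, `map_raw` and doses) and a JSON sidecar with the normalization
#' statistics and split membership.
#'
#' @param cohort A `sedrl_cohort`.
#' @param csv_path,json_path Output file paths.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, csv_path, json_path) {
  stopifnot(inherits(cohort, "sedrl_cohort"))
  rows <- lapply(cohort$trajectories, function(tr) {
    df <- as.data.frame(tr$state)
    cbind(data.frame(subject_id = tr$subject_id,
                     hour = seq_len(tr$icu_duration_h) - 1L),
          df,
          data.frame(sas = tr$sas, map_raw = tr$map,
                     propofol_dose = tr$propofol,
                     fentanyl_dose = tr$fentanyl))
  })
  wide <- do.call(rbind, rows)
  data.table::fwrite(wide, csv_path)
  side <- list(
    normalization = list(mean = as.list(cohort$stats$mean),
                         sd = as.list(cohort$stats$sd),
                         scaled = as.list(cohort$stats$scaled)),
    training_means = as.list(cohort$training_means),
    split = list(train_ids = cohort$split$train_ids,
                 val_ids = cohort$split$val_ids,
                 test_ids = cohort$split$test_ids))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
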
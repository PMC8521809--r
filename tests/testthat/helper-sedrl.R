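# Shared fixtures, built in code.

# Long-format observation rows for one subject.
obs_row <- function(subject, t, var, val) {
  data.frame(subject_id = subject, time_h = t, variable = var, value = val)
}

# A complete raw table for one subject: every feature, SAS and doses
# recorded once per hour (values constant unless overridden).
full_subject_obs <- function(subject = "s1", hours = 3, sas = 4,
                             hr = 80, map = 75) {
  feats <- sedrl_features()
  vals <- c(dbp = 60, nibp_mean = 76, resp_rate = 20, heart_rate = hr,
            spo2 = 97, arterial_ph = 7.4, peep = 5, fio2 = 45, pao2 = 120,
            plateau_pressure = 18, mean_airway_pressure = 8, map = map,
            age = 70, gender = 0)
  do.call(rbind, lapply(seq_len(hours) - 1L, function(t) {
    rbind(
      data.frame(subject_id = subject, time_h = t + 0.5, variable = feats,
                 value = unname(vals[feats])),
      data.frame(subject_id = subject, time_h = t + 0.25,
                 variable = c("sas", "propofol_dose", "fentanyl_dose"),
                 value = c(sas, 2, 1)))
  }))
}

# An imputed patient_trajectory with constant-but-jittered features, for
# normalizer and transition tests.
toy_trajectory <- function(subject = "s1", n = 4, seed = 1) {
  set.seed(seed)
  feats <- sedrl_features()
  st <- matrix(rnorm(n * length(feats), mean = 50, sd = 5),
               nrow = n, dimnames = list(NULL, feats))
  st[, "gender"] <- 0
  st[, "map"] <- 75 + rnorm(n, 0, 4)
  sedrl:::new_patient_trajectory(subject, st, sas = rep(3.5, n),
                                 map = st[, "map"],
                                 propofol = runif(n, 0, 4),
                                 fentanyl = runif(n, 0, 2))
}

# Independent direct evaluation of the printed band formula (test oracle;
# deliberately avoids plogis and the package's band_reward path).
band_oracle <- function(x, ltb, utb) {
  2 / (1 + exp(-(x - ltb))) - 2 / (1 + exp(-(x - utb))) - 1
}

# Brute-force per-hour metric oracles (independent loops).
pe_oracle <- function(v, ltb, utb) {
  out <- 0
  for (x in v) if (x < ltb || x > utb) out <- out + 1
  out / length(v) * 100
}
rmse_oracle <- function(v, ltb, utb) {
  s <- 0
  for (x in v) {
    d <- if (x < ltb) ltb - x else if (x > utb) utb - x else 0
    s <- s + d^2
  }
  sqrt(s / length(v))
}
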
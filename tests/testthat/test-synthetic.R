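test_that("patient sampling is deterministic with positive sensitivities", {
  p1 <- sample_patient(seed = 5)
  p2 <- sample_patient(seed = 5)
  expect_identical(p1, p2)
  expect_true(p1$k_p > 0 && p1$k_f > 0 && p1$h_p > 0)
  expect_true(p1$sas_baseline >= 4 && p1$sas_baseline <= 6)
  expect_true(p1$map_baseline >= 70 && p1$map_baseline <= 95)
})

test_that("sensitivities vary across patients with log-normal spread", {
  set.seed(99)
  kp <- replicate(1000, sample_patient()$k_p)
  expect_true(all(kp > 0))
  cfg <- synth_config()
  cv_expected <- sqrt(exp(cfg$sens_sdlog^2) - 1)
  cv <- sd(kp) / mean(kp)
  expect_lt(abs(cv - cv_expected) / cv_expected, 0.25)
  expect_lt(abs(median(kp) - cfg$k_p_med) / cfg$k_p_med, 0.1)
})

test_that("dosing lowers SAS and MAP; zero dose mean-reverts; SAS clipped", {
  p <- sample_patient(seed = 2)
  # pure mean reversion toward baseline, monotone
  sas <- 2; map <- 60
  for (i in 1:10) {
    nx <- step_patient(p, sas, map, c(0, 0), noise = FALSE)
    expect_gte(nx$sas, sas)
    expect_gte(nx$map, map)
    sas <- nx$sas; map <- nx$map
  }
  expect_lt(abs(sas - p$sas_baseline), 1)
  # propofol lowers both control variables relative to no dose
  nx <- step_patient(p, 5, 80, c(30, 0), noise = FALSE)
  nx0 <- step_patient(p, 5, 80, c(0, 0), noise = FALSE)
  expect_lt(nx$sas, nx0$sas)
  expect_lt(nx$map, nx0$map)
  expect_lt(nx$sas, 5)
  # clipping to the 1..7 scale under an extreme dose
  nx2 <- step_patient(p, 1.2, 80, c(200, 50), noise = FALSE)
  expect_gte(nx2$sas, 1)
  set.seed(3)
  s <- 4
  for (i in 1:200) {
    s <- step_patient(p, s, 80, c(runif(1, 0, 50), runif(1, 0, 20)))$sas
    expect_true(s >= 1 && s <= 7)
  }
})

test_that("dose response has a negative empirical propofol derivative", {
  set.seed(12)
  diffs <- replicate(200, {
    p <- sample_patient()
    sas <- runif(1, 2, 6)
    base <- step_patient(p, sas, 80, c(5, 2), noise = FALSE)$sas
    up <- step_patient(p, sas, 80, c(5 + 1, 2), noise = FALSE)$sas
    up - base
  })
  expect_lt(mean(diffs), 0)
  expect_true(all(diffs <= 0))
})

test_that("the clinician law is maintenance in band and monotone above it", {
  cfg <- synth_config()
  a_mid <- clinician_behavior(3.5, 80, cfg, noise = FALSE)
  expect_equal(unname(a_mid), c(cfg$maint_prop, cfg$maint_fent))
  a4 <- clinician_behavior(4, 80, cfg, noise = FALSE)
  a6 <- clinician_behavior(6, 80, cfg, noise = FALSE)
  expect_true(all(a6 > a4))
  # oversedated patients are tapered toward zero
  a2 <- clinician_behavior(2, 80, cfg, noise = FALSE)
  expect_equal(unname(a2), c(0, 0))
  set.seed(5)
  for (i in 1:50) {
    a <- clinician_behavior(runif(1, 1, 7), 80, cfg)
    expect_true(all(a >= 0))
  }
  # held doses drift but stay non-negative
  h <- clinician_behavior(5, 80, cfg, noise = FALSE, assess = FALSE,
                          prev_dose = c(3, 1))
  expect_equal(unname(h), c(3, 1))
})

test_that("cohort generation is deterministic with the right shape", {
  co <- generate_cohort(10, 24, seed = 8)
  expect_equal(sum(vapply(co$truth, function(x) length(x$sas), 0L)), 240L)
  co2 <- generate_cohort(10, 24, seed = 8)
  expect_identical(co$observations, co2$observations)
  expect_identical(co$params, co2$params)
  # long format carries every dose recording
  expect_equal(sum(co$observations$variable == "propofol_dose"), 240L)
  # feature recordings thinned by missingness
  n_feat_rows <- sum(co$observations$variable %in% sedrl_features())
  expect_lt(n_feat_rows, 240 * 14)
  expect_gt(n_feat_rows, 240 * 14 * 0.9)
})

test_that("the SAS marginal is unimodal with mode 4 under clinician dosing", {
  co <- generate_cohort(300, 48, seed = 12)
  sas <- round(unlist(lapply(co$truth, `[[`, "sas")))
  tab <- table(factor(sas, levels = 1:7))
  expect_equal(unname(which.max(tab)), 4L)
  # qualitative match to the reported distribution: half the hours at 4,
  # falling off on both sides
  expect_gt(tab["4"] / sum(tab), 0.35)
  expect_true(tab["3"] > tab["2"] && tab["5"] > tab["6"])
})

test_that("the sedation level is linearly recoverable from the state", {
  co <- generate_cohort(100, 48, seed = 7)
  pc <- preprocess_cohort(co$observations, seed = 7)
  ids <- as.character(pc$split$train_ids)
  S <- do.call(rbind, lapply(pc$trajectories[ids], `[[`, "state"))
  sas <- unlist(lapply(pc$trajectories[ids], `[[`, "sas"))
  fit <- lm.fit(cbind(1, S), sas)
  r2 <- 1 - sum(fit$residuals^2) / sum((sas - mean(sas))^2)
  expect_gt(r2, 0.8)   # the policy has no direct SAS input; the vitals
                       # must carry the signal for control to be learnable
})

test_that("policy rollouts on the simulator have matched shape and seeds", {
  co <- generate_cohort(6, 12, seed = 9)
  pc <- preprocess_cohort(co$observations, seed = 9)
  pol <- function(S) c(2, 1)
  set.seed(1)
  out <- simulate_policy(co$params[[1]], co$init[[1]], pol, pc$stats, 12)
  expect_equal(lengths(out[c("sas", "map", "propofol", "fentanyl")]),
               c(sas = 12L, map = 12L, propofol = 12L, fentanyl = 12L))
  expect_true(all(out$propofol == 2))
  set.seed(1)
  out2 <- simulate_policy(co$params[[1]], co$init[[1]], pol, pc$stats, 12)
  expect_identical(out, out2)
})
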
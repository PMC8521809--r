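test_that("hourly windowing averages recordings within half-open windows", {
  obs <- rbind(obs_row("a", 3.1, "heart_rate", 80),
               obs_row("a", 3.9, "heart_rate", 90))
  tr <- window_hourly(obs, "a")
  expect_equal(tr$icu_duration_h, 4L)
  expect_equal(unname(tr$state[4, "heart_rate"]), 85)

  tr1 <- window_hourly(obs_row("a", 0.5, "heart_rate", 80), "a")
  expect_equal(tr1$icu_duration_h, 1L)

  obs2 <- rbind(obs_row("a", 1.2, "map", 70), obs_row("a", 1.8, "map", 90),
                obs_row("a", 2.1, "map", 100))
  tr2 <- window_hourly(obs2, "a")
  expect_equal(tr2$icu_duration_h, 3L)
  expect_true(is.na(tr2$state[1, "map"]))
  expect_equal(unname(tr2$state[2, "map"]), 80)
  expect_equal(unname(tr2$state[3, "map"]), 100)
})

test_that("unrecorded doses mean no administration, not missing data", {
  tr <- window_hourly(obs_row("a", 0.5, "heart_rate", 80), "a")
  expect_identical(tr$propofol, 0)
  expect_identical(tr$fentanyl, 0)
})

test_that("windowing rejects bad input", {
  expect_error(window_hourly(obs_row("a", -1, "heart_rate", 80), "a"),
               "finite and >= 0")
  expect_error(window_hourly(obs_row("a", 1, "heart_rate", 80), "b"),
               "no observations")
  expect_error(window_hourly(obs_row("a", 1, "bogus", 80), "a"), "unknown")
  expect_error(window_hourly(obs_row("a", 1, "sas", 9), "a"), "\\[1, 7\\]")
})

test_that("windowing equals a brute-force group-by-floor oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    var <- sample(c("heart_rate", "map", "sas"), n, replace = TRUE)
    tm <- runif(n, 0, 8)
    val <- ifelse(var == "sas", sample(1:7, n, replace = TRUE),
                  runif(n, 40, 120))
    obs <- data.frame(subject_id = "x", time_h = tm, variable = var,
                      value = val)
    tr <- window_hourly(obs, "x")
    expect_equal(tr$icu_duration_h, floor(max(tm)) + 1L)
    for (v in unique(var)) {
      means <- tapply(val[var == v], floor(tm[var == v]), mean)
      for (w in names(means)) {
        got <- if (v == "sas") tr$sas[as.integer(w) + 1L] else
          tr$state[as.integer(w) + 1L, v]
        expect_equal(unname(got), unname(means[[w]]))
      }
    }
  }
})

test_that("sample-and-hold fills gaps; training mean fills leading gaps", {
  tr <- window_hourly(full_subject_obs(hours = 4), "s1")
  tr$state[2:3, "heart_rate"] <- NA
  tr$state[1, "peep"] <- NA
  means <- colMeans(tr$state, na.rm = TRUE)
  means["heart_rate"] <- 85
  means["peep"] <- 99
  out <- fill_missing(tr, means)
  expect_equal(unname(out$state[, "heart_rate"]), c(80, 80, 80, 80))
  expect_equal(unname(out$state[1, "peep"]), 99)   # no prior: training mean
  expect_equal(unname(out$state[2, "peep"]), 5)    # prior observation held
  expect_false(anyNA(out$state))
})

test_that("fully observed trajectories pass through imputation unchanged", {
  tr <- window_hourly(full_subject_obs(hours = 3), "s1")
  out <- fill_missing(tr, colMeans(tr$state))
  expect_equal(out$state, tr$state)
  expect_equal(out$sas, tr$sas)
})

test_that("windows with no measures or no SAS are removed and re-indexed", {
  tr <- window_hourly(full_subject_obs(hours = 5), "s1")
  tr$state[3, ] <- NA            # all measures missing
  tr$sas[4] <- NA                # SAS outcome missing
  out <- fill_missing(tr, colMeans(tr$state, na.rm = TRUE))
  expect_equal(out$icu_duration_h, 3L)
  expect_false(anyNA(out$state))
  expect_false(anyNA(out$sas))
  expect_error(fill_missing(tr, c(heart_rate = 1)), "lacks feature")
})

test_that("normalization uses training statistics with population variance", {
  t1 <- toy_trajectory("a", n = 1, seed = 1)
  t2 <- toy_trajectory("b", n = 1, seed = 2)
  t1$state[1, "heart_rate"] <- 80
  t2$state[1, "heart_rate"] <- 90
  stats <- fit_normalizer(list(t1, t2))
  expect_equal(unname(stats$mean["heart_rate"]), 85)
  expect_equal(unname(stats$sd["heart_rate"]), 5)  # divide by n
  n1 <- apply_normalizer(t1, stats)
  expect_equal(unname(n1$state[1, "heart_rate"]), -1)
  # validation subject scaled by training stats, not its own
  t3 <- toy_trajectory("c", n = 1, seed = 3)
  t3$state[1, "heart_rate"] <- 85
  expect_equal(unname(apply_normalizer(t3, stats)$state[1, "heart_rate"]), 0)
  # binary gender excluded from scaling
  expect_equal(unname(stats$sd["gender"]), 1)
  expect_equal(unname(stats$mean["gender"]), 0)
  # raw SAS/MAP/doses retained unscaled
  expect_equal(n1$sas, t1$sas)
  expect_equal(n1$map, t1$map)
})

test_that("normalized training features have mean 0 and unit variance", {
  trajs <- lapply(1:6, function(i) toy_trajectory(paste0("s", i), 5, i))
  stats <- fit_normalizer(trajs)
  normed <- lapply(trajs, apply_normalizer, stats = stats)
  X <- do.call(rbind, lapply(normed, `[[`, "state"))
  cont <- setdiff(sedrl_features(), "gender")
  expect_true(all(abs(colMeans(X[, cont])) < 1e-9))
  v <- colMeans(sweep(X[, cont], 2, colMeans(X[, cont]))^2)
  expect_true(all(abs(v - 1) < 1e-9))
  # idempotence: restandardizing standardized data changes nothing
  stats2 <- fit_normalizer(normed)
  expect_true(all(abs(stats2$mean[cont]) < 1e-12))
  expect_true(all(abs(stats2$sd[cont] - 1) < 1e-12))
  # denormalization inverts
  expect_equal(denormalize_state(normed[[1]]$state, stats),
               trajs[[1]]$state, tolerance = 1e-12)
})

test_that("zero-variance features are flagged and scaled by 1", {
  trajs <- lapply(1:3, function(i) toy_trajectory(paste0("s", i), 4, i))
  for (tr in seq_along(trajs)) trajs[[tr]]$state[, "age"] <- 70
  expect_warning(stats <- fit_normalizer(trajs), "zero-variance")
  expect_equal(unname(stats$sd["age"]), 1)
})

test_that("subject split is deterministic, disjoint and 60/20/20", {
  s <- split_cohort(paste0("p", 1:10), seed = 3)
  expect_equal(lengths(unclass(s)), c(train_ids = 6L, val_ids = 2L,
                                      test_ids = 2L))
  expect_identical(s, split_cohort(paste0("p", 1:10), seed = 3))
  big <- split_cohort(seq_len(1757), seed = 1)
  expect_equal(length(big$train_ids), 1055L)
  expect_equal(length(big$val_ids), 351L)
  expect_equal(length(big$test_ids), 351L)
  for (n in c(5, 7, 23, 101)) {
    sp <- split_cohort(seq_len(n), seed = n)
    all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_equal(sort(all_ids), seq_len(n))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
  expect_error(split_cohort(1:4), "at least 5")
})

test_that("cohort CSV reader handles long and wide dialects", {
  long <- full_subject_obs("s1", hours = 2)
  f1 <- tempfile(fileext = ".csv")
  write.csv(long, f1, row.names = FALSE)
  got <- read_cohort_csv(f1)
  expect_setequal(names(got), c("subject_id", "time_h", "variable", "value"))
  expect_equal(nrow(got), nrow(long))

  wide <- data.frame(subject_id = "s1", hour = 0:1, heart_rate = c(80, 82),
                     map = c(75, 76), sas = c(4, 4), propofol_dose = c(2, 2))
  f2 <- tempfile(fileext = ".csv")
  write.csv(wide, f2, row.names = FALSE)
  got2 <- read_cohort_csv(f2)
  expect_equal(nrow(got2), 2 * 4)
  expect_equal(got2$value[got2$variable == "heart_rate"], c(80, 82))
  expect_error(read_cohort_csv({
    f3 <- tempfile(fileext = ".csv"); write.csv(mtcars, f3); f3
  }), "unrecognized")
})

test_that("preprocess_cohort produces clean normalized trajectories", {
  co <- generate_cohort(8, 12, seed = 5)
  pc <- preprocess_cohort(co$observations, seed = 9)
  expect_s3_class(pc, "sedrl_cohort")
  expect_equal(length(pc$trajectories), 8L)
  for (tr in pc$trajectories) {
    expect_false(anyNA(tr$state))
    expect_false(anyNA(tr$sas))
    expect_true(all(tr$propofol >= 0 & tr$fentanyl >= 0))
  }
  expect_equal(length(pc$split$train_ids), 4L)  # 8 - round(1.6) - round(1.6)
  # round trip through the writers
  csvf <- tempfile(fileext = ".csv"); jsonf <- tempfile(fileext = ".json")
  write_cohort(pc, csvf, jsonf)
  wide <- read.csv(csvf)
  expect_equal(nrow(wide), sum(vapply(pc$trajectories, `[[`, 0L,
                                      "icu_duration_h")))
  side <- jsonlite::read_json(jsonf)
  expect_setequal(unlist(side$split), names(pc$trajectories))
})
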
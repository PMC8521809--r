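make_actor <- function(dose_max = c(5, 3), seed = 1) {
  net <- mlp_init(c(14, 8, 2), seed = seed)
  structure(list(net = net, dose_max = dose_max), class = "sedrl_actor")
}

test_that("soft update mixes target and online parameters convexly", {
  a <- mlp_init(c(2, 3, 1), seed = 1)
  b <- mlp_init(c(2, 3, 1), seed = 2)
  expect_equal(soft_update(a, b, 1), b)
  expect_equal(soft_update(a, b, 0), a)
  mid <- soft_update(a, b, 0.5)
  expect_equal(mid$W[[1]], (a$W[[1]] + b$W[[1]]) / 2)
  # stays within the elementwise min/max envelope
  m <- soft_update(a, b, 0.3)
  expect_true(all(m$W[[2]] >= pmin(a$W[[2]], b$W[[2]]) - 1e-12))
  expect_true(all(m$W[[2]] <= pmax(a$W[[2]], b$W[[2]]) + 1e-12))
  expect_error(soft_update(a, mlp_init(c(2, 4, 1), 3), 0.5))
})

test_that("action selection is deterministic without noise and clipped", {
  actor <- make_actor()
  s <- rnorm(14)
  expect_identical(select_action(actor, s), select_action(actor, s))
  set.seed(1)
  noisy <- select_action(actor, s, noise_sd = 10)
  expect_true(all(noisy >= 0 & noisy <= actor$dose_max))
  for (i in 1:20) {
    a <- select_action(actor, rnorm(14, sd = 5))
    expect_true(all(a >= 0 & a <= actor$dose_max))
  }
})

test_that("TD targets with gamma 0 equal the rewards exactly", {
  actor <- make_actor(seed = 3)
  critic <- structure(list(net = mlp_init(c(16, 8, 1), seed = 4),
                           dose_max = c(5, 3)), class = "sedrl_critic")
  opt <- sedrl:::adam_init(critic$net, lr = 1e-3)
  batch <- list(S = matrix(rnorm(6 * 14), 6), A = matrix(runif(12, 0, 3), 6),
                R = rnorm(6), S2 = matrix(rnorm(6 * 14), 6),
                weights = rep(1, 6), idx = 1:6)
  up <- critic_td_update(critic, opt, critic, actor, batch, gamma = 0)
  expect_equal(up$targets, batch$R)
  expect_equal(up$priorities, abs(up$td) + 1e-3)
})

test_that("critic loss equals a hand-computed importance-weighted MSE", {
  actor <- make_actor(seed = 5)
  critic <- structure(list(net = mlp_init(c(16, 8, 1), seed = 6),
                           dose_max = c(5, 3)), class = "sedrl_critic")
  opt <- sedrl:::adam_init(critic$net, lr = 1e-3)
  set.seed(7)
  w <- c(0.2, 0, 1, 0.5)
  batch <- list(S = matrix(rnorm(4 * 14), 4), A = matrix(runif(8, 0, 3), 4),
                R = rnorm(4), S2 = matrix(rnorm(4 * 14), 4),
                weights = w, idx = 1:4)
  gamma <- 0.5
  # independent recomputation by explicit loops over the stored weights
  manual_forward <- function(net, x) {
    a <- x
    for (l in seq_along(net$W)) {
      z <- as.numeric(a %*% net$W[[l]]) + as.numeric(net$b[[l]])
      a <- if (l < length(net$W)) pmax(z, 0) else z
    }
    a
  }
  td_manual <- numeric(4)
  for (i in 1:4) {
    a2 <- pmin(pmax(manual_forward(actor$net, batch$S2[i, ]), 0),
               actor$dose_max)
    q2 <- manual_forward(critic$net, c(batch$S2[i, ], a2 / critic$dose_max))
    y <- batch$R[i] + gamma * q2
    q <- manual_forward(critic$net,
                        c(batch$S[i, ], batch$A[i, ] / critic$dose_max))
    td_manual[i] <- q - y
  }
  up <- critic_td_update(critic, opt, critic, actor, batch, gamma = gamma)
  expect_equal(up$td, td_manual, tolerance = 1e-10)
  expect_equal(up$loss, mean(w * td_manual^2), tolerance = 1e-10)
  # zero-weight entries contribute nothing
  expect_equal(up$loss, mean(w * up$td^2))
})

test_that("the actor climbs a quadratic toy critic to its known optimum", {
  a_star <- c(2, 1)
  toy <- structure(list(
    q = function(S, A) -rowSums(sweep(A, 2, a_star)^2),
    grad = function(S, A) -2 * sweep(A, 2, a_star)),
    class = "critic_fn")
  actor <- make_actor(dose_max = c(5, 3), seed = 8)
  opt <- sedrl:::adam_init(actor$net, lr = 0.02)
  set.seed(9)
  S <- matrix(rnorm(32 * 14), 32)
  for (step in 1:2000) {
    up <- actor_dpg_update(actor, opt, toy, S)
    actor <- up$actor; opt <- up$opt
  }
  A_final <- sedrl:::actor_forward(actor, S)
  expect_lt(max(abs(sweep(A_final, 2, a_star))), 1e-2)
  expect_gt(up$objective, -1e-3)
})

test_that("a zero-gradient critic leaves the actor unchanged", {
  flat <- structure(list(q = function(S, A) rep(1, nrow(S)),
                         grad = function(S, A) matrix(0, nrow(S), 2)),
                    class = "critic_fn")
  actor <- make_actor(seed = 10)
  opt <- sedrl:::adam_init(actor$net, lr = 0.1)
  up <- actor_dpg_update(actor, opt, flat, matrix(rnorm(28), 2))
  expect_identical(up$actor$net$W, actor$net$W)
})

test_that("offline training is reproducible and stays within its buffer", {
  co <- generate_cohort(10, 10, seed = 31)
  pc <- preprocess_cohort(co$observations, seed = 31)
  cfg <- agent_config(n_steps = 200, critic_warmup = 50, log_every = 50,
                      batch_size = 16L, seed = 11)
  ag1 <- train_agent(pc, cfg, mode = "offline")
  ag2 <- train_agent(pc, cfg, mode = "offline")
  expect_identical(ag1$actor$net$W, ag2$actor$net$W)
  expect_identical(ag1$log, ag2$log)
  expect_s3_class(ag1, "ddpg_agent")
  expect_equal(nrow(ag1$log), 4L)
  # policy respects the per-drug bound
  S <- do.call(rbind, lapply(pc$trajectories, `[[`, "state"))
  A <- predict_doses(ag1, S)
  expect_true(all(A >= 0))
  expect_true(all(sweep(A, 2, ag1$dose_max, "<=")))
})

test_that("model-based training interacts with an environment", {
  co <- generate_cohort(6, 8, seed = 51)
  pc <- preprocess_cohort(co$observations, seed = 51)
  env <- synthetic_env(co$params, co$init, pc$stats, horizon = 8)
  cfg <- agent_config(n_steps = 150, critic_warmup = 30, log_every = 50,
                      buffer_capacity = 500, batch_size = 16, seed = 12)
  ag <- train_agent(env, cfg, mode = "model_based")
  expect_s3_class(ag, "ddpg_agent")
  expect_true(all(is.finite(ag$log$critic_loss)))
  expect_error(train_agent(list(), cfg, mode = "model_based"), "reset")
})
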
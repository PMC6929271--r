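test_that("step rewards implement both criteria", {
  expect_equal(step_reward("flexible", placement_valid = FALSE, is_terminal = FALSE), -10)
  expect_equal(step_reward("flexible", placement_valid = TRUE, is_terminal = FALSE), 0)
  expect_equal(step_reward("rigid", placement_valid = TRUE, is_terminal = FALSE), 0)
  expect_equal(step_reward("rigid", placement_valid = TRUE, is_terminal = TRUE, E = -4), 4)
  expect_equal(step_reward("flexible", placement_valid = FALSE, is_terminal = TRUE, E = -3), 3)
  expect_error(step_reward("rigid", TRUE, TRUE), "needs the final energy")
})

test_that("epsilon-greedy selection is uniform when exploring and greedy otherwise", {
  q <- hp_qtable(3)
  q_set(q, 5, 2, 2)
  set.seed(1)
  expect_equal(select_action(q, 5, epsilon = 0, valid_actions = 1:3), 2L)

  # epsilon = 1: empirical frequencies uniform within 3 sigma at 10,000 draws
  set.seed(2)
  draws <- replicate(10000, select_action(q, 99, epsilon = 1, valid_actions = 1:3))
  p <- 1 / 3
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(table(draws) - 10000 * p) < 3 * sigma))

  # all-zero row: uniform tie-break among maximizers
  set.seed(3)
  draws <- replicate(6000, select_action(q, 42, epsilon = 0, valid_actions = 1:3))
  expect_true(all(abs(table(draws) - 2000) < 3 * sqrt(6000 * p * (1 - p))))

  # deterministic tie-break picks the first maximizer
  expect_equal(select_action(q, 42, 0, 1:3, tie_break = "first"), 1L)
  expect_error(select_action(q, 1, 0.5, integer(0)), "dead end")
})

test_that("the Q update follows the one-step rule with terminal cutoff", {
  q <- hp_qtable(3)
  q_update(q, 1, 1, r = 0, s_next = 2, terminal = FALSE, alpha = 0.01, gamma = 0.9)
  expect_equal(q_row(q, 1)[1], 0)
  q_update(q, 1, 2, r = 4, s_next = 2, terminal = TRUE, alpha = 0.01, gamma = 0.9)
  expect_equal(q_row(q, 1)[2], 0.04)
  # bootstrap picks up the successor's maximum
  q_set(q, 2, 3, 1)
  q_update(q, 1, 1, r = 0, s_next = 2, terminal = FALSE, alpha = 0.5, gamma = 0.9)
  expect_equal(q_row(q, 1)[1], 0.5 * 0.9 * 1)
})

test_that("repeated sweeps on a two-step deterministic chain reach the Bellman fixed point", {
  # chain: s1 -a1-> s2 -a1-> terminal with reward 2; fixed point
  # Q(s2,a1) = 2, Q(s1,a1) = gamma * 2
  gamma <- 0.9
  q <- hp_qtable(1)
  for (sweep in 1:3000) {
    q_update(q, 1, 1, r = 0, s_next = 2, terminal = FALSE, alpha = 0.1, gamma = gamma)
    q_update(q, 2, 1, r = 2, s_next = 3, terminal = TRUE, alpha = 0.1, gamma = gamma)
  }
  expect_equal(q_row(q, 2)[1], 2, tolerance = 1e-6)
  expect_equal(q_row(q, 1)[1], gamma * 2, tolerance = 1e-6)
})

test_that("a two-residue episode takes exactly one action and earns |E| = 0", {
  cfg <- fast_cfg(episodes = 1, test_interval = 0, seed = 1)
  q <- hp_qtable(3)
  set.seed(1)
  out <- run_episode("HP", q, cfg)
  expect_true(out$complete)
  expect_equal(nrow(out$trajectory), 1L)
  expect_equal(out$trajectory$reward, 0)
  expect_equal(out$energy, 0)
})

test_that("rigid episodes always produce legal conformations", {
  cfg <- fast_cfg(episodes = 1, test_interval = 0, criterion = "rigid", seed = 5)
  q <- hp_qtable(3)
  set.seed(5)
  for (rep in 1:50) {
    out <- run_episode("HPHPPHHPH", q, cfg)
    if (out$complete) expect_true(is_legal(out$conformation))
  }
})

test_that("flexible episodes book -10 per overlap and |E| at the end", {
  cfg <- fast_cfg(episodes = 1, test_interval = 0, criterion = "flexible",
                  state_mode = "full4", seed = 3)
  q <- hp_qtable(4)
  set.seed(3)
  for (rep in 1:30) {
    out <- run_episode("HHPPHH", q, cfg)
    expect_true(out$complete)       # flexible never dead-ends
    tr <- out$trajectory
    # -10 applies to non-terminal overlaps only; a terminal overlap still
    # earns the |E| bonus
    expect_equal(sum(tr$reward == -10), sum(!tr$valid & !tr$terminal))
    expect_equal(sum(!tr$valid), out$invalid_steps)
    expect_equal(tr$reward[nrow(tr)], abs(out$energy))
    expect_equal(out$legal, out$invalid_steps == 0L)
  }
})

test_that("training is bitwise reproducible and matches the pure-R reference", {
  for (setup in list(list(criterion = "rigid", invalid_action = "reselect"),
                     list(criterion = "rigid", invalid_action = "mask"),
                     list(criterion = "flexible", invalid_action = "mask"))) {
    cfg <- fast_cfg(episodes = 300, test_interval = 50, seed = 11,
                    criterion = setup$criterion,
                    invalid_action = setup$invalid_action)
    a <- train("HPPHHPH", cfg, target_energy = -2)
    b <- train("HPPHHPH", cfg, target_energy = -2)
    expect_identical(a$curve, b$curve)

    ref <- train_reference("HPPHHPH", cfg, target_energy = -2)
    expect_identical(ref$curve$test_energy, a$curve$test_energy)
    expect_identical(ref$curve$legal, a$curve$legal)
    expect_equal(ref$n_states_visited, a$n_states_visited)
    # identical tables entry by entry
    qa <- a$qtable
    qr <- ref$qtable
    oa <- order(qa$state); or_ <- order(qr$state)
    expect_equal(qa$state[oa], qr$state[or_])
    expect_equal(unname(qa$q[oa, ]), unname(qr$q[or_, ]), tolerance = 1e-12)
  }
})

test_that("the greedy-rollout probe matches the reference too", {
  cfg <- fast_cfg(episodes = 200, test_interval = 40, seed = 4,
                  test_policy = "greedy")
  a <- train("HPPHHPH", cfg)
  ref <- train_reference("HPPHHPH", cfg)
  expect_identical(ref$curve$test_energy, a$curve$test_energy)
})

test_that("zero episodes produce an empty curve and pool", {
  fit <- train("HPPH", fast_cfg(episodes = 0, seed = 1))
  expect_equal(nrow(fit$curve), 0L)
  expect_length(fit$pool, 0L)
  expect_true(is.na(fit$best_energy))
})

test_that("short-sequence training converges to the oracle minimum", {
  # desk-scale convergence: most seeds reach E = -2 on the 7-mer
  finals <- vapply(1:5, function(s) {
    cfg <- hp_train_config(episodes = 1e5, test_interval = 1e4, seed = s,
                           return_q = FALSE)
    fit <- train("HPPHHPH", cfg, target_energy = -2)
    ifelse(is.na(fit$best_energy), 0L, fit$best_energy)
  }, integer(1))
  expect_gte(sum(finals == -2), 4)
})

test_that("Q values stay within the coarse reward bound", {
  cfg <- fast_cfg(episodes = 2e4, test_interval = 0, seed = 2)
  fit <- train("HPHHPHH", cfg)
  n <- 7
  bound <- max(10 * (n - 1), 2 * n) / (1 - cfg$gamma)
  expect_lte(fit$q_absmax, bound)
})

test_that("Q tables and configs round-trip through their file formats", {
  cfg <- fast_cfg(episodes = 500, test_interval = 100, seed = 6)
  fit <- train("HPHHPH", cfg)
  tmp <- tempfile(fileext = ".tsv")
  write_qtable(fit$qtable, tmp)
  back <- read_qtable(tmp)
  o1 <- order(fit$qtable$state); o2 <- order(back$state)
  expect_equal(back$state[o2], fit$qtable$state[o1])
  expect_equal(unname(back$q[o2, ]), unname(fit$qtable$q[o1, ]),
               tolerance = 1e-9)

  cf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(alpha = 0.05, episodes = 1000,
                            criterion = "flexible", state_mode = "full4"),
                       cf, auto_unbox = TRUE)
  cfg2 <- read_train_config(cf, overrides = list(episodes = 2000))
  expect_equal(cfg2$alpha, 0.05)
  expect_equal(cfg2$episodes, 2000L)
  expect_equal(cfg2$criterion, "flexible")
  skip_if_not_installed("yaml")
  cy <- tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.02", "epsilon: 0.3"), cy)
  cfg3 <- read_train_config(cy)
  expect_equal(cfg3$alpha, 0.02)
  expect_equal(cfg3$epsilon, 0.3)
  jsonlite::write_json(list(albha = 1), cf, auto_unbox = TRUE)
  expect_error(read_train_config(cf), "unknown config keys")
})

test_that("pool extraction follows argmax ties and keeps minimal legal leaves", {
  # force a unique greedy path: straight line
  q <- hp_qtable(3)
  s <- 1
  for (i in 1:3) { q_set(q, s, 2, 1); s <- transfer(s, 2, 3) }
  cfg <- fast_cfg(episodes = 1, seed = 1)
  out <- extract_pool(q, "HPPH", cfg)
  expect_length(out$pool, 1L)
  expect_equal(out$energy, 0L)
  expect_false(out$truncated)
  expect_equal(unname(out$pool[[1]]$coords[, "x"]), 0:3)

  # an untrained table ties everywhere: all legal walks are leaves, and for
  # an all-P sequence every one of them is optimal at E = 0
  qe <- hp_qtable(3)
  out <- extract_pool(qe, "PPPP", cfg, cap = 100)
  expect_true(all(vapply(out$pool, is_legal, logical(1))))
  expect_equal(out$energy, 0L)
})

test_that("trained pools contain distinct optimal structures", {
  cfg <- fast_cfg(episodes = 2e5, test_interval = 1e4, seed = 8)
  fit <- train("HHHPPPPHPHHPHH", cfg, target_energy = -5)
  if (!is.na(fit$pool_energy) && fit$pool_energy == -5) {
    expect_gte(length(fit$pool), 1L)
    for (conf in fit$pool) {
      expect_true(is_legal(conf))
      expect_equal(energy("HHHPPPPHPHHPHH", conf), -5)
    }
    keys <- vapply(fit$pool, function(cf) paste(t(cf$coords), collapse = ","),
                   character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
  pool2 <- extract_pool(fit$qtable, "HHHPPPPHPHHPHH", cfg, cap = 5000)
  expect_true(all(vapply(pool2$pool, is_legal, logical(1))))
})
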
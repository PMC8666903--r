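test_that("configuration validation catches impossible settings", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_agents = 1), "n_agents")
  expect_error(simulation_config(episodes_per_iteration = 0),
               "episodes_per_iteration")
  expect_error(simulation_config(epsilon = 1), "epsilon")
  expect_error(simulation_config(gamma = -2), "gamma")
  expect_error(simulation_config(condition = "network"), "condition")
})

test_that("initial populations are committed to the holistic seed language", {
  space <- default_space()
  cfg <- simulation_config()
  state <- init_population(cfg, space)
  expect_length(state$posteriors, 10L)
  expect_setequal(state$ages, 0:9)
  expect_identical(state$ages[which.max(state$ages)], 9L)
  for (i in seq_len(10L)) {
    expect_equal(unname(class_mass(state$posteriors[[i]], space)),
                 c(0, 1, 0, 0))
  }
})

test_that("turnover removes the oldest, adds an untrained newborn, and keeps ages {0..n-1}", {
  space <- default_space()
  cfg <- simulation_config(n_iterations = 5L, gamma = 100,
                           condition = "midlife", seed = 31L)
  state <- init_population(cfg, space)
  oldest_id <- state$agent_ids[which.max(state$ages)]
  set.seed(31L)
  weights <- production_weights(space, cfg$gamma)
  for (it in 1:25) {
    state <- turnover(state, space)
    expect_setequal(state$ages, 0:9)
    expect_false(oldest_id %in% state$agent_ids)
    newborn <- which(state$ages == 0L)
    expect_equal(state$posteriors[[newborn]], space$prior)
    oldest_id <- state$agent_ids[which.max(state$ages)]
    for (ep in 1:3) state <- run_episode(state, cfg, space, weights)
    expect_setequal(state$ages, 0:9)  # episodes never touch ages
  }
})

test_that("producer selection matches the transmission condition", {
  space <- default_space()
  cfg <- simulation_config()
  state <- init_population(cfg, space)
  expect_identical(state$ages[select_producer(state, "oldest")], 9L)
  expect_identical(state$ages[select_producer(state, "midlife")], 5L)
  broken <- state
  broken$ages <- rep(1L, 10L)
  expect_error(select_producer(broken, "oldest"), "distinct")
})

test_that("the analytic producer schedule gives 9 distinct producers, 5 older under midlife", {
  for (cond in c("oldest", "midlife")) {
    sched <- lifetime_producers(cond)
    expect_identical(nrow(sched), 9L)
    # Distinct birth offsets = distinct individuals.
    expect_identical(length(unique(sched$producer_birth_offset)), 9L)
  }
  expect_true(all(lifetime_producers("oldest")$producer_older))
  mid <- lifetime_producers("midlife")
  expect_identical(sum(mid$producer_older), 5L)
  expect_identical(sum(!mid$producer_older), 4L)
})

test_that("an episode changes exactly one posterior, never the producer's", {
  space <- default_space()
  cfg <- simulation_config(gamma = 100, epsilon = 0, condition = "oldest")
  state <- init_population(cfg, space)
  l0 <- find_language(space, c("ac", "bd", "pr", "qs"))
  weights <- production_weights(space, cfg$gamma)
  set.seed(17)
  for (rep in 1:30) {
    before <- state$posteriors
    state <- run_episode(state, cfg, space, weights)
    ep <- attr(state, "last_episode")
    expect_false(ep$learner == ep$producer)
    expect_identical(state$ages[ep$producer], 9L)
    # Noise-free point-mass producer emits its language's signal exactly.
    expect_identical(ep$s, unname(space$mapping[l0, ep$m]))
    changed <- which(vapply(seq_along(before), function(i) {
      !identical(before[[i]], state$posteriors[[i]])
    }, logical(1L)))
    expect_true(all(changed %in% ep$learner))
  }
})

test_that("emitted-signal error rate matches epsilon", {
  space <- default_space()
  p <- numeric(space$n_languages)
  l0 <- find_language(space, c("ac", "bd", "pr", "qs"))
  p[l0] <- 1
  set.seed(41)
  n <- 1e4
  correct <- replicate(n, {
    m <- sample.int(4L, 1L)
    s <- produce_signal(p, m, gamma = 100, epsilon = 0.05, space)
    s == space$mapping[l0, m]
  })
  sigma <- sqrt(0.95 * 0.05 / n)
  expect_lt(abs(mean(correct) - 0.95), 3 * sigma)
})

test_that("class masses aggregate the posterior exactly", {
  space <- default_space()
  cm <- class_mass(space$prior, space)
  expect_equal(sum(cm), 1, tolerance = 1e-12)
  tab <- oracle_prior_table()
  for (cls in language_class_levels) {
    expect_equal(unname(cm[cls]), sum(tab$prior[tab$class == cls]),
                 tolerance = 1e-12)
  }
  point <- make_initialized_agent(space, c("ac", "ad", "bc", "bd"))
  expect_equal(unname(class_mass(point$posterior, space)), c(0, 0, 1, 0))
})

test_that("simulations are reproducible and record normalised traces", {
  space <- default_space()
  cfg <- simulation_config(n_iterations = 30L, gamma = 100,
                           condition = "midlife", seed = 91L)
  tr1 <- run_simulation(cfg, space)
  tr2 <- run_simulation(cfg, space)
  expect_identical(tr1, tr2)
  expect_identical(nrow(tr1), 30L)
  mass <- as.matrix(tr1[language_class_levels])
  expect_true(all(abs(rowSums(mass) - 1) < 1e-10))
  expect_true(all(mass >= 0))
  # After the first turnover the oldest agent is still an initial agent.
  expect_equal(tr1$holistic[1L], 1)
})
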
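#' Simulation configuration
#'
#' Bundles and validates every parameter of one simulation run. Defaults
#' are the headline study conditions: 10 agents, 20 communication/learning
#' episodes per iteration, error rate `epsilon = 0.05`, initial holistic
#' language `ac bd pr qs`, and 2000 iterations (200 generations, one
#' generation being a complete replacement of the population). The
#' learning-from-learners condition is typically run for 200 iterations
#' because its dynamics are an order of magnitude faster.
#'
#' @param n_agents Population size (>= 2; default 10).
#' @param episodes_per_iteration Communication/learning episodes between
#'   consecutive turnovers (default 20).
#' @param n_iterations Number of turnover iterations (default 2000).
#' @param epsilon Shared error rate for production noise and the learner's
#'   likelihood (default 0.05).
#' @param gamma Communicative rationality exponent; 0 ignores ambiguity,
#'   large values (e.g. 100) forbid it in practice.
#' @param condition Producer-selection rule: `"oldest"` (vertical
#'   transmission, the most experienced agent always produces) or
#'   `"midlife"` (horizontal transmission, the producer is an agent half
#'   way through its lifespan, still learning).
#' @param initial_language Language every initial agent is committed to
#'   (default the holistic `ac bd pr qs`).
#' @param seed Integer seed; every random draw in the run derives from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_agents = 10L,
                              episodes_per_iteration = 20L,
                              n_iterations = 2000L,
                              epsilon = 0.05,
                              gamma = 0,
                              condition = c("oldest", "midlife"),
                              initial_language = c("ac", "bd", "pr", "qs"),
                              seed = 1L) {
  if (identical(condition, c("oldest", "midlife"))) condition <- "oldest"
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% c("oldest", "midlife")) {
    stop("`condition` must be \"oldest\" or \"midlife\"", call. = FALSE)
  }
  n_agents <- as.integer(n_agents)
  episodes_per_iteration <- as.integer(episodes_per_iteration)
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_agents) || n_agents < 2L) {
    stop("`n_agents` must be at least 2", call. = FALSE)
  }
  if (is.na(episodes_per_iteration) || episodes_per_iteration < 1L) {
    stop("`episodes_per_iteration` must be at least 1", call. = FALSE)
  }
  if (is.na(n_iterations) || n_iterations < 1L) {
    stop("`n_iterations` must be at least 1", call. = FALSE)
  }
  check_epsilon(epsilon)
  check_gamma(gamma)
  structure(
    list(n_agents = n_agents,
         episodes_per_iteration = episodes_per_iteration,
         n_iterations = n_iterations,
         epsilon = epsilon,
         gamma = gamma,
         condition = condition,
         initial_language = initial_language,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(x[[nm]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# The producer's age under each condition: the oldest agent, or the agent
# exactly half way through its lifespan (age n/2 of ages 0..n-1), the
# unique midlife rule under which a focal agent's lifetime producers split
# (n/2) older / (n/2 - 1) younger -- 5 older, 4 younger with 10 agents.
producer_age <- function(condition, n_agents) {
  switch(condition,
         oldest = n_agents - 1L,
         midlife = as.integer(n_agents %/% 2L),
         stop("unknown condition: ", condition, call. = FALSE))
}

#' Initialise a population
#'
#' Creates `n_agents` agents, each committed (point-mass posterior) to the
#' configured initial language. Ages are assigned 0 to `n_agents - 1` so
#' that turnover order is well defined from the first iteration; the
#' initial agents are interchangeable, so the assignment is unobservable.
#'
#' @param config A [simulation_config].
#' @param space A [enumerate_languages] result.
#' @return An object of class `population_state`: a list with `posteriors`
#'   (list of probability vectors, one per agent), `ages`, `agent_ids`,
#'   `next_id` and `iteration`.
#' @export
init_population <- function(config, space) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(space, "language_space"))
  l0 <- find_language(space, config$initial_language)
  p0 <- numeric(space$n_languages)
  p0[l0] <- 1
  n <- config$n_agents
  structure(
    list(posteriors = rep(list(p0), n),
         ages = seq_len(n) - 1L,
         agent_ids = seq_len(n),
         next_id = n + 1L,
         iteration = 0L),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> ", length(x$ages), " agents, iteration ",
      x$iteration, ", ages {", paste(sort(x$ages), collapse = ","), "}\n",
      sep = "")
  invisible(x)
}

#' Extract one agent from a population
#'
#' @param state A `population_state`.
#' @param i Position in the population (not the agent id).
#' @return An `agent` object.
#' @export
get_agent <- function(state, i) {
  stopifnot(inherits(state, "population_state"))
  new_agent(state$agent_ids[i], state$ages[i], state$posteriors[[i]])
}

#' Population turnover
#'
#' One birth-death step: the oldest agent is removed, every survivor ages
#' by one iteration, and a new untrained agent (posterior equal to the
#' prior, age 0) is added. After each turnover the age multiset is exactly
#' `{0, 1, ..., n_agents - 1}`.
#'
#' @param state A `population_state`.
#' @param space The `language_space` (source of the newborn's prior).
#' @return The updated `population_state`.
#' @export
turnover <- function(state, space) {
  stopifnot(inherits(state, "population_state"),
            inherits(space, "language_space"))
  oldest <- which.max(state$ages)
  state$posteriors[[oldest]] <- space$prior
  state$ages <- state$ages + 1L
  state$ages[oldest] <- 0L
  state$agent_ids[oldest] <- state$next_id
  state$next_id <- state$next_id + 1L
  state$iteration <- state$iteration + 1L
  state
}

#' Select the producing agent for an episode
#'
#' Deterministic given the condition: the oldest agent (`"oldest"`), or the
#' agent with age `n_agents %/% 2` (`"midlife"`), i.e. an agent still in
#' the process of learning.
#'
#' @param state A `population_state`.
#' @param condition `"oldest"` or `"midlife"`.
#' @return The position of the producer in the population.
#' @export
select_producer <- function(state, condition) {
  stopifnot(inherits(state, "population_state"))
  target <- producer_age(condition, length(state$ages))
  i <- which(state$ages == target)
  if (length(i) != 1L) {
    stop("population has no unique agent of age ", target,
         "; ages must be distinct", call. = FALSE)
  }
  i
}

#' Run one communication/learning episode
#'
#' A meaning is chosen uniformly at random; the condition's producer emits
#' a signal for it (posterior-weighted ambiguity-penalised argmax plus
#' production noise); a different, uniformly chosen agent observes the
#' meaning-signal pair and updates its posterior. Exactly one agent's
#' posterior changes.
#'
#' @param state A `population_state`.
#' @param config A `simulation_config`.
#' @param space The `language_space`.
#' @param weights Optional precomputed production weights for
#'   `config$gamma` (internal cache used by [run_simulation]).
#' @return The updated `population_state`, with an attribute
#'   `"last_episode"` recording `m`, `producer`, `s_p`, `s` and `learner`
#'   (positions and indices) for inspection.
#' @export
run_episode <- function(state, config, space, weights = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(weights)) weights <- production_weights(space, config$gamma)
  n <- length(state$ages)
  n_signals <- space$inventory$n_signals

  m <- sample.int(space$n_meanings, 1L)
  producer <- select_producer(state, config$condition)
  scores <- drop(crossprod(weights[[m]], state$posteriors[[producer]]))
  s_p <- choose_signal(scores)
  s <- apply_production_noise(s_p, config$epsilon, n_signals)
  learner <- sample.int(n - 1L, 1L)
  if (learner >= producer) learner <- learner + 1L

  w <- state$posteriors[[learner]] *
    likelihood_vector(space, m, s, config$epsilon)
  state$posteriors[[learner]] <- w / sum(w)

  attr(state, "last_episode") <-
    list(m = m, producer = producer, s_p = s_p, s = s, learner = learner)
  state
}

#' Posterior mass per language class
#'
#' Aggregates a posterior over the 4096 languages into the four class
#' masses (degenerate, holistic, combinatorial, other).
#'
#' @param posterior Probability vector over the language space.
#' @param space The `language_space`.
#' @return Named numeric vector of the four masses; sums to 1.
#' @export
class_mass <- function(posterior, space) {
  stopifnot(inherits(space, "language_space"),
            length(posterior) == space$n_languages)
  vapply(space$class_index[language_class_levels],
         function(ix) sum(posterior[ix]), numeric(1L))
}

#' Run one simulation
#'
#' The full turnover-and-interaction loop. Each iteration: (1) the oldest
#' agent is removed and an untrained newborn added; (2)
#' `episodes_per_iteration` communication/learning episodes take place;
#' (3) the oldest agent's posterior, aggregated into the four language
#' classes, is recorded. Runs are bit-for-bit reproducible from
#' `config$seed`.
#'
#' @param config A [simulation_config].
#' @param space A [enumerate_languages] result.
#' @return A `class_mass_trace`: a data frame with columns `iteration`,
#'   `degenerate`, `holistic`, `combinatorial`, `other` (one row per
#'   iteration; the four masses sum to 1), carrying the config as
#'   attribute `"config"`.
#' @examples
#' \donttest{
#' space <- enumerate_languages()
#' cfg <- simulation_config(n_iterations = 50, gamma = 100,
#'                          condition = "midlife", seed = 42)
#' trace <- run_simulation(cfg, space)
#' tail(trace)
#' }
#' @export
run_simulation <- function(config, space) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(space, "language_space"))
  set.seed(config$seed)
  weights <- production_weights(space, config$gamma)
  state <- init_population(config, space)
  n_iter <- config$n_iterations
  masses <- matrix(NA_real_, nrow = n_iter, ncol = 4L,
                   dimnames = list(NULL, language_class_levels))
  for (it in seq_len(n_iter)) {
    state <- turnover(state, space)
    for (ep in seq_len(config$episodes_per_iteration)) {
      state <- run_episode(state, config, space, weights)
    }
    oldest <- which.max(state$ages)
    masses[it, ] <- class_mass(state$posteriors[[oldest]], space)
  }
  new_trace(masses, config)
}

new_trace <- function(masses, config) {
  out <- data.frame(iteration = seq_len(nrow(masses)), masses)
  attr(out, "config") <- config
  class(out) <- c("class_mass_trace", "data.frame")
  out
}

#' Deterministic lifetime producer schedule of a focal agent
#'
#' Enumerates, analytically (no simulation), the producers a focal agent
#' can hear during its life under a transmission condition. In each
#' iteration of the focal agent's life (except the one where it is itself
#' the producer) the producer is the unique agent of the condition's
#' producer age; its birth time relative to the focal agent identifies it.
#' Under either condition the focal agent meets `n_agents - 1` distinct
#' producers; under `"midlife"` with 10 agents exactly 5 are older and 4
#' younger than the focal agent.
#'
#' @param condition `"oldest"` or `"midlife"`.
#' @param n_agents Population size (default 10).
#' @return A data frame with one row per iteration in which the focal
#'   agent can learn: `focal_age`, `producer_age`, `producer_birth_offset`
#'   (iterations the producer was born before the focal agent; positive
#'   means older) and `producer_older` (logical).
#' @export
lifetime_producers <- function(condition = c("oldest", "midlife"),
                               n_agents = 10L) {
  condition <- match.arg(condition)
  n_agents <- as.integer(n_agents)
  stopifnot(n_agents >= 2L)
  p_age <- producer_age(condition, n_agents)
  focal_age <- setdiff(seq_len(n_agents) - 1L, p_age)
  data.frame(
    focal_age = focal_age,
    producer_age = p_age,
    producer_birth_offset = p_age - focal_age,
    producer_older = p_age > focal_age
  )
}
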
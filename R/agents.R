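#' Likelihood of a signal given language, meaning and noise rate
#'
#' The learner's (unnormalised) observation model: a producer using language
#' `l` emits the signal paired with the meaning with probability close to 1,
#' \deqn{P(s \mid l, m) \propto (1-\epsilon) \textrm{ if } s \textrm{ paired with } m,\quad \epsilon/3 \textrm{ otherwise.}}
#' The off-diagonal mass is split over `n_wrong = 3` incorrect signals; this
#' constant is kept at 3 for the default eight-signal space and can be set
#' to `n_signals - 1` for other inventories.
#'
#' @param s Signal index (1-based) or token.
#' @param l Language: signal tokens or indices, one per meaning.
#' @param m Meaning index (1-based).
#' @param epsilon Error probability in `[0, 1)` (default 0.05).
#' @param inventory A [signal_inventory].
#' @param n_wrong Number of incorrect signals the error mass is split over
#'   (default 3).
#' @return The likelihood weight: `1 - epsilon` if `l` pairs `m` with `s`,
#'   else `epsilon / n_wrong`.
#' @examples
#' inv <- signal_inventory()
#' likelihood("ac", c("ac", "bd", "pr", "qs"), 1, 0.05, inv)  # 0.95
#' likelihood("pr", c("ac", "bd", "pr", "qs"), 1, 0.05, inv)  # 0.05/3
#' @export
likelihood <- function(s, l, m, epsilon = 0.05, inventory = signal_inventory(),
                       n_wrong = 3L) {
  check_epsilon(epsilon)
  idx <- as_language(l, inventory)
  s_idx <- as_language(s, inventory)
  m <- as.integer(m)
  stopifnot(length(s_idx) == 1L, m >= 1L, m <= length(idx))
  if (idx[m] == s_idx) 1 - epsilon else epsilon / n_wrong
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon >= 1) {
    stop("`epsilon` must be a single number in [0, 1)", call. = FALSE)
  }
  invisible(epsilon)
}

# Likelihood weights for one (meaning, signal) observation over every
# language in the space at once. The workhorse of posterior updating.
likelihood_vector <- function(space, m, s_idx, epsilon, n_wrong = 3L) {
  paired <- space$mapping[, m] == s_idx
  out <- rep.int(epsilon / n_wrong, space$n_languages)
  out[paired] <- 1 - epsilon
  out
}

new_agent <- function(agent_id, age, posterior) {
  structure(
    list(agent_id = as.integer(agent_id), age = as.integer(age),
         posterior = posterior),
    class = "agent"
  )
}

#' @export
print.agent <- function(x, ...) {
  cat("<agent> id ", x$agent_id, ", age ", x$age, ", posterior over ",
      length(x$posterior), " languages\n", sep = "")
  invisible(x)
}

#' Create an untrained agent
#'
#' A newborn learner: age 0 and posterior equal to the simplicity prior
#' (with no data the posterior is the prior).
#'
#' @param space A [enumerate_languages] result.
#' @param agent_id Integer identifier.
#' @return An `agent`: list with `agent_id`, `age`, `posterior`.
#' @export
make_untrained_agent <- function(space, agent_id = 1L) {
  stopifnot(inherits(space, "language_space"))
  new_agent(agent_id, 0L, space$prior)
}

#' Create an agent committed to a single language
#'
#' Used to seed initial populations: the posterior is a point mass on `l0`,
#' the limiting case of an agent trained on unlimited data from that
#' language.
#'
#' @param space A `language_space`.
#' @param l0 The language: signal tokens, signal indices, or a single
#'   language id.
#' @param agent_id Integer identifier.
#' @param age Initial age (iterations survived).
#' @return An `agent` whose posterior puts probability 1 on `l0`.
#' @export
make_initialized_agent <- function(space, l0, agent_id = 1L, age = 0L) {
  stopifnot(inherits(space, "language_space"))
  id <- if (length(l0) == 1L && is.numeric(l0)) {
    id <- as.integer(l0)
    if (is.na(id) || id < 1L || id > space$n_languages) {
      stop("language id out of range", call. = FALSE)
    }
    id
  } else {
    find_language(space, l0)
  }
  posterior <- numeric(space$n_languages)
  posterior[id] <- 1
  new_agent(agent_id, age, posterior)
}

#' Export a posterior snapshot as CSV
#'
#' Writes one row per language with columns `language_id` and
#' `probability`, at full precision.
#'
#' @param posterior Probability vector over the language space (e.g. an
#'   agent's `$posterior`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_posterior <- function(posterior, path) {
  df <- data.frame(language_id = seq_along(posterior),
                   probability = sprintf("%.17g", posterior))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Update an agent's posterior with one meaning-signal pair
#'
#' Bayes' rule applied incrementally: the posterior is multiplied by the
#' likelihood of the observed pair under every language and renormalised.
#' Sequential updates over a set of observations equal the batch
#' prior-times-product-of-likelihoods computation, so observation order
#' does not matter and agents need not store their data.
#'
#' @param agent An `agent`.
#' @param m Observed meaning index (1-based).
#' @param s Observed signal: index or token.
#' @param space The `language_space` the posterior is defined over.
#' @param epsilon Perception/production error rate used in the likelihood.
#' @param n_wrong Incorrect-signal count in the likelihood denominator.
#' @return The agent with updated posterior.
#' @export
update_posterior <- function(agent, m, s, space, epsilon = 0.05, n_wrong = 3L) {
  stopifnot(inherits(agent, "agent"), inherits(space, "language_space"))
  check_epsilon(epsilon)
  m <- as.integer(m)
  stopifnot(m >= 1L, m <= space$n_meanings)
  s_idx <- as_language(s, space$inventory)
  stopifnot(length(s_idx) == 1L)
  w <- agent$posterior * likelihood_vector(space, m, s_idx, epsilon, n_wrong)
  total <- sum(w)
  if (total <= 0 || !is.finite(total)) {
    stop("posterior update degenerated to zero mass (epsilon = 0 with ",
         "inconsistent data?)", call. = FALSE)
  }
  agent$posterior <- w / total
  agent
}
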
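#' Communicative weight of a signal given a language and meaning
#'
#' The ambiguity-penalised weight a rational speaker assigns to emitting
#' signal `s` for meaning `m` if language `l` were true:
#' \deqn{C(s \mid l, m) = (1/a)^\gamma \textrm{ if } s \textrm{ paired with } m \textrm{ in } l, \quad 0 \textrm{ otherwise,}}
#' where `a` is the ambiguity of `s` in `l` (how many meanings it covers).
#' With `gamma = 0` any paired signal weighs 1 (the speaker ignores
#' ambiguity); as `gamma` grows, ambiguous signals are increasingly
#' avoided.
#'
#' @inheritParams classify_language
#' @param m Meaning index (1-based).
#' @param s Signal index or token.
#' @param gamma Communicative rationality exponent, `gamma >= 0`.
#' @return A weight in `[0, 1]`.
#' @export
communication_weight <- function(l, m, s, gamma, inventory = signal_inventory()) {
  check_gamma(gamma)
  idx <- as_language(l, inventory)
  s_idx <- as_language(s, inventory)
  m <- as.integer(m)
  stopifnot(length(s_idx) == 1L, m >= 1L, m <= length(idx))
  if (idx[m] != s_idx) return(0)
  a <- sum(idx == s_idx)
  (1 / a)^gamma
}

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0) {
    stop("`gamma` must be a single non-negative number", call. = FALSE)
  }
  invisible(gamma)
}

# Precompute, for a fixed gamma, the languages x signals weight matrix
# C(s | l, m) for every meaning: a list with one matrix per meaning.
# Production scores are then a single matrix-vector product per episode.
production_weights <- function(space, gamma) {
  stopifnot(inherits(space, "language_space"))
  check_gamma(gamma)
  inv_amb_gamma <- matrix(0, nrow = space$n_languages,
                          ncol = space$inventory$n_signals)
  used <- space$ambiguity > 0L
  inv_amb_gamma[used] <- (1 / space$ambiguity[used])^gamma
  lapply(seq_len(space$n_meanings), function(m) {
    w <- matrix(0, nrow = space$n_languages, ncol = space$inventory$n_signals)
    for (s in seq_len(space$inventory$n_signals)) {
      paired <- space$mapping[, m] == s
      w[paired, s] <- inv_amb_gamma[paired, s]
    }
    w
  })
}

#' Production scores for every signal
#'
#' The speaker's objective: for each candidate signal, the posterior-
#' weighted sum of its communicative weight,
#' \eqn{\mathrm{score}(s) = \sum_l P(l \mid d)\, C(s \mid l, m)}. Production
#' emits the argmax of these scores (see [choose_signal]).
#'
#' @param posterior Probability vector over the language space (an agent's
#'   posterior).
#' @param m Meaning index (1-based).
#' @param gamma Communicative rationality exponent.
#' @param space A `language_space`.
#' @param weights Optional precomputed weight matrices from an internal
#'   cache; when simulating many episodes with fixed `gamma` the caller
#'   passes these to avoid recomputation.
#' @return Numeric vector of non-negative scores, one per signal. Scores
#'   sum to at most 1 (each language contributes at most its posterior
#'   mass).
#' @export
signal_scores <- function(posterior, m, gamma, space, weights = NULL) {
  stopifnot(inherits(space, "language_space"),
            length(posterior) == space$n_languages)
  m <- as.integer(m)
  stopifnot(m >= 1L, m <= space$n_meanings)
  if (is.null(weights)) weights <- production_weights(space, gamma)
  drop(crossprod(weights[[m]], posterior))
}

#' Pick the best-scoring signal
#'
#' Argmax over production scores; ties are broken uniformly at random so
#' symmetric states (e.g. a newborn agent's prior) induce no systematic
#' bias toward low-index signals.
#'
#' @param scores Numeric vector of signal scores.
#' @return The chosen signal index.
#' @export
choose_signal <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 1L || any(!is.finite(scores))) {
    stop("`scores` must be finite numbers", call. = FALSE)
  }
  best <- which(scores == max(scores))
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' Apply production noise to a chosen signal
#'
#' The speaker emits the intended signal with probability `1 - epsilon`,
#' and otherwise a uniformly chosen different signal (each alternative with
#' probability `epsilon / (n_signals - 1)`), modelling errors in
#' production.
#'
#' @param s_p Intended signal index.
#' @param epsilon Production error probability in `[0, 1)`.
#' @param n_signals Size of the signal inventory.
#' @return The emitted signal index.
#' @export
apply_production_noise <- function(s_p, epsilon, n_signals) {
  check_epsilon(epsilon)
  s_p <- as.integer(s_p)
  stopifnot(s_p >= 1L, s_p <= n_signals)
  if (epsilon > 0 && stats::runif(1L) < epsilon) {
    others <- seq_len(n_signals)[-s_p]
    others[sample.int(n_signals - 1L, 1L)]
  } else {
    s_p
  }
}

#' Produce a signal for a meaning
#'
#' The full production pipeline: score every signal under the speaker's
#' posterior, take the argmax (random tie-break) and apply production
#' noise.
#'
#' @inheritParams signal_scores
#' @param epsilon Production error probability.
#' @return The emitted signal index.
#' @export
produce_signal <- function(posterior, m, gamma, epsilon, space, weights = NULL) {
  scores <- signal_scores(posterior, m, gamma, space, weights)
  s_p <- choose_signal(scores)
  apply_production_noise(s_p, epsilon, space$inventory$n_signals)
}
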
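#' Default signal inventory
#'
#' The eight two-character signals used throughout: \code{ac, bd, ad, bc,
#' pr, ps, qr, qs}. The first character of a signal plays the role of one
#' abstract phonological slot (e.g. location or syllable onset) and the
#' second character another (e.g. handshape or rhyme). Characters a, b only
#' co-occur with c, d and p, q only with r, s, so the inventory splits into
#' two 2 x 2 blocks.
#'
#' @format A character vector of length 8.
#' @export
default_signals <- c("ac", "bd", "ad", "bc", "pr", "ps", "qr", "qs")

#' Construct a signal inventory
#'
#' A signal inventory is the finite, ordered set of signal tokens available
#' to every language in the hypothesis space. All tokens must be distinct
#' strings of the same length.
#'
#' @param signals Character vector of signal tokens. Defaults to the
#'   eight-signal inventory in [default_signals].
#' @return An object of class `signal_inventory`: a list with elements
#'   `signals` (the tokens, order preserved), `n_signals` and
#'   `signal_length` (characters per token).
#' @examples
#' inv <- signal_inventory()
#' inv$n_signals     # 8
#' inv$signal_length # 2
#' @export
signal_inventory <- function(signals = default_signals) {
  if (!is.character(signals) || length(signals) < 1L || anyNA(signals)) {
    stop("`signals` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(signals)) {
    stop("all signals must be distinct", call. = FALSE)
  }
  len <- unique(nchar(signals))
  if (length(len) != 1L) {
    stop("all signals must have the same number of characters", call. = FALSE)
  }
  structure(
    list(signals = signals, n_signals = length(signals), signal_length = len),
    class = "signal_inventory"
  )
}

#' @export
print.signal_inventory <- function(x, ...) {
  cat("<signal_inventory> ", x$n_signals, " signals of length ",
      x$signal_length, ": ", paste(x$signals, collapse = " "), "\n", sep = "")
  invisible(x)
}

# Coerce a language given as signal tokens or 1-based signal indices into an
# integer index vector, validating against the inventory.
as_language <- function(l, inventory) {
  if (is.character(l)) {
    idx <- match(l, inventory$signals)
    if (anyNA(idx)) {
      stop("unknown signal token(s): ",
           paste(l[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(l)
  if (anyNA(idx) || any(idx < 1L) || any(idx > inventory$n_signals)) {
    stop("signal indices must lie in 1..", inventory$n_signals, call. = FALSE)
  }
  idx
}

# Character matrix of a language: one row per meaning, one column per
# within-signal position.
language_chars <- function(l, inventory) {
  idx <- as_language(l, inventory)
  do.call(rbind, strsplit(inventory$signals[idx], "", fixed = TRUE))
}

#' Classify a language
#'
#' Languages fall into four mutually exclusive classes:
#' \describe{
#'   \item{degenerate}{every meaning maps to the same signal (one distinct
#'     signal): maximally simple, inexpressive.}
#'   \item{combinatorial}{every meaning has a distinct signal and the
#'     signals are built by full recombination of a minimal set of character
#'     values per position (for the default space: exactly two distinct
#'     characters in each of the two positions). These are the languages
#'     with minimal pairs, i.e. duality of patterning.}
#'   \item{holistic}{every meaning has a distinct signal but without full
#'     combinatorial reuse of parts.}
#'   \item{other}{everything else, e.g. partially degenerate languages.}
#' }
#'
#' @param l A language: character vector of signal tokens (one per meaning)
#'   or integer vector of 1-based signal indices.
#' @param inventory A [signal_inventory].
#' @return One of `"degenerate"`, `"holistic"`, `"combinatorial"`, `"other"`.
#' @examples
#' inv <- signal_inventory()
#' classify_language(c("ac", "ac", "ac", "ac"), inv)  # degenerate
#' classify_language(c("ac", "ad", "bc", "bd"), inv)  # combinatorial
#' classify_language(c("ac", "bd", "pr", "qs"), inv)  # holistic
#' classify_language(c("ac", "ac", "pr", "qs"), inv)  # other
#' @export
classify_language <- function(l, inventory) {
  idx <- as_language(l, inventory)
  n_meanings <- length(idx)
  n_distinct <- length(unique(idx))
  if (n_distinct == 1L) {
    return("degenerate")
  }
  if (n_distinct < n_meanings) {
    return("other")
  }
  # All signals distinct: combinatorial iff the signals form the full
  # Cartesian product of the per-position character sets (full recombination
  # of parts); with the default 2-position signals this is "exactly two
  # distinct characters in each position".
  chars <- language_chars(idx, inventory)
  n_per_pos <- apply(chars, 2L, function(col) length(unique(col)))
  if (prod(n_per_pos) == n_meanings) "combinatorial" else "holistic"
}

#' Coding length of a language in bits
#'
#' The description length used by the simplicity prior. Writing the language
#' as the concatenation of its signals (8 characters in the default space),
#' each character occurrence \eqn{l_i} is coded with its within-language
#' relative frequency \eqn{p(l_i)}, giving
#' \deqn{L(l) = -\sum_i \log_2 p(l_i).}
#' Languages that reuse few characters are cheap to code: in the default
#' space every degenerate language costs 8 bits, every combinatorial
#' language 16 bits, and holistic languages cost up to 24 bits, the
#' maximum being attained exactly when no character is reused (e.g. the
#' canonical `ac bd pr qs`).
#'
#' @inheritParams classify_language
#' @return Coding length in bits (non-negative scalar).
#' @examples
#' inv <- signal_inventory()
#' coding_length(c("ac", "ac", "ac", "ac"), inv)  # 8
#' coding_length(c("ac", "ad", "bc", "bd"), inv)  # 16
#' coding_length(c("ac", "bd", "pr", "qs"), inv)  # 24
#' @export
coding_length <- function(l, inventory) {
  chars <- as.vector(language_chars(l, inventory))
  counts <- table(chars)
  n <- length(chars)
  -sum(counts * log2(counts / n))
}

#' Enumerate the full hypothesis space of languages
#'
#' Builds every total mapping from meanings to signals (signals may be
#' shared across meanings), classifies each language, computes its coding
#' length and the normalised simplicity prior \eqn{P(l) \propto 2^{-L(l)}}.
#' With the default inventory and 4 meanings the space holds
#' \eqn{8^4 = 4096} languages partitioned into 8 degenerate, 1632 holistic,
#' 48 combinatorial and 2408 other.
#'
#' Enumeration order is a fixed mixed-radix scheme over meaning positions
#' with the signal index varying fastest on the last meaning, so language
#' ids are stable across runs and platforms.
#'
#' @param inventory A [signal_inventory].
#' @param n_meanings Number of distinct atomic meanings (default 4).
#' @return An object of class `language_space`: a list with elements
#'   `inventory`, `n_meanings`, `n_languages`, `mapping` (integer matrix,
#'   one row per language, one column per meaning, entries are signal
#'   indices), `classes` (factor with levels degenerate, holistic,
#'   combinatorial, other), `coding_lengths` (bits), `prior` (sums to 1),
#'   `ambiguity` (languages x signals integer matrix of per-signal
#'   ambiguities) and `class_index` (list of language ids per class).
#' @examples
#' space <- enumerate_languages()
#' space$n_languages          # 4096
#' class_counts(space)
#' @export
enumerate_languages <- function(inventory = signal_inventory(), n_meanings = 4L) {
  if (!inherits(inventory, "signal_inventory")) {
    inventory <- signal_inventory(inventory)
  }
  n_meanings <- as.integer(n_meanings)
  if (is.na(n_meanings) || n_meanings < 1L) {
    stop("`n_meanings` must be a positive integer", call. = FALSE)
  }
  k <- inventory$n_signals
  if (k^n_meanings > 1e7) {
    stop("hypothesis space too large to enumerate (", k^n_meanings,
         " languages)", call. = FALSE)
  }
  n_lang <- as.integer(k^n_meanings)

  # Mixed-radix digits of 0..n_lang-1, most significant digit = meaning 1.
  ids0 <- seq_len(n_lang) - 1L
  mapping <- matrix(0L, nrow = n_lang, ncol = n_meanings)
  rem <- ids0
  for (j in rev(seq_len(n_meanings))) {
    mapping[, j] <- as.integer(rem %% k) + 1L
    rem <- rem %/% k
  }

  # Per-language character codes over the concatenated signal string.
  sig_chars <- do.call(rbind, strsplit(inventory$signals, "", fixed = TRUE))
  alphabet <- sort(unique(as.vector(sig_chars)))
  sig_codes <- matrix(match(sig_chars, alphabet), nrow = k)
  char_codes <- matrix(0L, nrow = n_lang,
                       ncol = n_meanings * inventory$signal_length)
  for (j in seq_len(n_meanings)) {
    cols <- (j - 1L) * inventory$signal_length + seq_len(inventory$signal_length)
    char_codes[, cols] <- sig_codes[mapping[, j], , drop = FALSE]
  }
  n_chars <- ncol(char_codes)
  n_alpha <- length(alphabet)
  coding_lengths <- apply(char_codes, 1L, function(row) {
    tb <- tabulate(row, nbins = n_alpha)
    tb <- tb[tb > 0L]
    -sum(tb * log2(tb / n_chars))
  })

  classes <- apply(mapping, 1L, classify_language, inventory = inventory)
  classes <- factor(classes, levels = language_class_levels)

  w <- 2^(-coding_lengths)
  prior <- w / sum(w)

  amb <- matrix(0L, nrow = n_lang, ncol = k)
  for (s in seq_len(k)) {
    amb[, s] <- as.integer(rowSums(mapping == s))
  }

  structure(
    list(
      inventory = inventory,
      n_meanings = n_meanings,
      n_languages = n_lang,
      mapping = mapping,
      classes = classes,
      coding_lengths = coding_lengths,
      prior = prior,
      ambiguity = amb,
      class_index = split(seq_len(n_lang), classes)
    ),
    class = "language_space"
  )
}

#' Language class labels
#'
#' The fixed ordering of the four language classes used in factors, traces
#' and plots.
#' @export
language_class_levels <- c("degenerate", "holistic", "combinatorial", "other")

#' @export
print.language_space <- function(x, ...) {
  cat("<language_space> ", x$n_languages, " languages = ",
      x$inventory$n_signals, " signals ^ ", x$n_meanings, " meanings\n",
      sep = "")
  print(class_counts(x))
  invisible(x)
}

#' Count languages per class
#'
#' @param space A [enumerate_languages] result.
#' @return Named integer vector over the four classes; sums to
#'   `space$n_languages`.
#' @export
class_counts <- function(space) {
  stopifnot(inherits(space, "language_space"))
  tab <- table(space$classes)
  out <- as.integer(tab[language_class_levels])
  names(out) <- language_class_levels
  out
}

#' Simplicity prior over the language space
#'
#' Normalises \eqn{2^{-L(l)}} over all languages, so that more complex
#' (longer-coded) languages get lower prior probability. The ratio between
#' two languages' priors is \eqn{2^{L_2 - L_1}}: a degenerate language (8
#' bits) is \eqn{2^{16}} times more probable a priori than a holistic one
#' (24 bits).
#'
#' @param space A `language_space` with coding lengths populated.
#' @return Numeric probability vector aligned with the enumeration order;
#'   sums to 1.
#' @export
compute_prior <- function(space) {
  stopifnot(inherits(space, "language_space"))
  w <- 2^(-space$coding_lengths)
  w / sum(w)
}

#' Ambiguity of a signal within a language
#'
#' The number of meanings the signal expresses in that language. An unused
#' signal has ambiguity 0; in a degenerate language the shared signal has
#' ambiguity equal to the number of meanings.
#'
#' @inheritParams classify_language
#' @param s Signal: token or 1-based index into the inventory.
#' @return Integer count in `0..length(l)`.
#' @examples
#' inv <- signal_inventory()
#' ambiguity(c("ac", "ac", "ac", "ac"), "ac", inv)  # 4
#' ambiguity(c("ac", "ac", "pr", "qs"), "ac", inv)  # 2
#' @export
ambiguity <- function(l, s, inventory) {
  idx <- as_language(l, inventory)
  s_idx <- as_language(s, inventory)
  if (length(s_idx) != 1L) stop("`s` must be a single signal", call. = FALSE)
  sum(idx == s_idx)
}

#' Look up a language id by its signals
#'
#' @param space A `language_space`.
#' @param signals Character vector of signal tokens, one per meaning (or
#'   integer signal indices).
#' @return The language id (row of `space$mapping`).
#' @examples
#' space <- enumerate_languages()
#' id <- find_language(space, c("ac", "bd", "pr", "qs"))
#' space$classes[id]  # holistic
#' @export
find_language <- function(space, signals) {
  stopifnot(inherits(space, "language_space"))
  idx <- as_language(signals, space$inventory)
  if (length(idx) != space$n_meanings) {
    stop("language must give one signal per meaning (", space$n_meanings, ")",
         call. = FALSE)
  }
  hit <- which(colSums(t(space$mapping) != idx) == 0L)
  if (length(hit) != 1L) stop("language not found in space", call. = FALSE)
  hit
}

#' Format languages as signal strings
#'
#' @param space A `language_space`.
#' @param ids Language ids (default all).
#' @return Character vector like `"ac bd pr qs"`.
#' @export
language_labels <- function(space, ids = seq_len(space$n_languages)) {
  stopifnot(inherits(space, "language_space"))
  apply(space$mapping[ids, , drop = FALSE], 1L,
        function(row) paste(space$inventory$signals[row], collapse = " "))
}

#' Export the enumerated language space as CSV
#'
#' Writes one row per language with columns `language_id`,
#' `signal_per_meaning` (space-separated tokens), `class`,
#' `coding_length_bits` and `prior`.
#'
#' @param space A `language_space`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_language_space <- function(space, path) {
  stopifnot(inherits(space, "language_space"))
  df <- data.frame(
    language_id = seq_len(space$n_languages),
    signal_per_meaning = language_labels(space),
    class = as.character(space$classes),
    coding_length_bits = space$coding_lengths,
    prior = space$prior,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
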
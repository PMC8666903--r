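# Independent brute-force oracles used to pin expected values. These work
# directly on signal strings via expand.grid and string operations, sharing
# no code path with the package internals they check.

oracle_signals <- c("ac", "bd", "ad", "bc", "pr", "ps", "qr", "qs")

# Every language as a row of four signal strings.
oracle_all_languages <- function(signals = oracle_signals, n_meanings = 4L) {
  grid <- do.call(expand.grid,
                  c(rep(list(signals), n_meanings),
                    list(stringsAsFactors = FALSE)))
  as.matrix(grid[, rev(seq_len(n_meanings)), drop = FALSE])
}

oracle_classify <- function(sig_row) {
  uniq <- unique(sig_row)
  if (length(uniq) == 1L) return("degenerate")
  if (length(uniq) < length(sig_row)) return("other")
  first <- unique(substr(sig_row, 1L, 1L))
  second <- unique(substr(sig_row, 2L, 2L))
  if (length(first) == 2L && length(second) == 2L) "combinatorial"
  else "holistic"
}

oracle_coding_length <- function(sig_row) {
  chars <- unlist(strsplit(paste0(sig_row, collapse = ""), ""))
  freq <- table(chars) / length(chars)
  -sum(log2(freq[chars]))
}

# Normalising constant of the simplicity prior and the prior mass of a class.
oracle_prior_table <- function() {
  langs <- oracle_all_languages()
  L <- apply(langs, 1L, oracle_coding_length)
  cls <- apply(langs, 1L, oracle_classify)
  w <- 2^(-L)
  list(labels = apply(langs, 1L, paste, collapse = " "),
       class = cls, bits = L, prior = w / sum(w))
}

# Batch Bayes: prior times product of likelihoods over all observations,
# keyed by language label so enumeration order never matters.
# obs: data.frame with columns m (meaning index) and s (signal token).
oracle_batch_posterior <- function(obs, epsilon = 0.05) {
  langs <- oracle_all_languages()
  L <- apply(langs, 1L, oracle_coding_length)
  w <- 2^(-L)
  for (k in seq_len(nrow(obs))) {
    lik <- ifelse(langs[, obs$m[k]] == obs$s[k], 1 - epsilon, epsilon / 3)
    w <- w * lik
  }
  p <- w / sum(w)
  names(p) <- apply(langs, 1L, paste, collapse = " ")
  p
}

# Align a package posterior (enumeration order) with an oracle posterior
# (named by language label).
align_posterior <- function(posterior, space) {
  names(posterior) <- language_labels(space)
  posterior
}

default_space <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- enumerate_languages()
    cache
  }
})
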
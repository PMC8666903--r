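test_that("default enumeration matches brute-force class census", {
  space <- default_space()
  expect_equal(space$n_languages, 4096L)
  expect_equal(nrow(space$mapping), 4096L)

  oracle_cls <- apply(oracle_all_languages(), 1L, oracle_classify)
  oracle_counts <- table(factor(oracle_cls, language_class_levels))
  counts <- class_counts(space)
  expect_identical(unname(counts), as.integer(oracle_counts))
  expect_identical(counts[["degenerate"]], 8L)
  expect_identical(counts[["holistic"]], 1632L)
  expect_identical(counts[["combinatorial"]], 48L)
  expect_identical(counts[["other"]], 2408L)
  expect_identical(sum(counts), 4096L)

  # Census agrees language-by-language with the string-based oracle.
  oracle_by_label <- stats::setNames(oracle_cls,
                                     apply(oracle_all_languages(), 1L,
                                           paste, collapse = " "))
  expect_identical(unname(oracle_by_label[language_labels(space)]),
                   as.character(space$classes))
})

test_that("worked classification examples land in the stated classes", {
  inv <- signal_inventory()
  expect_identical(classify_language(c("ac", "ac", "ac", "ac"), inv),
                   "degenerate")
  expect_identical(classify_language(c("ac", "bd", "pr", "qs"), inv),
                   "holistic")
  expect_identical(classify_language(c("ac", "ad", "bc", "bd"), inv),
                   "combinatorial")
  expect_identical(classify_language(c("ac", "ac", "pr", "qs"), inv),
                   "other")
})

test_that("coding lengths reproduce the worked values and are constant per class", {
  inv <- signal_inventory()
  expect_equal(coding_length(c("ac", "ac", "ac", "ac"), inv), 8)
  expect_equal(coding_length(c("ac", "ad", "bc", "bd"), inv), 16)
  expect_equal(coding_length(c("ac", "bd", "pr", "qs"), inv), 24)
  # character counts a:2 c:2 p:1 r:1 q:1 s:1 over 8 characters
  expect_equal(coding_length(c("ac", "ac", "pr", "qs"), inv), 20)

  space <- default_space()
  expect_true(all(space$coding_lengths[space$classes == "degenerate"] == 8))
  expect_true(all(space$coding_lengths[space$classes == "combinatorial"] == 16))
  # Holistic languages code at up to 24 bits; the maximum is attained
  # exactly when the four signals share no character (96 such languages,
  # including the canonical ac bd pr qs).
  hol_bits <- space$coding_lengths[space$classes == "holistic"]
  expect_true(all(hol_bits <= 24 + 1e-12))
  expect_identical(sum(abs(hol_bits - 24) < 1e-12), 96L)
  expect_true(all(space$coding_lengths >= 0))

  # Whole-space agreement with the independent string-based computation.
  oracle_bits <- apply(oracle_all_languages(), 1L, oracle_coding_length)
  names(oracle_bits) <- apply(oracle_all_languages(), 1L, paste,
                              collapse = " ")
  expect_equal(unname(oracle_bits[language_labels(space)]),
               space$coding_lengths, tolerance = 1e-12)
})

test_that("coding length is invariant under meaning permutation and character relabelling", {
  inv <- signal_inventory()
  space <- default_space()
  set.seed(4242)
  # a<->b swap keeps every token inside the inventory and preserves the
  # position structure of the signals.
  relabel <- function(sig) chartr("ab", "ba", sig)
  for (rep in 1:25) {
    id <- sample.int(space$n_languages, 1L)
    sigs <- strsplit(language_labels(space, id), " ")[[1L]]
    L0 <- coding_length(sigs, inv)
    expect_equal(coding_length(sample(sigs), inv), L0, tolerance = 1e-12)
    expect_equal(coding_length(relabel(sigs), inv), L0, tolerance = 1e-12)
  }
})

test_that("simplicity prior is normalised with the closed-form class ratios", {
  space <- default_space()
  expect_equal(sum(space$prior), 1, tolerance = 1e-12)
  expect_true(all(space$prior >= 0))
  expect_equal(compute_prior(space), space$prior, tolerance = 1e-15)

  p_deg <- space$prior[find_language(space, c("ac", "ac", "ac", "ac"))]
  p_hol <- space$prior[find_language(space, c("ac", "bd", "pr", "qs"))]
  p_com <- space$prior[find_language(space, c("ac", "ad", "bc", "bd"))]
  expect_equal(p_deg / p_hol, 2^16, tolerance = 1e-9)
  expect_equal(p_deg / p_com, 2^8, tolerance = 1e-9)
})

test_that("ambiguity counts meanings sharing a signal", {
  inv <- signal_inventory()
  expect_identical(ambiguity(c("ac", "ac", "ac", "ac"), "ac", inv), 4L)
  expect_identical(ambiguity(c("ac", "bd", "pr", "qs"), "pr", inv), 1L)
  expect_identical(ambiguity(c("ac", "ac", "pr", "qs"), "ac", inv), 2L)
  expect_identical(ambiguity(c("ac", "ac", "pr", "qs"), "bd", inv), 0L)
})

test_that("non-default spaces enumerate and classify sensibly", {
  one <- enumerate_languages(signal_inventory("ac"), n_meanings = 1L)
  expect_identical(one$n_languages, 1L)
  expect_identical(as.character(one$classes), "degenerate")
  expect_equal(one$prior, 1)

  two <- enumerate_languages(signal_inventory(c("ac", "bd")), n_meanings = 2L)
  expect_identical(two$n_languages, 4L)
  expect_equal(sum(two$prior), 1, tolerance = 1e-12)
  expect_identical(sum(two$classes == "degenerate"), 2L)
})

test_that("invalid configurations are rejected", {
  expect_error(signal_inventory(character(0)), "non-empty")
  expect_error(signal_inventory(c("ac", "ac")), "distinct")
  expect_error(signal_inventory(c("ac", "bda")), "same number")
  expect_error(enumerate_languages(signal_inventory(), n_meanings = 0),
               "positive")
  expect_error(classify_language(c("zz", "ac", "ac", "ac"),
                                 signal_inventory()), "unknown signal")
  expect_error(find_language(default_space(), c("ac", "bd")), "one signal per")
})

test_that("language-space CSV export round-trips the key columns", {
  space <- enumerate_languages(signal_inventory(c("ac", "bd")), 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_language_space(space, path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(df), c("language_id", "signal_per_meaning", "class",
                                "coding_length_bits", "prior"))
  expect_identical(nrow(df), 4L)
  expect_identical(df$signal_per_meaning, language_labels(space))
  expect_equal(df$prior, space$prior, tolerance = 1e-6)
})
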
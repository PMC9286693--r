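test_that("phoneme feature rows are injective, binary and non-empty", {
  ft <- phoneme_features()
  fm <- attr(ft, "matrix")
  expect_equal(ncol(fm), 22L)
  expect_true(all(fm %in% c(0, 1)))
  expect_false(anyDuplicated(apply(fm, 1L, paste, collapse = "")) > 0)
  expect_true(all(rowSums(fm) > 0))
})

test_that("the carrot example aligns as printed", {
  slots <- align_to_template(c("kh", "{", "r", "@", "t"), c(2L, 3L))
  expect_equal(format_alignment(slots), "kh _ _ { _ r _ _ @ _ t _ _")
})

test_that("monosyllables occupy only the leftmost template slots", {
  slots <- align_to_template(c("t", "a", "p"), 3L)
  expect_true(all(is.na(slots[9:13])))
  expect_equal(format_alignment(slots), "t _ _ a _ p _ _ _ _ _ _ _")
})

test_that("alignment is a bijection onto occupied slots", {
  lex <- fixture_lexicon()
  for (i in seq_len(nrow(lex$words))) {
    a <- lex$alignments[[i]]
    expect_equal(sum(!is.na(a)), lex$words$n_phonemes[i])
    ps <- attr(a, "phoneme_slots")
    expect_false(any(duplicated(ps)))
    p <- parse_sampa(lex$words$sampa[i])
    expect_equal(a[ps], p$phonemes)
  }
})

test_that("overfull syllables are rejected naming the syllable", {
  expect_error(align_to_template(c("s", "t", "r", "s", "a"), 5L),
               "syllable 1")
  expect_error(
    align_to_template(c("t", "a", "s", "t", "s", "t", "r", "a"), c(5L, 3L)),
    "syllable 2")
})

test_that("encoded phonology has length 292 with correct prosody bits", {
  v_di <- encode_phonology(c("kh", "{", "r", "@", "t"), c(2L, 3L),
                           stress = 1L, language = "A")
  v_mono <- encode_phonology(c("t", "a", "p"), 3L, language = "B")
  expect_length(v_di, 292L)
  expect_true(all(v_di %in% c(0, 1)))
  expect_equal(unname(v_di[287:288]), c(1, 1))   # disyllabic thermometer
  expect_equal(unname(v_mono[287:288]), c(0, 1)) # monosyllabic
  expect_equal(unname(v_mono[289:290]), c(1, 0)) # stress on syllable 1
  expect_equal(unname(v_di[291:292]), c(1, 0))   # language A one-hot
  expect_equal(unname(v_mono[291:292]), c(0, 1))
})

test_that("prosody and language switches zero the right bits", {
  v <- encode_phonology(c("t", "a", "p"), 3L, language = "A",
                        use_prosody = FALSE, language_unit = "none")
  expect_equal(unname(v[287:292]), rep(0, 6))
  v2 <- encode_phonology(c("t", "a", "p"), 3L, language = "A",
                         use_prosody = FALSE, language_unit = "B")
  expect_equal(unname(v2[291:292]), c(0, 1))
  # feature bits unaffected by the switches
  expect_equal(v[1:286], v2[1:286])
})

test_that("encoding is deterministic and onset-preserving", {
  a <- encode_phonology(c("t", "a", "p"), 3L)
  b <- encode_phonology(c("t", "a", "p"), 3L)
  expect_identical(a, b)
  # words sharing their first phonemes agree on the occupied onset slots
  x <- encode_phonology(c("t", "a", "p"), 3L, language = "A")
  y <- encode_phonology(c("t", "a", "s"), 3L, language = "A")
  expect_equal(x[1:110], y[1:110])  # slots 1-5 cover onset + nucleus
})

test_that("binarize_embedding thresholds strictly below -0.175", {
  expect_equal(binarize_embedding(numeric(300)), numeric(300))
  expect_equal(binarize_embedding(c(-0.2, -0.175, 0.3), n_bits = 3L),
               c(1, 0, 0))
  expect_error(binarize_embedding(numeric(299)), "length")
  set.seed(1)
  x <- rnorm(300)
  got <- binarize_embedding(x)
  want <- vapply(x, function(v) as.numeric(v < -0.175), numeric(1))
  expect_equal(got, want)
})

test_that("synthetic generator reproduces the requested structure", {
  lex <- generate_synthetic_lexicon(n_pairs = 121L,
                                    disyllabic_count = c(A = 39L, B = 45L),
                                    seed = 3L)
  expect_equal(nrow(lex$words), 242L)
  expect_equal(sum(lex$words$language == "A" & lex$words$n_syllables == 2), 39L)
  expect_equal(sum(lex$words$language == "B" & lex$words$n_syllables == 2), 45L)
  expect_equal(ncol(lex$phon), 292L)
  expect_equal(ncol(lex$sem), 300L)
  # identical semantics within a pair
  for (p in c(1L, 60L, 121L)) {
    rows <- lex$sem[lex$words$pair_id == p, , drop = FALSE]
    expect_equal(rows[1L, ], rows[2L, ])
  }
  lex2 <- generate_synthetic_lexicon(n_pairs = 121L,
                                     disyllabic_count = c(A = 39L, B = 45L),
                                     seed = 3L)
  expect_identical(lex$phon, lex2$phon)
  expect_identical(lex$sem, lex2$sem)
})

test_that("semantic popcount matches its binomial sampling distribution", {
  lex <- generate_synthetic_lexicon(n_pairs = 121L,
                                    disyllabic_count = c(A = 39L, B = 45L),
                                    sem_ones_target = 52.7, seed = 8L)
  pops <- rowSums(lex$sem_pairs)
  p0 <- 52.7 / 300
  # marginally every bit is Bernoulli(p0), so each popcount is
  # Binomial(300, p0); popcounts of same-cluster pairs are positively
  # correlated, so bound the SD of the mean by the single-vector binomial SD
  # over sqrt(n_clusters) (the worst case of full within-cluster correlation)
  sd_bin <- sqrt(300 * p0 * (1 - p0))
  expect_lt(abs(mean(pops) - 52.7), 3 * sd_bin / sqrt(12))
})

test_that("lexicon TSV round-trip is exact and invariants are enforced", {
  lex <- fixture_tiny_lexicon()
  path <- file.path(withr::local_tempdir(), "lex.tsv")
  save_lexicon(lex, path)
  lex2 <- load_lexicon(path)
  expect_equal(lex$words[c("orthography", "language", "sampa", "stress",
                           "pair_id")],
               lex2$words[c("orthography", "language", "sampa", "stress",
                            "pair_id")])
  expect_equal(unname(lex$phon), unname(lex2$phon))
  expect_equal(unname(lex$sem), unname(lex2$sem))

  # a row with 3 syllables is rejected with its line number
  bad <- lex$words
  bad$sampa[2] <- "t a . p a . k a"
  path2 <- file.path(withr::local_tempdir(), "bad.tsv")
  utils::write.table(bad[c("orthography", "language", "sampa", "stress",
                           "pair_id")],
                     path2, sep = "\t", quote = FALSE, row.names = FALSE)
  file.copy(paste0(path, ".sem.tsv"), paste0(path2, ".sem.tsv"))
  expect_error(load_lexicon(path2), "row 3")

  # a pair present in only one language is rejected
  bad2 <- lex$words[-1L, ]
  path3 <- file.path(withr::local_tempdir(), "bad2.tsv")
  utils::write.table(bad2[c("orthography", "language", "sampa", "stress",
                            "pair_id")],
                     path3, sep = "\t", quote = FALSE, row.names = FALSE)
  file.copy(paste0(path, ".sem.tsv"), paste0(path3, ".sem.tsv"))
  expect_error(load_lexicon(path3), "exactly one lexeme per language")
})
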
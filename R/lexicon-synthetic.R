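# Synthetic bilingual lexicon generator.  Emulates the statistics of the
# bilingual training vocabulary the simulations assume: 121 translation
# pairs per default, a mono/disyllabic mix (39 disyllables in language A, 45
# in language B), sparse binary semantics (~52.7 ones over 300 bits) with
# cluster structure, and identical semantics within a translation pair.

sample_syllable <- function(n_syll, which_syll, coda1 = 0L, features,
                            min_phonemes_left = 0L) {
  cons <- features$symbol[features$type == "C"]
  vows <- features$symbol[features$type == "V"]
  if (which_syll == 1L) {
    onset_n <- sample(0:3, 1L, prob = c(0.25, 0.45, 0.25, 0.05))
  } else {
    max_onset <- 3L - coda1
    onset_n <- sample(0:max_onset, 1L,
                      prob = c(0.3, 0.5, 0.15, 0.05)[seq_len(max_onset + 1L)])
  }
  nuc_n <- sample(1:2, 1L, prob = c(0.85, 0.15))
  coda_max <- if (which_syll == 1L && n_syll == 2L) 2L else 3L
  coda_n <- sample(0:coda_max, 1L,
                   prob = c(0.35, 0.45, 0.15, 0.05)[seq_len(coda_max + 1L)])
  c(sample(cons, onset_n, replace = TRUE),
    sample(vows, nuc_n, replace = TRUE),
    sample(cons, coda_n, replace = TRUE))
}

sample_word_form <- function(disyllabic, features) {
  n_syll <- if (disyllabic) 2L else 1L
  s1 <- sample_syllable(n_syll, 1L, features = features)
  cons <- features$symbol[features$type == "C"]
  vows <- features$symbol[features$type == "V"]
  ty1 <- phoneme_type(s1, features)
  coda1 <- sum(ty1 == "C") - (which(ty1 == "V")[1L] - 1L)
  if (n_syll == 2L) {
    s2 <- sample_syllable(n_syll, 2L, coda1 = coda1, features = features)
    phonemes <- c(s1, s2)
    syllable_lengths <- c(length(s1), length(s2))
  } else {
    phonemes <- s1
    syllable_lengths <- length(s1)
  }
  # masking and incremental presentation need at least two phonemes
  if (length(phonemes) < 2L) {
    phonemes <- c(phonemes, sample(cons, 1L))
    syllable_lengths[length(syllable_lengths)] <- syllable_lengths[length(syllable_lengths)] + 1L
  }
  list(phonemes = phonemes, syllable_lengths = syllable_lengths)
}

#' Generate a synthetic bilingual lexicon
#'
#' Samples phonotactically valid mono/disyllabic word forms from the fixed
#' phoneme inventory for both languages of every translation pair, and
#' cluster-structured sparse binary semantics shared within each pair.
#' Semantic vectors are drawn by sampling a cluster prototype with
#' independent Bernoulli bits of rate `sem_ones_target / 300` and then
#' resampling a fraction `flip_prob` of each member's bits from the same
#' Bernoulli rate, which leaves the expected popcount at `sem_ones_target`.
#' Fully reproducible from `seed`.
#'
#' @param n_pairs number of translation pairs (>= 4).
#' @param disyllabic_count number of disyllabic words per language, named
#'   vector `c(A = ..., B = ...)`.
#' @param sem_ones_target expected number of ones per 300-bit semantic
#'   vector.
#' @param n_sem_clusters number of semantic clusters.
#' @param flip_prob per-bit probability of resampling a cluster member's bit.
#' @param seed integer seed.
#' @param features phoneme feature table.
#' @return a [bilingual_lexicon()].
#' @export
generate_synthetic_lexicon <- function(n_pairs = 121L,
                                       disyllabic_count = c(A = 39L, B = 45L),
                                       sem_ones_target = 52.7,
                                       n_sem_clusters = 12L,
                                       flip_prob = 0.1,
                                       seed = 1L,
                                       features = phoneme_features()) {
  stopifnot(n_pairs >= 4L, all(disyllabic_count <= n_pairs))
  set.seed(seed)
  rows <- list()
  for (lg in c("A", "B")) {
    n_di <- disyllabic_count[[lg]]
    is_di <- c(rep(TRUE, n_di), rep(FALSE, n_pairs - n_di))
    seen <- character(0)
    for (p in seq_len(n_pairs)) {
      form <- NULL
      for (attempt in seq_len(200L)) {
        cand <- sample_word_form(is_di[p], features)
        stress <- if (length(cand$syllable_lengths) == 2L)
          sample(1:2, 1L, prob = c(0.7, 0.3)) else 1L
        sig <- paste(deparse_sampa(cand$phonemes, cand$syllable_lengths),
                     stress, sep = "|")
        if (!(sig %in% seen)) { form <- c(cand, stress = stress); seen <- c(seen, sig); break }
      }
      if (is.null(form))
        stop("could not generate distinct word forms for n_pairs = ", n_pairs)
      rows[[length(rows) + 1L]] <- data.frame(
        orthography = paste0(gsub("[^A-Za-z0-9]", "", paste(form$phonemes, collapse = "")),
                             "_", p),
        language = lg,
        sampa = deparse_sampa(form$phonemes, form$syllable_lengths),
        stress = form$stress,
        pair_id = p,
        stringsAsFactors = FALSE)
    }
  }
  words <- do.call(rbind, rows)

  p0 <- sem_ones_target / 300
  cluster <- rep_len(seq_len(n_sem_clusters), n_pairs)
  prototypes <- matrix(rbinom(n_sem_clusters * 300L, 1L, p0),
                       n_sem_clusters, 300L)
  sem <- matrix(0, n_pairs, 300L, dimnames = list(seq_len(n_pairs), NULL))
  for (p in seq_len(n_pairs)) {
    repeat {
      v <- prototypes[cluster[p], ]
      flip <- runif(300L) < flip_prob
      v[flip] <- rbinom(sum(flip), 1L, p0)
      key <- paste(v, collapse = "")
      if (!key %in% apply(sem[seq_len(p - 1L), , drop = FALSE], 1L,
                          paste, collapse = "")) break
    }
    sem[p, ] <- v
  }
  lex <- bilingual_lexicon(words, sem, features)
  lex$sem_clusters <- cluster
  lex
}
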
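# The bilingual lexicon container: translation pairs across two languages
# ("A" and "B" roles, e.g. English/Dutch), their phonological encodings and
# their shared semantic vectors.

parse_sampa <- function(sampa_string) {
  toks <- strsplit(trimws(sampa_string), "\\s+")[[1L]]
  breaks <- which(toks == ".")
  if (length(breaks) > 1L)
    stop("more than one syllable boundary marker '.'")
  if (length(breaks) == 1L) {
    if (breaks == 1L || breaks == length(toks))
      stop("syllable boundary at word edge")
    phonemes <- toks[-breaks]
    syllable_lengths <- c(breaks - 1L, length(toks) - breaks)
  } else {
    phonemes <- toks
    syllable_lengths <- length(toks)
  }
  list(phonemes = phonemes, syllable_lengths = syllable_lengths)
}

deparse_sampa <- function(phonemes, syllable_lengths) {
  if (length(syllable_lengths) == 2L) {
    paste(c(phonemes[seq_len(syllable_lengths[1L])], ".",
            phonemes[-seq_len(syllable_lengths[1L])]), collapse = " ")
  } else paste(phonemes, collapse = " ")
}

lexeme_key <- function(language, orthography) paste(language, orthography, sep = ":")

#' Construct a bilingual lexicon
#'
#' Assembles the package's central data structure from a word table and a
#' semantic matrix.  Validates the pairing structure (every `pair_id` occurs
#' exactly once per language), encodes every word's phonology (full training
#' encoding: prosody on, own language unit on) and checks that phonological
#' vectors are pairwise distinct within each language.  Translation
#' equivalents share one identical semantic vector.
#'
#' @param words data.frame with columns `orthography`, `language` (`"A"` or
#'   `"B"`), `sampa` (space-separated phoneme symbols with an optional `.`
#'   token marking the syllable boundary), `stress` (1 or 2) and `pair_id`.
#' @param sem binary matrix with one row per pair, rownames = `pair_id`.
#' @param features phoneme feature table.
#' @return an object of class `bilingual_lexicon`: list with elements
#'   `words` (the validated table plus derived columns), `phon` (n_words x
#'   292 encoding matrix, rownames `language:orthography`), `sem` (n_words x
#'   300, rows repeated within a pair), `sem_pairs` (n_pairs x 300) and
#'   `alignments` (per-word slot vectors).
#' @export
bilingual_lexicon <- function(words, sem, features = phoneme_features()) {
  req <- c("orthography", "language", "sampa", "stress", "pair_id")
  miss <- setdiff(req, names(words))
  if (length(miss)) stop("missing lexicon columns: ", paste(miss, collapse = ", "))
  words <- as.data.frame(words, stringsAsFactors = FALSE)
  if (!all(words$language %in% c("A", "B")))
    stop("language must be 'A' or 'B'")
  if (anyDuplicated(words[c("language", "orthography")]))
    stop("duplicate (language, orthography) entries")
  tab <- table(words$pair_id, words$language)
  if (!all(tab == 1L))
    stop("every pair_id must have exactly one lexeme per language")

  n <- nrow(words)
  parsed <- lapply(words$sampa, parse_sampa)
  words$n_phonemes <- vapply(parsed, function(p) length(p$phonemes), integer(1))
  words$n_syllables <- vapply(parsed, function(p) length(p$syllable_lengths), integer(1))
  if (any(words$stress > words$n_syllables))
    stop("stress index exceeds number of syllables for ",
         lexeme_key(words$language, words$orthography)[words$stress > words$n_syllables][1L])

  keys <- lexeme_key(words$language, words$orthography)
  phon <- matrix(0, n, PHON_BITS, dimnames = list(keys, NULL))
  alignments <- vector("list", n)
  for (i in seq_len(n)) {
    v <- encode_phonology(parsed[[i]]$phonemes, parsed[[i]]$syllable_lengths,
                          stress = words$stress[i], language = words$language[i],
                          use_prosody = TRUE, language_unit = "own",
                          features = features)
    phon[i, ] <- v
    alignments[[i]] <- align_to_template(parsed[[i]]$phonemes,
                                         parsed[[i]]$syllable_lengths, features)
  }
  for (lg in c("A", "B")) {
    sub <- phon[words$language == lg, , drop = FALSE]
    if (anyDuplicated(apply(sub, 1L, paste, collapse = "")))
      stop("phonological vectors are not distinct within language ", lg)
  }

  sem <- as.matrix(sem)
  if (ncol(sem) != 300L) stop("semantic matrix must have 300 columns")
  if (is.null(rownames(sem))) stop("semantic matrix needs pair_id rownames")
  idx <- match(as.character(words$pair_id), rownames(sem))
  if (anyNA(idx)) stop("missing semantic vector for pair_id ",
                       words$pair_id[is.na(idx)][1L])
  sem_words <- sem[idx, , drop = FALSE]
  rownames(sem_words) <- keys
  names(alignments) <- keys
  structure(list(words = words, phon = phon, sem = sem_words,
                 sem_pairs = sem, alignments = alignments,
                 features = features),
            class = "bilingual_lexicon")
}

#' @export
print.bilingual_lexicon <- function(x, ...) {
  cat("bilingual_lexicon:", nrow(x$words), "lexemes,",
      length(unique(x$words$pair_id)), "translation pairs\n")
  for (lg in c("A", "B")) {
    w <- x$words[x$words$language == lg, ]
    cat("  language", lg, ":", nrow(w), "words (",
        sum(w$n_syllables == 2), "disyllabic )\n")
  }
  cat("  phonology:", ncol(x$phon), "bits; semantics:", ncol(x$sem),
      "bits, mean popcount", round(mean(rowSums(x$sem_pairs)), 2), "\n")
  invisible(x)
}

#' Words of one language
#' @param lexicon a `bilingual_lexicon`.
#' @param language `"A"` or `"B"`.
#' @return integer row indices into `lexicon$words` (lexicon order).
#' @export
language_index <- function(lexicon, language) {
  which(lexicon$words$language == language)
}

#' Task-specific phonological encodings
#'
#' Re-encodes all words of a lexicon under a given prosody/language-unit
#' regime (the test regimes differ from the training encoding).
#'
#' @inheritParams language_index
#' @param use_prosody logical; zero the length/stress bits when `FALSE`.
#' @param language_unit `"own"`, `"A"`, `"B"` or `"none"`.
#' @return matrix (n_words x 292) with lexeme-key rownames.
#' @export
phon_matrix <- function(lexicon, use_prosody = TRUE, language_unit = "own") {
  if (use_prosody && language_unit == "own") return(lexicon$phon)
  out <- lexicon$phon
  if (!use_prosody) out[, c(LENGTH_BITS, STRESS_BITS)] <- 0
  out[, LANG_BITS] <- 0
  if (language_unit == "A") out[, LANG_BITS[1L]] <- 1
  if (language_unit == "B") out[, LANG_BITS[2L]] <- 1
  if (language_unit == "own") {
    out[, LANG_BITS[1L]] <- as.numeric(lexicon$words$language == "A")
    out[, LANG_BITS[2L]] <- as.numeric(lexicon$words$language == "B")
  }
  out
}

#' Save / load a bilingual lexicon as TSV
#'
#' The word table is written as UTF-8 TSV (columns `orthography`,
#' `language`, `sampa`, `stress`, `pair_id`); the semantic matrix is written
#' alongside it as `<path>.sem.tsv` (first column `pair_id`, then 300 bit
#' columns).  `load_lexicon(save_lexicon(x))` reproduces `x` field for
#' field.
#'
#' @param lexicon a `bilingual_lexicon`.
#' @param path path of the word TSV.
#' @return `save_lexicon` returns `path` invisibly; `load_lexicon` returns a
#'   `bilingual_lexicon`.
#' @export
save_lexicon <- function(lexicon, path) {
  cols <- c("orthography", "language", "sampa", "stress", "pair_id")
  utils::write.table(lexicon$words[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  semdf <- data.frame(pair_id = rownames(lexicon$sem_pairs),
                      lexicon$sem_pairs, check.names = FALSE)
  colnames(semdf) <- c("pair_id", paste0("s", seq_len(ncol(lexicon$sem_pairs))))
  utils::write.table(semdf, paste0(path, ".sem.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname save_lexicon
#' @param features phoneme feature table used to re-encode the words.
#' @export
load_lexicon <- function(path, features = phoneme_features()) {
  words <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot read lexicon TSV: ", conditionMessage(e)))
  req <- c("orthography", "language", "sampa", "stress", "pair_id")
  miss <- setdiff(req, names(words))
  if (length(miss)) stop("malformed lexicon file, missing columns: ",
                         paste(miss, collapse = ", "))
  for (i in seq_len(nrow(words))) {
    ok <- tryCatch({ parse_sampa(words$sampa[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("malformed row ", i + 1L, " (", words$orthography[i], "): ", ok)
  }
  sem_path <- paste0(path, ".sem.tsv")
  if (!file.exists(sem_path))
    stop("semantic matrix file not found: ", sem_path)
  semdf <- utils::read.delim(sem_path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  sem <- as.matrix(semdf[, -1L, drop = FALSE])
  rownames(sem) <- as.character(semdf[[1L]])
  colnames(sem) <- NULL
  bilingual_lexicon(words, sem, features)
}
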
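# Phonological and semantic encoders.

#' Encode a word's phonology as a 292-bit vector
#'
#' Builds the slot/feature phonological representation: 13 slots x 22
#' articulatory features (286 bits), 2 syllabic-length bits (thermometer
#' code: monosyllabic `01`, disyllabic `11`), 2 stress bits (one-hot over
#' syllables; monosyllables stress syllable 1), and 2 language bits (one-hot
#' over the two languages, or both zero).  Occupied slots carry their
#' phoneme's feature row; empty slots are all-zero.
#'
#' @param sampa character vector of phoneme symbols.
#' @param syllable_lengths integer vector, length 1 or 2.
#' @param stress index of the stressed syllable (1 or 2).
#' @param language `"A"` or `"B"`: the word's language (used when
#'   `language_unit = "own"`).
#' @param use_prosody if `FALSE`, length and stress bits are zeroed (test
#'   regimes avoid assumptions about how noise affects prosodic cues).
#' @param language_unit which language unit to switch on: `"own"` (the
#'   word's language), `"A"`, `"B"`, or `"none"` (both zero).
#' @param features phoneme feature table.
#' @return numeric vector of length 292 with entries in \{0, 1\}; attribute
#'   `phoneme_slots` as in [align_to_template()].
#' @export
encode_phonology <- function(sampa, syllable_lengths, stress = 1L,
                             language = c("A", "B"),
                             use_prosody = TRUE,
                             language_unit = c("own", "A", "B", "none"),
                             features = phoneme_features()) {
  language <- match.arg(language)
  language_unit <- match.arg(language_unit)
  stress <- as.integer(stress)
  if (stress < 1L || stress > length(syllable_lengths))
    stop("stress index (", stress, ") exceeds the number of syllables")
  slots <- align_to_template(sampa, syllable_lengths, features)
  fm <- feature_matrix(features)
  v <- numeric(PHON_BITS)
  occ <- which(!is.na(slots))
  for (s in occ) v[slot_bits(s)] <- fm[slots[s], ]
  if (use_prosody) {
    v[LENGTH_BITS] <- if (length(syllable_lengths) == 2L) c(1, 1) else c(0, 1)
    v[STRESS_BITS] <- if (stress == 2L) c(0, 1) else c(1, 0)
  }
  lu <- switch(language_unit, own = language, language_unit)
  if (lu == "A") v[LANG_BITS] <- c(1, 0)
  if (lu == "B") v[LANG_BITS] <- c(0, 1)
  attr(v, "phoneme_slots") <- attr(slots, "phoneme_slots")
  v
}

#' Binarize a real-valued semantic embedding
#'
#' Converts a 300-dimensional real embedding (e.g., a word-embedding vector)
#' to a sparse binary semantic vector: bit i is 1 iff the real value is
#' strictly lower than the threshold.  The default threshold of -0.175
#' yields sparse vectors comparable in density to the phonological code.
#'
#' @param real_vector numeric vector of length `n_bits`.
#' @param threshold cut point; values strictly below it map to 1.
#' @param n_bits expected length (300 for the standard scheme).
#' @return binary numeric vector of the same length.
#' @export
binarize_embedding <- function(real_vector, threshold = -0.175, n_bits = 300L) {
  if (length(real_vector) != n_bits)
    stop("embedding has length ", length(real_vector), ", expected ", n_bits)
  as.numeric(real_vector < threshold)
}
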
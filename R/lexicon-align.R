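# Slot alignment: phoneme sequences are fitted into a fixed 13-slot
# disyllabic template CCCVVCCCVVCCC with left-alignment within each syllable.
# "Time into space": word onsets always occupy the leftmost slots, so the
# left part of the vector carries onset information for every word while the
# right part is only populated by disyllables.

# Slot roles (1-based):
#   1-3   onset consonants, syllable 1
#   4-5   vowels, syllable 1
#   6-8   shared consonant band: coda of syllable 1, then (left-aligned into
#         whatever the coda leaves free) the onset of syllable 2
#   9-10  vowels, syllable 2
#   11-13 coda consonants, syllable 2

#' Align a phoneme sequence to the 13-slot word template
#'
#' Places phonemes of a mono- or disyllabic word into the template
#' `CCCVVCCCVVCCC` using a left-alignment strategy per syllable: onset
#' consonants left-align into the syllable's C slots, vowels into its V
#' slots, coda consonants into the following C slots.  Syllable-2 onset
#' consonants occupy the shared consonant band (slots 6-8) after syllable 1's
#' coda; words whose coda + following onset overflow that band are rejected.
#'
#' @param sampa character vector of phoneme symbols (one element per
#'   phoneme), all present in [phoneme_features()].
#' @param syllable_lengths integer vector (length 1 or 2) giving the number
#'   of phonemes in each syllable; must sum to `length(sampa)`.
#' @param features phoneme feature table.
#' @return character vector of length 13: the phoneme occupying each slot or
#'   `NA` for empty slots.  Attribute `phoneme_slots` maps phoneme position
#'   (in input order) to its slot index.
#' @examples
#' align_to_template(c("kh", "{", "r", "@", "t"), c(2, 3))
#' @export
align_to_template <- function(sampa, syllable_lengths,
                              features = phoneme_features()) {
  stopifnot(length(sampa) >= 1L)
  syllable_lengths <- as.integer(syllable_lengths)
  if (!length(syllable_lengths) %in% 1:2)
    stop("words must have 1 or 2 syllables, got ", length(syllable_lengths))
  if (any(syllable_lengths < 1L))
    stop("each syllable must contain at least one phoneme")
  if (sum(syllable_lengths) != length(sampa))
    stop("syllable lengths (", sum(syllable_lengths),
         ") do not sum to the number of phonemes (", length(sampa), ")")
  type <- phoneme_type(sampa, features)

  slots <- rep(NA_character_, PHON_SLOTS)
  phoneme_slots <- integer(length(sampa))
  offset <- 0L
  # slot ranges per syllable: list(onset, vowels, coda)
  shared_next <- 6L  # next free slot in the shared consonant band
  for (s in seq_along(syllable_lengths)) {
    n <- syllable_lengths[s]
    idx <- offset + seq_len(n)
    ty <- type[idx]
    v <- which(ty == "V")
    if (length(v) == 0L)
      stop("syllable ", s, " has no vowel")
    if (any(diff(v) != 1L))
      stop("syllable ", s, " has non-contiguous vowels")
    onset <- idx[seq_len(v[1L] - 1L)]
    nucleus <- idx[v]
    coda <- idx[setdiff(seq_len(n), c(seq_len(v[1L] - 1L), v))]
    if (length(nucleus) > 2L)
      stop("syllable ", s, " has more than 2 vocalic segments")
    if (s == 1L) {
      if (length(onset) > 3L)
        stop("syllable 1 onset exceeds 3 consonants")
      if (length(coda) > 3L)
        stop("syllable 1 coda exceeds 3 consonants")
      on_slots <- seq_len(length(onset))
      nu_slots <- 3L + seq_len(length(nucleus))
      co_slots <- 5L + seq_len(length(coda))
      shared_next <- 6L + length(coda)
    } else {
      if (shared_next + length(onset) - 1L > 8L)
        stop("syllable 2 onset does not fit the shared consonant band ",
             "(slots 6-8) after syllable 1's coda")
      if (length(coda) > 3L)
        stop("syllable 2 coda exceeds 3 consonants")
      on_slots <- if (length(onset)) shared_next + seq_len(length(onset)) - 1L
                  else integer(0)
      nu_slots <- 8L + seq_len(length(nucleus))
      co_slots <- 10L + seq_len(length(coda))
    }
    pos <- c(on_slots, nu_slots, co_slots)
    ph <- c(onset, nucleus, coda)
    slots[pos] <- sampa[ph]
    phoneme_slots[ph] <- pos
    offset <- offset + n
  }
  attr(slots, "phoneme_slots") <- phoneme_slots
  slots
}

#' Render a slot alignment as the template string
#'
#' @param slots result of [align_to_template()].
#' @return a single string with `_` for empty slots.
#' @export
format_alignment <- function(slots) {
  paste(ifelse(is.na(slots), "_", slots), collapse = " ")
}
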
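# Test-time input construction: graded Gaussian noise on occupied slots,
# word-initial vs word-final masking, and incremental (timestep-wise)
# presentation of phonological forms.

#' Split a word's phonemes into initial and final masking sets
#'
#' Deterministic stand-in for per-word masking inventories: the initial set
#' is the first `ceiling(k/2)` phonemes, the final set the last
#' `floor(k/2)`; the two sets partition the word.
#'
#' @param n_phonemes number of phonemes `k` (>= 2).
#' @return list with integer vectors `initial` and `final` (phoneme
#'   positions).
#' @export
masking_split <- function(n_phonemes) {
  n_phonemes <- as.integer(n_phonemes)
  if (n_phonemes < 2L)
    stop("cannot split a single-phoneme word into initial/final sets")
  k <- ceiling(n_phonemes / 2)
  list(initial = seq_len(k), final = seq.int(k + 1L, n_phonemes))
}

#' Add Gaussian noise to occupied slots of a phonological vector
#'
#' Draws i.i.d. Gaussian noise (mean 0, SD `sd`) for every feature bit of
#' the targeted occupied slots and adds it to the encoding.  Untargeted
#' slots, empty slots, and the prosody and language bits are never altered.
#' With `position = "whole"` all occupied slots are targeted; `"initial"` /
#' `"final"` target the slots of the word-initial / word-final phoneme sets
#' from [masking_split()].  `sd = 0` returns the input unchanged.  Inputs
#' are not clipped: the network consumes real-valued vectors.
#'
#' @param phon encoded phonological vector (length 292) carrying the
#'   `phoneme_slots` attribute from [encode_phonology()], or that attribute
#'   supplied via `phoneme_slots`.
#' @param sd noise standard deviation (>= 0).
#' @param position `"whole"`, `"initial"` or `"final"`.
#' @param phoneme_slots integer vector mapping phoneme order to slot index.
#' @return numeric vector of length 292 (real-valued).
#' @export
add_noise <- function(phon, sd = 0, position = c("whole", "initial", "final"),
                      phoneme_slots = attr(phon, "phoneme_slots")) {
  position <- match.arg(position)
  stopifnot(sd >= 0, length(phon) == PHON_BITS)
  if (is.null(phoneme_slots))
    stop("phoneme_slots mapping required (encode with encode_phonology)")
  out <- as.numeric(phon)
  if (sd == 0) {
    attr(out, "phoneme_slots") <- phoneme_slots
    return(out)
  }
  target_ph <- switch(position,
    whole = seq_along(phoneme_slots),
    initial = masking_split(length(phoneme_slots))$initial,
    final = masking_split(length(phoneme_slots))$final)
  bits <- unlist(lapply(phoneme_slots[target_ph], slot_bits))
  out[bits] <- out[bits] + stats::rnorm(length(bits), 0, sd)
  attr(out, "phoneme_slots") <- phoneme_slots
  out
}

#' Incremental (timestep-wise) presentation of a phonological form
#'
#' Builds the input presented at timestep `t` of online spoken-word
#' recognition: the slots of phonemes `1..t` carry their (optionally
#' noisified) feature patterns; all later slots are zero; prosody and
#' language bits are zero throughout.  `t = 0` is the baseline window:
#' an all-zero vector.  `t` beyond the word's length clamps to the full
#' form.
#'
#' @param phon encoded phonological vector with `phoneme_slots` attribute
#'   (encode with `use_prosody = FALSE`, `language_unit = "none"` for the
#'   online regime; prosody/language bits are zeroed here regardless).
#' @param t timestep (integer >= 0).
#' @param noise_sd Gaussian noise SD applied to the presented slots.
#' @param phoneme_slots integer vector mapping phoneme order to slot index.
#' @return numeric vector of length 292.
#' @export
incremental_input <- function(phon, t, noise_sd = 0,
                              phoneme_slots = attr(phon, "phoneme_slots")) {
  if (t < 0) stop("timestep must be non-negative")
  stopifnot(length(phon) == PHON_BITS)
  if (is.null(phoneme_slots))
    stop("phoneme_slots mapping required (encode with encode_phonology)")
  out <- numeric(PHON_BITS)
  t <- min(as.integer(t), length(phoneme_slots))
  if (t >= 1L) {
    present <- phoneme_slots[seq_len(t)]
    bits <- unlist(lapply(present, slot_bits))
    out[bits] <- as.numeric(phon)[bits]
    if (noise_sd > 0)
      out[bits] <- out[bits] + stats::rnorm(length(bits), 0, noise_sd)
  }
  out
}

# Matrix of incremental inputs at timestep t for a set of lexicon words
# (rows).  Base encodings have prosody off and language unit off.
incremental_matrix <- function(lexicon, idx, t, noise_sd = 0) {
  base <- phon_matrix(lexicon, use_prosody = FALSE, language_unit = "none")
  out <- matrix(0, length(idx), PHON_BITS,
                dimnames = list(rownames(base)[idx], NULL))
  for (j in seq_along(idx)) {
    i <- idx[j]
    slots_al <- lexicon$alignments[[i]]
    out[j, ] <- incremental_input(base[i, ], t, noise_sd,
                                  phoneme_slots = attr(slots_al, "phoneme_slots"))
  }
  out
}
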
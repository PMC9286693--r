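# Simulation B: online visual-world paradigm.  Words are presented
# incrementally (one phoneme per timestep); at each timestep the model
# "looks" at the display item whose semantics is closest to the output
# semantics activation.  Looking preferences are smoothed log ratios of
# looks to the critical item over mean looks to the distractors,
# baseline-corrected at timestep 0.

#' Build a visual-world display for a target word
#'
#' The onset competitor is the same-language word sharing the longest
#' phoneme prefix with the target (ties: smallest phonological Euclidean
#' distance, then lexicon order); if no word shares the first phoneme, the
#' nearest phonological neighbour is used and the display is flagged.  The
#' three distractors are the words jointly most distant from both target
#' and competitor in phonology and semantics: each candidate is scored by
#' `min(rank of phonological distance from target, from competitor) +
#' min(rank of semantic distance from target, from competitor)` (higher
#' rank = farther) and the top three scores win, ties by lexicon order.
#'
#' @param target lexeme key (`"language:orthography"`) or row index into
#'   `lexicon$words`.
#' @param lexicon a `bilingual_lexicon` with at least 5 words in the
#'   target's language.
#' @return list with `target`, `competitor`, `distractors` (keys), their
#'   indices, `prefix_len` (shared initial phonemes) and `flagged`.
#' @export
build_display <- function(target, lexicon) {
  keys <- rownames(lexicon$phon)
  ti <- if (is.character(target)) match(target, keys) else as.integer(target)
  if (is.na(ti)) stop("unknown target: ", target)
  lang <- lexicon$words$language[ti]
  same <- setdiff(language_index(lexicon, lang), ti)
  if (length(same) < 4L) stop("need at least 5 words in language ", lang)
  t_ph <- parse_sampa(lexicon$words$sampa[ti])$phonemes
  prefix_len <- vapply(same, function(j) {
    ph <- parse_sampa(lexicon$words$sampa[j])$phonemes
    k <- 0L
    while (k < min(length(t_ph), length(ph)) && t_ph[k + 1L] == ph[k + 1L])
      k <- k + 1L
    k
  }, integer(1))
  pd <- euclidean_cross(lexicon$phon[ti, , drop = FALSE],
                        lexicon$phon[same, , drop = FALSE])[1L, ]
  flagged <- max(prefix_len) == 0L
  ord <- order(-prefix_len, pd, same)
  comp <- same[ord[1L]]

  cand <- setdiff(same, comp)
  cd_pt <- euclidean_cross(lexicon$phon[cand, , drop = FALSE],
                           lexicon$phon[c(ti, comp), , drop = FALSE])
  cd_st <- euclidean_cross(lexicon$sem[cand, , drop = FALSE],
                           lexicon$sem[c(ti, comp), , drop = FALSE])
  r_pt <- pmin(rank(cd_pt[, 1L], ties.method = "first"),
               rank(cd_pt[, 2L], ties.method = "first"))
  r_st <- pmin(rank(cd_st[, 1L], ties.method = "first"),
               rank(cd_st[, 2L], ties.method = "first"))
  score <- r_pt + r_st
  distr <- cand[order(-score, cand)][1:3]
  list(target = keys[ti], target_idx = ti,
       competitor = keys[comp], competitor_idx = comp,
       distractors = keys[distr], distractor_idx = distr,
       prefix_len = max(prefix_len), flagged = flagged)
}

#' Displays for all words of one language
#' @inheritParams build_display
#' @param language `"A"` or `"B"`.
#' @return named list of displays keyed by target lexeme key.
#' @export
build_displays <- function(lexicon, language = "B") {
  idx <- language_index(lexicon, language)
  ds <- lapply(idx, build_display, lexicon = lexicon)
  names(ds) <- rownames(lexicon$phon)[idx]
  ds
}

# One "look" per (item, repetition, timestep): the display item whose
# semantic vector is closest to the output semantics.  Returns a logical:
# did the model look at the critical item?
look_at_critical <- function(out_sem, crit_idx, distr_idx, lexicon) {
  items <- c(crit_idx, distr_idx)
  D <- euclidean_cross(out_sem, lexicon$sem[items, , drop = FALSE])
  apply(D, 1L, which_min_first) == 1L
}

#' Run the online visual-world experiment
#'
#' For each display and condition (target-present or competitor-present),
#' the target word is presented incrementally under the given noise level;
#' at each timestep one look is assigned to the display item (critical item
#' or one of the three distractors) minimizing the Euclidean distance
#' between its semantics and the output-semantics activation.  Looks are
#' aggregated over repetitions and replications; the looking preference is
#' `log((looks_critical + 0.5) / (mean distractor looks + 0.5))`, minus its
#' value at timestep 0 (baseline correction after the log).
#'
#' @inheritParams run_offline_experiment
#' @param displays from [build_displays()]; their targets define the item
#'   set (all must be words of `target_language`).
#' @param noise_sds e.g. `c(0, 0.3, 0.6)`.
#' @param timesteps vector of timesteps, default `0:5`; words shorter than
#'   `max(timesteps)` hold their full form at later timesteps.
#' @return list with `series`: data.frame (`version`, `sd`, `condition`
#'   in `target`/`competitor`, `t`, `looks_critical`, `looks_distractor`
#'   (mean per distractor), `preference` = baseline-corrected log ratio)
#'   and `items`: per-item preferences for the binwise tests (`version`,
#'   `sd`, `condition`, `target`, `t`, `preference`).
#' @export
run_online_experiment <- function(models, lexicon, displays,
                                  target_language = "B",
                                  noise_sds = c(0, 0.3, 0.6),
                                  timesteps = 0:5, repetitions = 10L,
                                  seed = 1L, decoder = c("model", "input")) {
  decoder <- match.arg(decoder)
  if (timesteps[1L] != 0L)
    stop("timesteps must start at 0 (the baseline window)")
  idx <- vapply(displays, `[[`, integer(1), "target_idx")
  conditions <- c("target", "competitor")
  rows <- list(); item_rows <- list()
  stage <- 0L
  for (vi in seq_along(models)) {
    version <- names(models)[vi]
    reps_models <- models[[vi]]
    if (inherits(reps_models, "trained_model")) reps_models <- list(reps_models)
    for (sd in noise_sds) {
      # looks[t, item, condition] accumulated over repetitions+replications
      looks_c <- array(0, c(length(timesteps), length(idx), 2L))
      looks_d <- array(0, c(length(timesteps), length(idx), 2L))
      for (ri in seq_along(reps_models)) {
        model <- reps_models[[ri]]
        lc_rep <- array(0, c(length(timesteps), length(idx), 2L))
        ld_rep <- array(0, c(length(timesteps), length(idx), 2L))
        for (rep_i in seq_len(repetitions)) {
          stage <- stage + 1L
          set.seed(derive_seed(seed, stage + 7919L * vi))
          for (tt in seq_along(timesteps)) {
            t <- timesteps[tt]
            X <- incremental_matrix(lexicon, idx, t, noise_sd = sd)
            out <- if (decoder == "model") forward(model, X)$output_sem else X
            for (ci in 1:2) {
              crit <- if (ci == 1L)
                vapply(displays, `[[`, integer(1), "target_idx")
              else vapply(displays, `[[`, integer(1), "competitor_idx")
              for (w in seq_along(idx)) {
                d <- displays[[w]]
                items <- c(crit[w], d$distractor_idx)
                refs <- if (decoder == "model")
                  lexicon$sem[items, , drop = FALSE]
                else phon_matrix(lexicon, use_prosody = FALSE,
                                 language_unit = "none")[items, , drop = FALSE]
                D <- euclidean_cross(out[w, , drop = FALSE], refs)
                j <- which_min_first(D[1L, ])
                if (j == 1L) lc_rep[tt, w, ci] <- lc_rep[tt, w, ci] + 1
                else ld_rep[tt, w, ci] <- ld_rep[tt, w, ci] + 1
              }
            }
          }
          if (sd == 0) {
            # clean presentation is deterministic: replicate counts instead
            lc_rep <- lc_rep * repetitions
            ld_rep <- ld_rep * repetitions
            break
          }
        }
        looks_c <- looks_c + lc_rep
        looks_d <- looks_d + ld_rep
      }
      n_eff <- length(reps_models) * repetitions
      for (ci in 1:2) {
        lc_m <- matrix(looks_c[, , ci], nrow = length(timesteps))
        ld_m <- matrix(looks_d[, , ci], nrow = length(timesteps))
        pref_item <- log((lc_m + 0.5) / (ld_m / 3 + 0.5))
        pref_item <- sweep(pref_item, 2L, pref_item[1L, ], "-")
        for (w in seq_along(idx)) {
          item_rows[[length(item_rows) + 1L]] <- data.frame(
            version = version, sd = sd, condition = conditions[ci],
            target = names(displays)[w], t = timesteps,
            preference = pref_item[, w], stringsAsFactors = FALSE)
        }
        lc <- rowSums(lc_m)
        ld <- rowSums(ld_m) / 3
        pref <- log((lc + 0.5) / (ld + 0.5))
        pref <- pref - pref[1L]
        rows[[length(rows) + 1L]] <- data.frame(
          version = version, sd = sd, condition = conditions[ci],
          t = timesteps, looks_critical = lc / (n_eff * length(idx)),
          looks_distractor = ld / (n_eff * length(idx)),
          preference = pref, stringsAsFactors = FALSE)
      }
    }
  }
  list(series = do.call(rbind, rows), items = do.call(rbind, item_rows))
}
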
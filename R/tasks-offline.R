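# Simulation A: offline spoken-word identification under graded,
# positioned noise, plus the untrained Input-based baseline.

#' Identify a word from output semantics (nearest-neighbour criterion)
#'
#' Presents phonological input(s) to the trained model (no semantic input)
#' and decodes the response as the candidate word whose semantic vector is
#' closest, in Euclidean distance, to the output-semantics activation.
#' Ties break by lexicon order.
#'
#' @param model a `trained_model`.
#' @param phon_input numeric vector (292) or matrix (n x 292) of inputs.
#' @param lexicon a `bilingual_lexicon`.
#' @param candidate_language `"A"` or `"B"`: the candidate vocabulary.
#' @return data.frame with one row per input: `response` (lexeme key),
#'   `response_idx` (row in `lexicon$words`), `distance` (rank-1 Euclidean
#'   distance).
#' @export
identify_word <- function(model, phon_input, lexicon, candidate_language) {
  idx <- language_index(lexicon, candidate_language)
  if (!length(idx)) stop("empty candidate set for language ", candidate_language)
  if (!is.matrix(phon_input)) phon_input <- matrix(phon_input, nrow = 1L)
  out <- forward(model, phon_input)$output_sem
  D <- euclidean_cross(out, lexicon$sem[idx, , drop = FALSE])
  j <- apply(D, 1L, which_min_first)
  data.frame(response = rownames(lexicon$phon)[idx[j]],
             response_idx = idx[j],
             distance = D[cbind(seq_len(nrow(D)), j)],
             stringsAsFactors = FALSE)
}

#' Input-based identification (untrained baseline)
#'
#' The baseline model involves no training: the response to a phonological
#' input is simply the vocabulary word with the closest matching phonology
#' (Euclidean distance to the candidates' full phonological encodings,
#' prosody off, language unit matching the task's input regime).  Because
#' nothing is learned, its responses are identical under any
#' native/non-native labelling.
#'
#' @inheritParams identify_word
#' @param use_prosody,language_unit encoding regime of the reference
#'   vectors; match the regime of `phon_input`.
#' @return data.frame as in [identify_word()].
#' @export
input_based_identify <- function(phon_input, lexicon, candidate_language,
                                 use_prosody = FALSE,
                                 language_unit = candidate_language) {
  idx <- language_index(lexicon, candidate_language)
  if (!length(idx)) stop("empty candidate set for language ", candidate_language)
  if (!is.matrix(phon_input)) phon_input <- matrix(phon_input, nrow = 1L)
  refs <- phon_matrix(lexicon, use_prosody = use_prosody,
                      language_unit = language_unit)[idx, , drop = FALSE]
  D <- euclidean_cross(phon_input, refs)
  j <- apply(D, 1L, which_min_first)
  data.frame(response = rownames(lexicon$phon)[idx[j]],
             response_idx = idx[j],
             distance = D[cbind(seq_len(nrow(D)), j)],
             stringsAsFactors = FALSE)
}

#' Run the offline spoken-word identification experiment
#'
#' Full factorial over model version (native/non-native) x noise SD x noise
#' position x word x noise repetition for one target language.  Inputs are
#' full phonological forms with prosody off and the target language's unit
#' on; noise is added to occupied slots only.  In the zero-noise condition
#' the position factor is inert (recorded as `"whole"`).
#'
#' @param models named list `list(native = ..., nonnative = ...)` of trained
#'   models (a single model may also be supplied under either name).  Each
#'   entry may itself be a list of replications.
#' @param lexicon a `bilingual_lexicon`.
#' @param target_language `"A"` or `"B"`.
#' @param noise_sds noise grid, e.g. `c(0, 0.3, 0.6, 0.9)`.
#' @param positions positions for sd > 0, default `c("initial", "final")`.
#' @param repetitions fresh noise draws per (word, condition).
#' @param seed integer seed for the noise draws.
#' @param decoder `"model"` (trained network) or `"input"` (Input-based
#'   baseline; version labels then have no effect on responses).
#' @return data.frame of trial records: `version`, `replication`, `sd`,
#'   `position`, `repetition`, `target` (key), `target_idx`, `response`,
#'   `response_idx`, `correct`.
#' @export
run_offline_experiment <- function(models, lexicon, target_language = "B",
                                   noise_sds = c(0, 0.3, 0.6, 0.9),
                                   positions = c("initial", "final"),
                                   repetitions = 10L, seed = 1L,
                                   decoder = c("model", "input")) {
  decoder <- match.arg(decoder)
  idx <- language_index(lexicon, target_language)
  base <- phon_matrix(lexicon, use_prosody = FALSE,
                      language_unit = target_language)
  slots <- lapply(lexicon$alignments[idx],
                  function(a) attr(a, "phoneme_slots"))
  rows <- list()
  stage <- 0L
  for (vi in seq_along(models)) {
    version <- names(models)[vi]
    reps_models <- models[[vi]]
    if (inherits(reps_models, "trained_model")) reps_models <- list(reps_models)
    for (ri in seq_along(reps_models)) {
      model <- reps_models[[ri]]
      for (sd in noise_sds) {
        pos_set <- if (sd == 0) "whole" else positions
        for (pos in pos_set) {
          for (rep_i in seq_len(repetitions)) {
            stage <- stage + 1L
            set.seed(derive_seed(seed, stage))
            X <- matrix(0, length(idx), PHON_BITS)
            for (j in seq_along(idx)) {
              X[j, ] <- add_noise(base[idx[j], ], sd = sd, position = pos,
                                  phoneme_slots = slots[[j]])
            }
            resp <- if (decoder == "model")
              identify_word(model, X, lexicon, target_language)
            else
              input_based_identify(X, lexicon, target_language,
                                   use_prosody = FALSE,
                                   language_unit = target_language)
            rows[[length(rows) + 1L]] <- data.frame(
              version = version, replication = ri, sd = sd, position = pos,
              repetition = rep_i,
              target = rownames(lexicon$phon)[idx],
              target_idx = idx,
              response = resp$response, response_idx = resp$response_idx,
              correct = resp$response_idx == idx,
              stringsAsFactors = FALSE)
            if (sd == 0) break  # no noise: repetitions are identical
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Unique misperception errors per incorrectly identified word
#'
#' For each word, counts the distinct erroneous response types across its
#' trials; the condition-level summary is the mean over words with at least
#' one error (words identified correctly on every repetition contribute no
#' value).
#'
#' @param trials trial table from [run_offline_experiment()] (any subset,
#'   typically one condition cell).
#' @return list with `per_word` (data.frame `target`, `n_unique_errors`
#'   for words with >= 1 error) and `mean` (their mean; `NaN` if no word
#'   erred).
#' @export
unique_misperceptions <- function(trials) {
  if (nrow(trials) == 0L) stop("no trials supplied")
  sp <- split(trials, trials$target)
  counts <- vapply(sp, function(d) {
    length(unique(d$response[!d$correct]))
  }, integer(1))
  keep <- counts > 0L
  list(per_word = data.frame(target = names(counts)[keep],
                             n_unique_errors = unname(counts[keep]),
                             stringsAsFactors = FALSE),
       mean = mean(counts[keep]))
}

#' Condition-level offline summary
#'
#' Aggregates a trial table into per-cell accuracy and mean unique
#' misperception errors (averaged over replications and repetitions).
#'
#' @param trials trial table from [run_offline_experiment()].
#' @return data.frame with one row per (version, sd, position):
#'   `accuracy`, `unique_errors`.
#' @export
summarize_offline <- function(trials) {
  cells <- unique(trials[c("version", "sd", "position")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- trials[trials$version == cells$version[i] &
                   trials$sd == cells$sd[i] &
                   trials$position == cells$position[i], ]
    # unique-error counts are per word within one trained network; the cell
    # value averages the per-replication means
    ue <- vapply(split(cell, cell$replication),
                 function(d) unique_misperceptions(d)$mean, numeric(1))
    data.frame(version = cells$version[i], sd = cells$sd[i],
               position = cells$position[i],
               accuracy = mean(cell$correct),
               unique_errors = if (all(is.nan(ue))) NaN else
                 mean(ue[!is.nan(ue)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$version, out$sd, out$position), ]
}
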
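# Mechanistic analysis: rank-order competition measures at the output,
# input and hidden layers (intra- and interlingual), cumulative unique
# misperceptions during incremental presentation, and representational
# similarity analysis (RSA) against the training set's phonological and
# semantic similarity structure.

#' Rank of the target among reference activations
#'
#' Euclidean distances between a current activation (one row per trial) and
#' a fixed set of reference activations are sorted ascending; the returned
#' rank is the position of the target's reference (1 = closest; ties break
#' by reference order, i.e. lexicon order).  A rank of r means r - 1
#' spurious words outperform the target in competition.
#'
#' @param activation numeric vector or matrix (n x d) of current
#'   activations.
#' @param references matrix (m x d) of full-presentation reference
#'   activations, rownames = lexeme keys.
#' @param target index (or rowname) of the target within `references`.
#' @return integer vector of ranks (length n).
#' @export
closeness_rank <- function(activation, references, target) {
  if (!is.matrix(activation)) activation <- matrix(activation, nrow = 1L)
  if (is.character(target)) target <- match(target, rownames(references))
  if (is.na(target) || target < 1L || target > nrow(references))
    stop("reference set does not contain the target")
  D <- euclidean_cross(activation, references)
  as.integer(apply(D, 1L, function(d) rank(d, ties.method = "first")[target]))
}

#' Reference activations for the rank measures
#'
#' For the output layer the references are the semantic vectors themselves;
#' for the input layer, the full phonological encodings (prosody off,
#' language unit off, matching the online input regime); for the hidden
#' layers PS2 and S4, the activations elicited by the clean, full
#' phonological form presented together with its input semantics.
#'
#' @param model a `trained_model`.
#' @param lexicon a `bilingual_lexicon`.
#' @return list of matrices `input_phon`, `PS2`, `S4`, `output_sem`, each
#'   with one row per lexicon word (lexeme-key rownames).
#' @export
reference_activations <- function(model, lexicon) {
  Xp <- phon_matrix(lexicon, use_prosody = FALSE, language_unit = "none")
  act <- forward_batch(model, Xp, lexicon$sem)
  out <- list(input_phon = Xp, PS2 = act$PS2, S4 = act$S4,
              output_sem = lexicon$sem)
  for (nm in names(out)) rownames(out[[nm]]) <- rownames(lexicon$phon)
  out
}

#' Online accuracy at a timestep
#'
#' Fraction of words whose output semantics is closer to the target word's
#' semantics than to any other same-language word's (i.e. output-layer rank
#' 1).
#'
#' @param ranks integer vector of output-layer ranks (one per word).
#' @return proportion in `[0, 1]`.
#' @export
online_accuracy <- function(ranks) mean(ranks == 1L)

#' Cumulative unique misperception errors over timesteps
#'
#' Counts the distinct erroneous responses observed up to each timestep;
#' the count freezes from the first timestep at which the word is correctly
#' recognized onward.
#'
#' @param responses character vector of decoded responses at timesteps
#'   `1..T` (in order).
#' @param target the correct response.
#' @return integer vector of per-timestep cumulative counts (length T),
#'   non-decreasing.
#' @export
cumulative_unique_errors <- function(responses, target) {
  seen <- character(0)
  out <- integer(length(responses))
  frozen <- FALSE
  for (t in seq_along(responses)) {
    if (!frozen) {
      if (responses[t] == target) frozen <- TRUE
      else seen <- union(seen, responses[t])
    }
    out[t] <- length(seen)
  }
  out
}

#' Representational dissimilarity matrix (RDM)
#'
#' Pairwise cosine distances between the activation patterns of all words
#' (one row per word) at one layer/timestep/condition.  Symmetric with zero
#' diagonal; zero-norm activations are maximally dissimilar (entry 1) to
#' all others.
#'
#' @param activations matrix (n_words x d), rownames = lexeme keys.
#' @return an `rdm`: n x n numeric matrix.
#' @export
build_rdm <- function(activations) {
  d <- cosine_dist(activations)
  structure(d, class = c("rdm", class(d)))
}

#' Correlate two RDMs (RSA)
#'
#' Pearson correlation over the strict upper triangles of two RDMs with the
#' same item ordering.  A constant RDM yields `NA`.
#'
#' @param rdm_a,rdm_b square dissimilarity matrices of equal size.
#' @return Pearson correlation coefficient (scalar, possibly `NA`).
#' @export
rsa_correlate <- function(rdm_a, rdm_b) {
  stopifnot(nrow(rdm_a) == nrow(rdm_b), ncol(rdm_a) == ncol(rdm_b))
  ut <- upper.tri(rdm_a)
  a <- rdm_a[ut]; b <- rdm_b[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Run the mechanistic analysis
#'
#' Presents all words of the target language incrementally (clean and under
#' noise) and computes, per timestep and condition: online accuracy,
#' cumulative unique misperception errors, rank-order closeness to the
#' target at the output, input and hidden (PS2, S4) layers, interlingual
#' variants of the rank measures (candidate scope = the nontarget
#' language), and RSA correlations of every layer's RDM with the
#' phonological and semantic reference RDMs of the training set.
#'
#' @param models named list of model versions, each a `trained_model` or a
#'   list of replications.
#' @param lexicon a `bilingual_lexicon`.
#' @param target_language `"A"` or `"B"`.
#' @param noise_sds noise conditions, default `c(0, 0.75)` (clean vs the
#'   mechanistic noise level).
#' @param timesteps default `1:5`.
#' @param repetitions noise repetitions (clean runs once).
#' @param seed integer seed.
#' @return list of tidy data.frames: `accuracy` (version, sd, t, value),
#'   `cumulative_errors`, `ranks` (with `layer` and `scope` in
#'   target/nontarget), `rsa` (layer, reference in phonology/semantics,
#'   version, sd, t, value).
#' @export
run_mechanistic <- function(models, lexicon, target_language = "B",
                            noise_sds = c(0, 0.75), timesteps = 1:5,
                            repetitions = 5L, seed = 1L) {
  idx_t <- language_index(lexicon, target_language)
  idx_n <- language_index(lexicon, setdiff(c("A", "B"), target_language))
  keys <- rownames(lexicon$phon)
  layers <- c("input_phon", "PS2", "S4", "output_sem")
  ref_phon_rdm <- build_rdm(lexicon$phon[idx_t, , drop = FALSE])
  ref_sem_rdm <- build_rdm(lexicon$sem[idx_t, , drop = FALSE])

  acc_rows <- list(); cum_rows <- list(); rank_rows <- list(); rsa_rows <- list()
  stage <- 0L
  for (vi in seq_along(models)) {
    version <- names(models)[vi]
    reps_models <- models[[vi]]
    if (inherits(reps_models, "trained_model")) reps_models <- list(reps_models)
    for (ri in seq_along(reps_models)) {
      model <- reps_models[[ri]]
      refs <- reference_activations(model, lexicon)
      for (sd in noise_sds) {
        n_rep <- if (sd == 0) 1L else repetitions
        acc_acc <- matrix(0, n_rep, length(timesteps))
        cum_acc <- matrix(0, n_rep, length(timesteps))
        rank_acc <- array(0, c(n_rep, length(timesteps), length(layers), 2L),
                          dimnames = list(NULL, NULL, layers,
                                          c("target", "nontarget")))
        rsa_acc <- array(0, c(n_rep, length(timesteps), length(layers), 2L),
                         dimnames = list(NULL, NULL, layers,
                                         c("phonology", "semantics")))
        for (rep_i in seq_len(n_rep)) {
          stage <- stage + 1L
          set.seed(derive_seed(seed, stage + 104729L * vi))
          resp_mat <- matrix("", length(idx_t), length(timesteps))
          out_rank1 <- matrix(0L, length(idx_t), length(timesteps))
          for (tt in seq_along(timesteps)) {
            t <- timesteps[tt]
            X <- incremental_matrix(lexicon, idx_t, t, noise_sd = sd)
            act <- forward(model, X)
            for (li in seq_along(layers)) {
              ly <- layers[li]
              A <- act[[ly]]
              # intralingual ranks
              R_t <- refs[[ly]][idx_t, , drop = FALSE]
              D <- euclidean_cross(A, R_t)
              rk <- vapply(seq_along(idx_t), function(w)
                rank(D[w, ], ties.method = "first")[w], numeric(1))
              rank_acc[rep_i, tt, li, "target"] <-
                rank_acc[rep_i, tt, li, "target"] + mean(rk)
              if (ly == "output_sem") {
                out_rank1[, tt] <- as.integer(rk)
                best <- apply(D, 1L, which_min_first)
                resp_mat[, tt] <- keys[idx_t[best]]
              }
              # interlingual competition: rank of the nearest
              # nontarget-language word among all words' references
              R_n <- refs[[ly]][idx_n, , drop = FALSE]
              Dn <- euclidean_cross(A, R_n)
              Dall <- cbind(D, Dn)
              rk_best_n <- vapply(seq_len(nrow(Dall)), function(w) {
                r <- rank(Dall[w, ], ties.method = "first")
                min(r[(length(idx_t) + 1L):ncol(Dall)])
              }, numeric(1))
              rank_acc[rep_i, tt, li, "nontarget"] <-
                rank_acc[rep_i, tt, li, "nontarget"] + mean(rk_best_n)
              # RSA
              rdm <- build_rdm(A)
              rsa_acc[rep_i, tt, li, "phonology"] <-
                rsa_correlate(rdm, ref_phon_rdm)
              rsa_acc[rep_i, tt, li, "semantics"] <-
                rsa_correlate(rdm, ref_sem_rdm)
            }
            acc_acc[rep_i, tt] <- online_accuracy(out_rank1[, tt])
          }
          cum <- t(vapply(seq_along(idx_t), function(w)
            cumulative_unique_errors(resp_mat[w, ], keys[idx_t[w]]),
            numeric(length(timesteps))))
          cum_acc[rep_i, ] <- colMeans(cum)
        }
        add <- function(lst, df) { lst[[length(lst) + 1L]] <- df; lst }
        acc_rows <- add(acc_rows, data.frame(
          version = version, replication = ri, sd = sd, t = timesteps,
          value = colMeans(acc_acc), stringsAsFactors = FALSE))
        cum_rows <- add(cum_rows, data.frame(
          version = version, replication = ri, sd = sd, t = timesteps,
          value = colMeans(cum_acc), stringsAsFactors = FALSE))
        for (li in seq_along(layers)) for (sc in c("target", "nontarget")) {
          rank_rows <- add(rank_rows, data.frame(
            version = version, replication = ri, sd = sd,
            layer = layers[li], scope = sc, t = timesteps,
            value = colMeans(matrix(rank_acc[, , li, sc], nrow = n_rep)),
            stringsAsFactors = FALSE))
        }
        for (li in seq_along(layers)) for (rf in c("phonology", "semantics")) {
          rsa_rows <- add(rsa_rows, data.frame(
            version = version, replication = ri, sd = sd,
            layer = layers[li], reference = rf, t = timesteps,
            value = colMeans(matrix(rsa_acc[, , li, rf], nrow = n_rep)),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(accuracy = do.call(rbind, acc_rows),
       cumulative_errors = do.call(rbind, cum_rows),
       ranks = do.call(rbind, rank_rows),
       rsa = do.call(rbind, rsa_rows))
}

#' Interlingual rank of the target word within the nontarget vocabulary
#'
#' Rank computed as in [closeness_rank()] but with the candidate scope
#' restricted to the nontarget language's reference activations.
#'
#' @param activation current activation (vector or n x d matrix).
#' @param references full reference matrix (all words).
#' @param nontarget_idx indices of the nontarget-language words within
#'   `references`.
#' @param target index (into `references`) of the nontarget word whose rank
#'   is sought; defaults to the nearest nontarget word per trial.
#' @return integer vector of ranks within the nontarget vocabulary.
#' @export
interlingual_rank <- function(activation, references, nontarget_idx,
                              target = NULL) {
  if (!is.matrix(activation)) activation <- matrix(activation, nrow = 1L)
  refs <- references[nontarget_idx, , drop = FALSE]
  D <- euclidean_cross(activation, refs)
  if (is.null(target)) {
    apply(D, 1L, function(d) min(rank(d, ties.method = "first")))
  } else {
    j <- match(target, nontarget_idx)
    if (is.na(j)) stop("target is not in the nontarget scope")
    apply(D, 1L, function(d) rank(d, ties.method = "first")[j])
  }
}
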
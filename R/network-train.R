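# Training: greedy layerwise pretraining followed by denoising fine-tuning
# with three interleaved mapping types under an exposure ratio.

bce_loss <- function(Y, T_) {
  eps <- 1e-7
  Y <- pmin(pmax(Y, eps), 1 - eps)
  -mean(T_ * log(Y) + (1 - T_) * log(1 - Y))
}

# Train a shallow autoencoder X -> sigmoid(XW+b) -> sigmoid(.Wd+bd) ~ X by
# full-batch gradient descent, returning updated encoder weights and the
# per-epoch loss trace.  The throwaway decoder weights are discarded.
shallow_ae <- function(X, W, b, epochs, lr, momentum = 0.9) {
  n <- nrow(X); d <- ncol(X)
  Wd <- glorot(ncol(W), d); bd <- numeric(d)
  losses <- numeric(epochs)
  vW <- 0 * W; vb <- 0 * b; vWd <- 0 * Wd; vbd <- 0 * bd
  for (e in seq_len(epochs)) {
    H <- sigmoid(sweep(X %*% W, 2L, b, "+"))
    Y <- sigmoid(sweep(H %*% Wd, 2L, bd, "+"))
    losses[e] <- bce_loss(Y, X)
    if (!is.finite(losses[e]))
      stop("non-finite pretraining loss at epoch ", e)
    d_out <- (Y - X) / n
    g_Wd <- crossprod(H, d_out); g_bd <- colSums(d_out)
    d_h <- (d_out %*% t(Wd)) * H * (1 - H)
    g_W <- crossprod(X, d_h); g_b <- colSums(d_h)
    vWd <- momentum * vWd + g_Wd; vbd <- momentum * vbd + g_bd
    vW <- momentum * vW + g_W; vb <- momentum * vb + g_b
    Wd <- Wd - lr * vWd; bd <- bd - lr * vbd
    W <- W - lr * vW; b <- b - lr * vb
  }
  list(W = W, b = b, losses = losses)
}

#' Greedy layerwise pretraining
#'
#' Pretrains the encoder stack layer by layer: each encoder layer is trained
#' as a shallow autoencoder on the activations produced by the layers below
#' it (phonological pathway P0 then P1, semantic pathway S1, then the
#' bottleneck PS2 on the concatenated P1/S1 codes).  Decoder weights used
#' during pretraining are throwaway; only encoder weights are kept.
#'
#' @param model an (untrained) `trained_model`.
#' @param lexicon a `bilingual_lexicon`; pretraining uses the full training
#'   encodings of all its words.
#' @param epochs epochs per layer (0 = no-op).
#' @param lr learning rate (momentum 0.9 updates).
#' @param seed integer seed (throwaway decoder initialization).
#' @return the model with updated encoder weights and a `pretrain` log
#'   (data.frame layer/epoch/loss).
#' @export
pretrain <- function(model, lexicon, epochs = 50L, lr = 0.1, seed = 1L) {
  stopifnot(inherits(model, "trained_model"))
  if (epochs == 0L) return(model)
  set.seed(seed)
  Xp <- lexicon$phon
  Xs <- lexicon$sem
  W <- model$W
  log_rows <- list()
  add_log <- function(layer, losses)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      layer = layer, epoch = seq_along(losses), loss = losses)

  r <- shallow_ae(Xp, W$enc_p0, W$b_p0, epochs, lr)
  W$enc_p0 <- r$W; W$b_p0 <- r$b; add_log("P0", r$losses)
  H_p0 <- sigmoid(sweep(Xp %*% W$enc_p0, 2L, W$b_p0, "+"))

  r <- shallow_ae(H_p0, W$enc_p1, W$b_p1, epochs, lr)
  W$enc_p1 <- r$W; W$b_p1 <- r$b; add_log("P1", r$losses)
  H_p1 <- sigmoid(sweep(H_p0 %*% W$enc_p1, 2L, W$b_p1, "+"))

  r <- shallow_ae(Xs, W$enc_s1, W$b_s1, epochs, lr)
  W$enc_s1 <- r$W; W$b_s1 <- r$b; add_log("S1", r$losses)
  H_s1 <- sigmoid(sweep(Xs %*% W$enc_s1, 2L, W$b_s1, "+"))

  r <- shallow_ae(cbind(H_p1, H_s1), rbind(W$enc_pp2, W$enc_sp2), W$b_ps2,
                  epochs, lr)
  W$enc_pp2 <- r$W[seq_len(model$arch$p1), , drop = FALSE]
  W$enc_sp2 <- r$W[model$arch$p1 + seq_len(model$arch$s1), , drop = FALSE]
  W$b_ps2 <- r$b; add_log("PS2", r$losses)

  model$W <- W
  model$log$pretrain <- do.call(rbind, log_rows)
  model
}

# One minibatch gradient step.  `phase` selects the mapping type:
#  "phon" : phonology in (corrupted), phonology target, zero semantic input
#  "sem"  : semantics in (corrupted), semantics target, zero phonological input
#  "both" : both in (corrupted), both targets
# Targets are always the uncorrupted vectors (denoising objective).
finetune_step <- function(W, arch, Xp, Xs, Tp, Ts, phase) {
  n <- nrow(Xp)
  h_p0 <- sigmoid(sweep(Xp %*% W$enc_p0, 2L, W$b_p0, "+"))
  h_p1 <- sigmoid(sweep(h_p0 %*% W$enc_p1, 2L, W$b_p1, "+"))
  h_s1 <- sigmoid(sweep(Xs %*% W$enc_s1, 2L, W$b_s1, "+"))
  h_ps2 <- sigmoid(sweep(h_p1 %*% W$enc_pp2 + h_s1 %*% W$enc_sp2, 2L,
                         W$b_ps2, "+"))
  loss <- 0
  d_ps2_acc <- matrix(0, n, arch$ps2)
  upd <- list()
  if (phase %in% c("phon", "both")) {
    h_p3 <- sigmoid(sweep(h_ps2 %*% W$dec_p3, 2L, W$b_p3, "+"))
    y_p <- sigmoid(sweep(h_p3 %*% W$dec_pout, 2L, W$b_pout, "+"))
    loss <- loss + bce_loss(y_p, Tp)
    d_out <- (y_p - Tp) / n
    upd$dec_pout <- crossprod(h_p3, d_out); upd$b_pout <- colSums(d_out)
    d_p3 <- (d_out %*% t(W$dec_pout)) * h_p3 * (1 - h_p3)
    upd$dec_p3 <- crossprod(h_ps2, d_p3); upd$b_p3 <- colSums(d_p3)
    d_ps2_acc <- d_ps2_acc + d_p3 %*% t(W$dec_p3)
  }
  if (phase %in% c("sem", "both")) {
    h_s3 <- sigmoid(sweep(h_ps2 %*% W$dec_s3, 2L, W$b_s3, "+"))
    h_s4 <- sigmoid(sweep(h_s3 %*% W$dec_s4, 2L, W$b_s4, "+"))
    y_s <- sigmoid(sweep(h_s4 %*% W$dec_sout, 2L, W$b_sout, "+"))
    loss <- loss + bce_loss(y_s, Ts)
    d_out <- (y_s - Ts) / n
    upd$dec_sout <- crossprod(h_s4, d_out); upd$b_sout <- colSums(d_out)
    d_s4 <- (d_out %*% t(W$dec_sout)) * h_s4 * (1 - h_s4)
    upd$dec_s4 <- crossprod(h_s3, d_s4); upd$b_s4 <- colSums(d_s4)
    d_s3 <- (d_s4 %*% t(W$dec_s4)) * h_s3 * (1 - h_s3)
    upd$dec_s3 <- crossprod(h_ps2, d_s3); upd$b_s3 <- colSums(d_s3)
    d_ps2_acc <- d_ps2_acc + d_s3 %*% t(W$dec_s3)
  }
  d_ps2 <- d_ps2_acc * h_ps2 * (1 - h_ps2)
  upd$enc_pp2 <- crossprod(h_p1, d_ps2)
  upd$enc_sp2 <- crossprod(h_s1, d_ps2)
  upd$b_ps2 <- colSums(d_ps2)
  d_p1 <- (d_ps2 %*% t(W$enc_pp2)) * h_p1 * (1 - h_p1)
  upd$enc_p1 <- crossprod(h_p0, d_p1); upd$b_p1 <- colSums(d_p1)
  d_p0 <- (d_p1 %*% t(W$enc_p1)) * h_p0 * (1 - h_p0)
  upd$enc_p0 <- crossprod(Xp, d_p0); upd$b_p0 <- colSums(d_p0)
  d_s1 <- (d_ps2 %*% t(W$enc_sp2)) * h_s1 * (1 - h_s1)
  upd$enc_s1 <- crossprod(Xs, d_s1); upd$b_s1 <- colSums(d_s1)
  list(grads = upd, loss = loss)
}

#' Denoising fine-tuning under an exposure ratio
#'
#' Each epoch draws `batch_size` training presentations: a word is drawn
#' with probability proportional to its language's exposure weight and one
#' of three mapping types is drawn per the phase schedule (phonology ->
#' phonology, semantics -> semantics, or both presented simultaneously).
#' Presented inputs are corrupted with i.i.d. Gaussian noise
#' (`corruption_sd`) and, in the joint mapping type, masking noise: with
#' probability `modality_dropout` one modality's input is zeroed while both
#' targets remain the uncorrupted vectors.  This masking corruption is what
#' lets the phonology-to-semantics mapping emerge without any explicit
#' supervised mapping phase.  The presentations of each mapping type within
#' an epoch form one minibatch gradient step.  Total presentations
#' (`batch_size * epochs`) are identical across exposure-ratio settings, so
#' any performance asymmetry between the two model versions reflects
#' exposure, not amount of training.
#'
#' @param model a `trained_model` (typically pretrained).
#' @param lexicon a `bilingual_lexicon`.
#' @param exposure_ratio length-2 numeric `c(A, B)` of exposure weights,
#'   e.g. `c(3, 1)` for a native-A model; both must be positive when both
#'   languages are present.
#' @param phases_schedule `"interleaved"` (the three mapping types are mixed
#'   in every epoch, 1/3 each in expectation) or `"sequential"` (three
#'   consecutive blocks: phonology, semantics, both).
#' @param corruption_sd SD of the Gaussian input corruption.
#' @param modality_dropout probability, in the joint mapping type, of
#'   zeroing one modality's input (half the probability each).
#' @param epochs number of epochs.
#' @param batch_size presentations per epoch.
#' @param lr learning rate (classical momentum updates).
#' @param momentum momentum coefficient of the weight updates.
#' @param seed integer seed.
#' @return the model with updated weights, `exposure_ratio` recorded and a
#'   `finetune` log (epoch, n_A/n_B draws, per-phase counts, loss).
#' @export
finetune <- function(model, lexicon, exposure_ratio = c(3, 1),
                     phases_schedule = c("interleaved", "sequential"),
                     corruption_sd = 0.1, modality_dropout = 0.5,
                     epochs = 5000L, batch_size = 128L,
                     lr = 0.05, momentum = 0.9, seed = 1L) {
  stopifnot(inherits(model, "trained_model"))
  phases_schedule <- match.arg(phases_schedule)
  lang <- lexicon$words$language
  if (any(exposure_ratio <= 0) && all(c("A", "B") %in% lang))
    stop("zero exposure weight for a language present in the lexicon")
  w_word <- ifelse(lang == "A", exposure_ratio[1L], exposure_ratio[2L])
  prob <- w_word / sum(w_word)
  Xp_all <- lexicon$phon
  Xs_all <- lexicon$sem
  n_words <- nrow(Xp_all)
  arch <- model$arch
  W <- model$W
  phases <- c("phon", "sem", "both")
  V <- list()
  set.seed(seed)
  log_df <- data.frame(epoch = seq_len(epochs), n_A = 0L, n_B = 0L,
                       n_phon = 0L, n_sem = 0L, n_both = 0L, loss = NA_real_)
  for (e in seq_len(epochs)) {
    idx <- sample.int(n_words, batch_size, replace = TRUE, prob = prob)
    ph <- if (phases_schedule == "interleaved") {
      sample(phases, batch_size, replace = TRUE)
    } else {
      phases[pmin(3L, 1L + ((e - 1L) * 3L) %/% epochs)]
    }
    if (length(ph) == 1L) ph <- rep(ph, batch_size)
    log_df$n_A[e] <- sum(lang[idx] == "A")
    log_df$n_B[e] <- sum(lang[idx] == "B")
    total_loss <- 0; n_steps <- 0L
    for (p in phases) {
      sel <- idx[ph == p]
      if (!length(sel)) next
      log_df[[paste0("n_", p)]][e] <- length(sel)
      Tp <- Xp_all[sel, , drop = FALSE]
      Ts <- Xs_all[sel, , drop = FALSE]
      Xp <- if (p %in% c("phon", "both"))
        Tp + matrix(stats::rnorm(length(Tp), 0, corruption_sd), nrow(Tp))
      else matrix(0, nrow(Tp), arch$n_phon)
      Xs <- if (p %in% c("sem", "both"))
        Ts + matrix(stats::rnorm(length(Ts), 0, corruption_sd), nrow(Ts))
      else matrix(0, nrow(Ts), arch$n_sem)
      if (p == "both" && modality_dropout > 0) {
        dr <- stats::runif(nrow(Xp))
        Xs[dr < modality_dropout / 2, ] <- 0
        Xp[dr >= modality_dropout / 2 & dr < modality_dropout, ] <- 0
      }
      st <- finetune_step(W, arch, Xp, Xs, Tp, Ts, p)
      if (!is.finite(st$loss)) stop("non-finite fine-tuning loss at epoch ", e)
      for (nm in names(st$grads)) {
        V[[nm]] <- momentum * (if (is.null(V[[nm]])) 0 else V[[nm]]) +
          st$grads[[nm]]
        W[[nm]] <- W[[nm]] - lr * V[[nm]]
      }
      total_loss <- total_loss + st$loss; n_steps <- n_steps + 1L
    }
    log_df$loss[e] <- total_loss / max(1L, n_steps)
  }
  model$W <- W
  model$exposure_ratio <- exposure_ratio
  model$log$finetune <- log_df
  model
}

#' Train one model version end to end
#'
#' Convenience wrapper: build, pretrain, fine-tune.
#'
#' @inheritParams finetune
#' @param arch an [arch_spec()]; its seed is replaced by `seed`.
#' @param pretrain_epochs epochs per layer for pretraining.
#' @param ... passed to [finetune()].
#' @return a fully trained `trained_model`.
#' @export
train_model <- function(lexicon, exposure_ratio = c(3, 1), arch = arch_spec(),
                        pretrain_epochs = 50L, seed = 1L, ...) {
  arch$seed <- as.integer(seed)
  m <- build_model(arch)
  m <- pretrain(m, lexicon, epochs = pretrain_epochs,
                seed = derive_seed(seed, 1L))
  finetune(m, lexicon, exposure_ratio = exposure_ratio,
           seed = derive_seed(seed, 2L), ...)
}
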
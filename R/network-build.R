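# Deep autoencoder architecture.
#
# Two encoder pathways meet in a shared bottleneck and two decoder pathways
# reconstruct the inputs:
#
#   phonology (292) -> P0 -> P1 \
#                                >-> PS2 (bottleneck)
#   semantics (300) -> S1       /
#   PS2 -> P3 -> phonology out (292)
#   PS2 -> S3 -> S4 -> semantics out (300)
#
# All units are logistic (sigmoid).  Spoken-word recognition is tested by
# presenting phonology alone (zero semantic input) and reading the semantic
# output.

#' Architecture specification
#'
#' @param p0,p1 phonological encoder hidden layer sizes.
#' @param s1 semantic encoder hidden layer size.
#' @param ps2 bottleneck size; must be strictly smaller than both inputs.
#' @param p3 phonological decoder hidden layer size.
#' @param s3,s4 semantic decoder hidden layer sizes.
#' @param n_phon,n_sem input/output dimensionalities.
#' @param seed integer seed for weight initialization.
#' @return an `arch_spec` list.
#' @export
arch_spec <- function(p0 = 200L, p1 = 120L, s1 = 120L, ps2 = 80L,
                      p3 = 200L, s3 = 120L, s4 = 200L,
                      n_phon = 292L, n_sem = 300L, seed = 1L) {
  sizes <- c(p0 = p0, p1 = p1, s1 = s1, ps2 = ps2, p3 = p3, s3 = s3, s4 = s4,
             n_phon = n_phon, n_sem = n_sem)
  if (any(sizes <= 0)) stop("all layer sizes must be positive")
  if (ps2 >= n_phon || ps2 >= n_sem)
    stop("bottleneck (", ps2, ") must be strictly smaller than both inputs")
  structure(c(as.list(sizes), list(seed = as.integer(seed))),
            class = "arch_spec")
}

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

#' Build an untrained model
#'
#' Initializes all weights reproducibly from the architecture's seed
#' (uniform Glorot initialization; biases zero).
#'
#' @param arch an [arch_spec()].
#' @return a `trained_model` object (untrained): list with `arch`, weight
#'   list `W`, an empty training `log`, and `exposure_ratio = NULL`.
#' @export
build_model <- function(arch = arch_spec()) {
  stopifnot(inherits(arch, "arch_spec"))
  set.seed(arch$seed)
  W <- list(
    enc_p0  = glorot(arch$n_phon, arch$p0),  b_p0  = numeric(arch$p0),
    enc_p1  = glorot(arch$p0, arch$p1),      b_p1  = numeric(arch$p1),
    enc_s1  = glorot(arch$n_sem, arch$s1),   b_s1  = numeric(arch$s1),
    enc_pp2 = glorot(arch$p1, arch$ps2),
    enc_sp2 = glorot(arch$s1, arch$ps2),     b_ps2 = numeric(arch$ps2),
    dec_p3  = glorot(arch$ps2, arch$p3),     b_p3  = numeric(arch$p3),
    dec_pout = glorot(arch$p3, arch$n_phon), b_pout = numeric(arch$n_phon),
    dec_s3  = glorot(arch$ps2, arch$s3),     b_s3  = numeric(arch$s3),
    dec_s4  = glorot(arch$s3, arch$s4),      b_s4  = numeric(arch$s4),
    dec_sout = glorot(arch$s4, arch$n_sem),  b_sout = numeric(arch$n_sem))
  structure(list(arch = arch, W = W, exposure_ratio = NULL,
                 log = list(), seed = arch$seed),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  a <- x$arch
  cat("trained_model: phon(", a$n_phon, ") -> P0(", a$p0, ") -> P1(", a$p1,
      ") -> PS2(", a$ps2, ") <- S1(", a$s1, ") <- sem(", a$n_sem, ")\n", sep = "")
  cat("  decoders: PS2 -> P3(", a$p3, ") -> phon; PS2 -> S3(", a$s3,
      ") -> S4(", a$s4, ") -> sem\n", sep = "")
  if (!is.null(x$exposure_ratio))
    cat("  exposure ratio A:B =", paste(x$exposure_ratio, collapse = ":"), "\n")
  cat("  training log stages:", paste(names(x$log), collapse = ", "), "\n")
  invisible(x)
}

# Forward pass over a batch.  Xp: n x 292, Xs: n x 300 (real-valued inputs
# allowed).  Returns all layer activations as matrices.
forward_batch <- function(model, Xp, Xs) {
  W <- model$W
  Xp <- if (is.matrix(Xp)) Xp else matrix(Xp, nrow = 1L)
  Xs <- if (is.matrix(Xs)) Xs else matrix(Xs, nrow = 1L)
  if (ncol(Xp) != model$arch$n_phon)
    stop("phonological input has ", ncol(Xp), " columns, expected ",
         model$arch$n_phon)
  if (ncol(Xs) != model$arch$n_sem)
    stop("semantic input has ", ncol(Xs), " columns, expected ", model$arch$n_sem)
  h_p0 <- sigmoid(sweep(Xp %*% W$enc_p0, 2L, W$b_p0, "+"))
  h_p1 <- sigmoid(sweep(h_p0 %*% W$enc_p1, 2L, W$b_p1, "+"))
  h_s1 <- sigmoid(sweep(Xs %*% W$enc_s1, 2L, W$b_s1, "+"))
  h_ps2 <- sigmoid(sweep(h_p1 %*% W$enc_pp2 + h_s1 %*% W$enc_sp2, 2L,
                         W$b_ps2, "+"))
  h_p3 <- sigmoid(sweep(h_ps2 %*% W$dec_p3, 2L, W$b_p3, "+"))
  y_p <- sigmoid(sweep(h_p3 %*% W$dec_pout, 2L, W$b_pout, "+"))
  h_s3 <- sigmoid(sweep(h_ps2 %*% W$dec_s3, 2L, W$b_s3, "+"))
  h_s4 <- sigmoid(sweep(h_s3 %*% W$dec_s4, 2L, W$b_s4, "+"))
  y_s <- sigmoid(sweep(h_s4 %*% W$dec_sout, 2L, W$b_sout, "+"))
  list(input_phon = Xp, input_sem = Xs, P0 = h_p0, P1 = h_p1, S1 = h_s1,
       PS2 = h_ps2, P3 = h_p3, output_phon = y_p, S3 = h_s3, S4 = h_s4,
       output_sem = y_s)
}

#' Forward pass with activation snapshot
#'
#' Runs a (possibly real-valued, e.g. noisified) input pair through the
#' network and returns the activations of the layers used by the
#' mechanistic analyses.  Deterministic given the model weights.
#'
#' @param model a `trained_model`.
#' @param phon_input numeric vector (length 292) or matrix (n x 292).
#' @param sem_input numeric vector (length 300) or matrix (n x 300);
#'   all-zero in the spoken-word recognition test regime.
#' @return list of activation matrices with elements `input_phon`, `P0`,
#'   `PS2`, `S4`, `output_sem` (class `activation_snapshot`).
#' @export
forward <- function(model, phon_input,
                    sem_input = matrix(0, NROW(phon_input), model$arch$n_sem)) {
  if (!is.matrix(phon_input)) phon_input <- matrix(phon_input, nrow = 1L)
  if (!is.matrix(sem_input)) sem_input <- matrix(sem_input, nrow = 1L)
  act <- forward_batch(model, phon_input, sem_input)
  structure(act[c("input_phon", "P0", "PS2", "S4", "output_sem")],
            class = "activation_snapshot")
}

#' Save / load a trained model checkpoint
#'
#' Checkpoints hold the weights, architecture, exposure configuration,
#' training log and seed.  They are runtime artifacts (RDS), written by the
#' command-line tools between the train and simulate steps.
#'
#' @param model a `trained_model`.
#' @param path checkpoint path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_model")) stop("not a model checkpoint: ", path)
  m
}
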
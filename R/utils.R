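# Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a stage seed from a master seed
#'
#' Every stochastic component of the package draws its seed from a single
#' master seed through this function, so that a whole experiment is
#' reproducible from one integer.  The scheme is a fixed linear congruential
#' step per stage index, kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (>= 0); distinct stages yield distinct
#'   seeds for all practical stage counts.
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  m <- 2147483647
  s <- (as.double(master) %% m)
  for (i in seq_len(stage + 1L)) {
    s <- (s * 48271 + 11) %% m
  }
  as.integer(s)
}

# Pairwise Euclidean distances between the rows of X (n x d) and Y (m x d).
# Returns an n x m matrix.  Used by the nearest-neighbour decoders and the
# rank-order competition measures.
euclidean_cross <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  sx <- rowSums(X^2)
  sy <- rowSums(Y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Cosine distance (1 - cosine similarity) between rows of X.  Rows with zero
# norm are maximally dissimilar (distance 1) to everything, by convention.
cosine_dist <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  Xn <- X / nrm
  s <- tcrossprod(Xn)
  s[s > 1] <- 1; s[s < -1] <- -1
  d <- 1 - s
  if (any(zero)) {
    d[zero, ] <- 1
    d[, zero] <- 1
  }
  diag(d) <- 0
  d
}

# argmin with deterministic first-index tie-break (lexicon order).
which_min_first <- function(x) which(x == min(x))[1L]
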
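test_that("cumulative unique errors reproduce the worked example", {
  # target dollar; responses deur, dolfijn, dolfijn, dollar, dollar
  resp <- c("deur", "dolfijn", "dolfijn", "dollar", "dollar")
  expect_equal(cumulative_unique_errors(resp, "dollar"), c(1, 2, 2, 2, 2))
  expect_equal(cumulative_unique_errors(rep("x", 4), "x"), rep(0, 4))
  # counts freeze after first success, even if later responses err
  expect_equal(cumulative_unique_errors(c("a", "t", "b"), "t"), c(1, 1, 1))
  # counts are non-decreasing
  set.seed(11)
  for (i in 1:20) {
    r <- sample(letters[1:4], 6, replace = TRUE)
    expect_true(all(diff(cumulative_unique_errors(r, "a")) >= 0))
  }
})

test_that("closeness rank matches a brute-force sorted-distance position", {
  lex <- fixture_lexicon()
  m <- fixture_models()$native[[1L]]
  refs <- reference_activations(m, lex)
  idx <- language_index(lex, "B")
  set.seed(13)
  X <- incremental_matrix <- phon_matrix(lex, use_prosody = FALSE,
                                         language_unit = "none")[idx, ] +
    matrix(rnorm(length(idx) * 292, 0, 0.5), length(idx))
  act <- forward(m, X)
  for (layer in c("input_phon", "PS2", "S4", "output_sem")) {
    R <- refs[[layer]][idx, , drop = FALSE]
    A <- act[[layer]]
    for (w in c(1L, 4L, 8L)) {
      got <- closeness_rank(A[w, ], R, w)
      d <- apply(R, 1L, function(r) sqrt(sum((A[w, ] - r)^2)))
      expect_equal(got, unname(rank(d, ties.method = "first")[w]))
    }
  }
  # the target's own full pattern is rank 1 at the input layer
  X0 <- phon_matrix(lex, use_prosody = FALSE, language_unit = "none")[idx, ]
  expect_equal(closeness_rank(X0[3L, ], X0, 3L), 1L)
  expect_error(closeness_rank(X0[1L, ], X0, 999L), "target")
})

test_that("a printed top-3 ordering yields rank 2", {
  # top matches deur, dollar, dolfijn for target dollar -> rank 2
  refs <- rbind(deur = c(0, 0.1), dollar = c(0, 0.25), dolfijn = c(0, 0.6))
  query <- c(0, 0)
  expect_equal(closeness_rank(query, refs, "dollar"), 2L)
})

test_that("interlingual rank respects its scope", {
  lex <- fixture_lexicon()
  m <- fixture_models()$native[[1L]]
  refs <- reference_activations(m, lex)
  idx_n <- language_index(lex, "A")
  set.seed(14)
  x <- runif(300)
  r <- interlingual_rank(x, refs$output_sem, idx_n,
                         target = idx_n[5L])
  expect_lte(r, length(idx_n))
  d <- apply(refs$output_sem[idx_n, ], 1L, function(v) sqrt(sum((x - v)^2)))
  expect_equal(r, unname(rank(d, ties.method = "first")[5L]))
})

test_that("RDMs are symmetric, zero-diagonal and match a pairwise loop", {
  set.seed(15)
  A <- matrix(runif(8 * 6), 8, 6)
  A[3L, ] <- A[1L, ]          # identical pair -> distance 0
  A[5L, ] <- 0                # zero-norm row -> distance 1 by convention
  rdm <- build_rdm(A)
  expect_equal(dim(rdm), c(8L, 8L))
  expect_equal(unname(diag(rdm)), rep(0, 8))
  expect_equal(rdm, t(rdm), ignore_attr = TRUE)
  expect_equal(rdm[1L, 3L], 0)
  expect_true(all(rdm[5L, -5L] == 1))
  for (i in 1:8) for (j in 1:8) {
    if (i == j || i == 5L || j == 5L) next
    want <- 1 - sum(A[i, ] * A[j, ]) /
      (sqrt(sum(A[i, ]^2)) * sqrt(sum(A[j, ]^2)))
    expect_equal(rdm[i, j], want, tolerance = 1e-12)
  }
  # orthogonal activations -> distance 1
  B <- rbind(c(1, 0), c(0, 1))
  expect_equal(build_rdm(B)[1L, 2L], 1)
})

test_that("RSA correlation behaves at its fixed points", {
  set.seed(16)
  A <- matrix(runif(12 * 5), 12, 5)
  rdm <- build_rdm(A)
  expect_equal(rsa_correlate(rdm, rdm), 1)
  neg <- 1 - rdm
  diag(neg) <- 0
  expect_equal(rsa_correlate(rdm, neg), -1)
  const <- matrix(1, 12, 12); diag(const) <- 0
  expect_true(is.na(rsa_correlate(rdm, 0 * rdm)))
  expect_true(all(abs(rsa_correlate(rdm, build_rdm(matrix(runif(60), 12)))) <= 1))
})

test_that("online accuracy equals the rank-1 fraction (cross-module)", {
  ranks <- c(1L, 2L, 1L, 5L, 1L)
  expect_equal(online_accuracy(ranks), 3 / 5)
  # cross-module: identification correctness at t equals rank-1 outcomes
  lex <- fixture_lexicon()
  m <- fixture_models()$native[[1L]]
  idx <- language_index(lex, "B")
  refs <- lex$sem[idx, , drop = FALSE]
  for (t in c(2L, 4L)) {
    X <- noisylex:::incremental_matrix(lex, idx, t)
    out <- forward(m, X)$output_sem
    rks <- vapply(seq_along(idx), function(w)
      closeness_rank(out[w, ], refs, w), integer(1))
    correct <- identify_word(m, X, lex, "B")$response_idx == idx
    expect_equal(online_accuracy(rks), mean(correct))
    expect_equal(rks == 1L, unname(correct))
  }
  # clean accuracy approaches ceiling by the last timestep
  mech <- fixture_mechanistic()
  acc <- mech$accuracy
  a5 <- acc$value[acc$version == "native" & acc$sd == 0 & acc$t == 5]
  expect_gte(mean(a5), 0.9)
})
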
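test_that("architecture validation rejects a non-bottleneck", {
  expect_error(arch_spec(ps2 = 292L), "bottleneck")
  expect_error(arch_spec(p0 = 0L), "positive")
})

test_that("building is deterministic from the seed", {
  m1 <- build_model(arch_spec(seed = 5L))
  m2 <- build_model(arch_spec(seed = 5L))
  expect_identical(m1$W, m2$W)
  m3 <- build_model(arch_spec(seed = 6L))
  expect_false(identical(m1$W, m3$W))
})

test_that("forward pass exposes the documented layers at the right sizes", {
  m <- build_model(arch_spec(seed = 1L))
  snap <- forward(m, numeric(292), numeric(300))
  expect_named(snap, c("input_phon", "P0", "PS2", "S4", "output_sem"))
  expect_equal(vapply(snap, ncol, integer(1)),
               c(input_phon = 292L, P0 = 200L, PS2 = 80L, S4 = 200L,
                 output_sem = 300L))
  # sigmoid outputs are finite and inside (0, 1) even for all-zero input
  expect_true(all(is.finite(snap$output_sem)))
  expect_true(all(snap$output_sem > 0 & snap$output_sem < 1))
  # omitted semantic input defaults to zero (test regime)
  snap2 <- forward(m, numeric(292))
  expect_identical(snap$output_sem, snap2$output_sem)
  expect_error(forward(m, numeric(100)), "292")
})

test_that("forward is deterministic and sensitive to single input bits", {
  lex <- fixture_tiny_lexicon()
  m <- train_model(lex, c(1, 1), seed = 2L, epochs = 100L,
                   batch_size = 32L, lr = 0.05)
  x <- lex$phon[1L, ]
  s1 <- forward(m, x)
  s2 <- forward(m, x)
  expect_identical(s1, s2)
  x2 <- x
  x2[5L] <- 1 - x2[5L]
  s3 <- forward(m, x2)
  expect_false(isTRUE(all.equal(s1$P0, s3$P0)))
})

test_that("pretraining with zero epochs is a no-op and otherwise reduces error", {
  lex <- fixture_tiny_lexicon()
  m0 <- build_model(arch_spec(seed = 3L))
  expect_identical(pretrain(m0, lex, epochs = 0L)$W, m0$W)
  m1 <- pretrain(m0, lex, epochs = 50L, seed = 4L)
  lg <- m1$log$pretrain
  for (layer in unique(lg$layer)) {
    tr <- lg$loss[lg$layer == layer]
    expect_lt(tr[length(tr)], tr[1L])
  }
  m2 <- pretrain(m0, lex, epochs = 50L, seed = 4L)
  expect_identical(m1$W, m2$W)
})

test_that("fine-tuning is reproducible and honours the exposure ratio", {
  lex <- fixture_tiny_lexicon()
  m0 <- pretrain(build_model(arch_spec(seed = 5L)), lex, epochs = 20L,
                 seed = 6L)
  m1 <- finetune(m0, lex, exposure_ratio = c(3, 1), epochs = 150L,
                 batch_size = 32L, seed = 8L)
  m2 <- finetune(m0, lex, exposure_ratio = c(3, 1), epochs = 150L,
                 batch_size = 32L, seed = 8L)
  expect_identical(m1$W, m2$W)
  lg <- m1$log$finetune
  n_A <- sum(lg$n_A); n_tot <- sum(lg$n_A + lg$n_B)
  # binomial check on the draws: expected fraction 0.75
  expect_lt(abs(n_A / n_tot - 0.75), 3 * sqrt(0.75 * 0.25 / n_tot))
  expect_error(finetune(m0, lex, exposure_ratio = c(1, 0)), "zero exposure")
})

test_that("both versions see the same total number of presentations", {
  lex <- fixture_tiny_lexicon()
  m0 <- pretrain(build_model(arch_spec(seed = 5L)), lex, epochs = 10L,
                 seed = 6L)
  mA <- finetune(m0, lex, exposure_ratio = c(3, 1), epochs = 60L,
                 batch_size = 32L, seed = 1L)
  mB <- finetune(m0, lex, exposure_ratio = c(1, 3), epochs = 60L,
                 batch_size = 32L, seed = 1L)
  tot <- function(m) sum(m$log$finetune$n_A + m$log$finetune$n_B)
  expect_equal(tot(mA), tot(mB))
  expect_equal(tot(mA), 60L * 32L)
})

test_that("trained models reach ceiling on the majority language, clean", {
  lex <- fixture_lexicon()
  models <- fixture_models()
  accs <- sapply(c("native", "nonnative"), function(v) {
    mean(sapply(models[[v]], function(m) {
      idx <- language_index(lex, "B")
      Xp <- phon_matrix(lex, use_prosody = FALSE,
                        language_unit = "B")[idx, , drop = FALSE]
      mean(identify_word(m, Xp, lex, "B")$response_idx == idx)
    }))
  })
  # language B is the majority language of the native version
  expect_gte(accs["native"], 0.9)
  expect_lte(accs["nonnative"], accs["native"])
})

test_that("the sequential phase schedule trains in three blocks", {
  lex <- fixture_tiny_lexicon()
  m0 <- pretrain(build_model(arch_spec(seed = 9L)), lex, epochs = 5L,
                 seed = 2L)
  m <- finetune(m0, lex, exposure_ratio = c(1, 1),
                phases_schedule = "sequential", epochs = 90L,
                batch_size = 16L, seed = 3L)
  lg <- m$log$finetune
  # first third phonology-only, middle third semantics-only, last third joint
  expect_true(all(lg$n_phon[1:30] == 16L & lg$n_sem[1:30] == 0L))
  expect_true(all(lg$n_sem[31:60] == 16L & lg$n_both[31:60] == 0L))
  expect_true(all(lg$n_both[61:90] == 16L & lg$n_phon[61:90] == 0L))
})
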
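# Shared fixtures, built once per test run and cached.  The trained fixture
# is the expensive part (~10 models at reduced scale); every test that needs
# trained networks reuses it.

.fixtures <- new.env(parent = emptyenv())

fixture_lexicon <- function() {
  if (is.null(.fixtures$lex))
    .fixtures$lex <- generate_synthetic_lexicon(
      n_pairs = 20L, disyllabic_count = c(A = 7L, B = 8L), seed = 42L)
  .fixtures$lex
}

# 5 trained replications per version at reduced scale; language B is the
# native (majority) language of the "native" version, as in the online and
# mechanistic simulations.
fixture_models <- function() {
  if (is.null(.fixtures$models)) {
    lex <- fixture_lexicon()
    .fixtures$models <- list(
      native = lapply(1:5, function(r)
        train_model(lex, exposure_ratio = c(1, 3),
                    seed = derive_seed(7L, 10L + r),
                    epochs = 1000L, batch_size = 64L, lr = 0.05)),
      nonnative = lapply(1:5, function(r)
        train_model(lex, exposure_ratio = c(3, 1),
                    seed = derive_seed(7L, 20L + r),
                    epochs = 1000L, batch_size = 64L, lr = 0.05)))
  }
  .fixtures$models
}

fixture_offline <- function() {
  if (is.null(.fixtures$offline))
    .fixtures$offline <- run_offline_experiment(
      fixture_models(), fixture_lexicon(), target_language = "B",
      repetitions = 10L, seed = 101L)
  .fixtures$offline
}

fixture_displays <- function() {
  if (is.null(.fixtures$displays))
    .fixtures$displays <- build_displays(fixture_lexicon(), "B")
  .fixtures$displays
}

fixture_online <- function() {
  if (is.null(.fixtures$online))
    .fixtures$online <- run_online_experiment(
      fixture_models(), fixture_lexicon(), fixture_displays(),
      target_language = "B", noise_sds = c(0, 0.3, 0.6),
      repetitions = 10L, seed = 77L)
  .fixtures$online
}

fixture_mechanistic <- function() {
  if (is.null(.fixtures$mech))
    .fixtures$mech <- run_mechanistic(
      fixture_models(), fixture_lexicon(), target_language = "B",
      noise_sds = c(0, 0.75), repetitions = 5L, seed = 55L)
  .fixtures$mech
}

# tiny lexicon for cheap structural tests
fixture_tiny_lexicon <- function() {
  if (is.null(.fixtures$tiny))
    .fixtures$tiny <- generate_synthetic_lexicon(
      n_pairs = 6L, disyllabic_count = c(A = 2L, B = 3L), seed = 9L)
  .fixtures$tiny
}

# brute-force Euclidean nearest neighbour (independent of the package's
# vectorized distance code)
brute_nearest <- function(x, refs) {
  d <- apply(refs, 1L, function(r) sqrt(sum((x - r)^2)))
  which(d == min(d))[1L]
}
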
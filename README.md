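# noisylex

Simulating native and non-native spoken-word recognition in background
noise with a bilingual deep-autoencoder lexicon.

## What this is for

Recognizing a spoken word means beating its phonological neighbours:
similarly sounding words are co-activated and compete until the input
disambiguates them.  Background noise enlarges this competitor space —
listeners make more *distinct* misperception errors, and looks to onset
competitors in visual-world eye-tracking persist longer — and non-native
listeners show the same effects, amplified.  `noisylex` is for researchers
in psycholinguistics and computational cognitive science who want a fully
inspectable model of these phenomena: a neural network whose recognition
behavior reproduces the offline and online signatures of competition under
noise, and whose internal activation states can be queried directly to ask
*how many* competitors are engaged at every moment.

## The model

A deep autoencoder maps a 292-bit slot/feature phonological code and a
300-bit sparse binary semantic code through a shared bottleneck:

```
phonology (292) -> P0 (200) -> P1 (120) \
                                         >-> PS2 (80)
semantics (300) -> S1 (120)             /
PS2 -> P3 (200) -> phonology out;  PS2 -> S3 (120) -> S4 (200) -> semantics out
```

Training interleaves three reconstruction mappings (phonology alone,
semantics alone, both together) under denoising corruption; the network is
never trained explicitly on sound-to-meaning mapping, yet after training a
phonological input alone yields the right semantics at the output layer
(decoded by a Euclidean nearest-neighbour rule over the vocabulary).
"Native" and "non-native" versions share the identical architecture and
differ only in the language exposure ratio (3:1 vs 1:3) during training,
with the total number of presentations held equal.

Word recognition under noise is simulated by adding Gaussian noise
(SD 0.30 / 0.60 / 0.90) to the occupied slots of the input — whole-word,
word-initial or word-final — and online recognition by presenting phonemes
incrementally (timestep *t* = first *t* phonemes; *t* = 0 is the silent
baseline).  An *Input-based* baseline with no training (nearest
phonological form wins) isolates how much behavior comes from the input
code rather than from learning.  Mechanistic analyses compute rank-order
closeness of each layer's activation to every word's reference pattern,
cumulative unique misperception errors, and representational similarity
(cosine-distance RDMs correlated against the training set's phonological
and semantic structure).

## Worked example

```r
library(noisylex)

# a small bilingual lexicon: 20 translation pairs
lex <- generate_synthetic_lexicon(n_pairs = 20,
                                  disyllabic_count = c(A = 7, B = 8),
                                  seed = 42)
print(lex)
#> bilingual_lexicon: 40 lexemes, 20 translation pairs
#>   language A : 20 words ( 7 disyllabic )
#>   language B : 20 words ( 8 disyllabic )
#>   phonology: 292 bits; semantics: 300 bits, mean popcount 54.2

# one native-B and one non-native-B listener (exposure 1:3 vs 3:1)
native    <- train_model(lex, exposure_ratio = c(1, 3), seed = 1,
                         epochs = 1000, batch_size = 64, lr = 0.05)
nonnative <- train_model(lex, exposure_ratio = c(3, 1), seed = 1,
                         epochs = 1000, batch_size = 64, lr = 0.05)

# offline identification in graded, positioned noise
trials <- run_offline_experiment(list(native = native, nonnative = nonnative),
                                 lex, target_language = "B",
                                 repetitions = 10, seed = 7)
print(summarize_offline(trials), digits = 3)
#>      version  sd position accuracy unique_errors
#> 1     native 0.0    whole    1.000           NaN
#> 3     native 0.3    final    1.000           NaN
#> 2     native 0.3  initial    0.995          1.00
#> 5     native 0.6    final    0.965          1.40
#> 4     native 0.6  initial    0.865          2.00
#> 7     native 0.9    final    0.830          1.83
#> 6     native 0.9  initial    0.665          2.58
#> 8  nonnative 0.0    whole    1.000           NaN
#> 10 nonnative 0.3    final    1.000           NaN
#> 9  nonnative 0.3  initial    0.980          2.00
#> 12 nonnative 0.6    final    0.935          1.67
#> 11 nonnative 0.6  initial    0.800          2.27
#> 14 nonnative 0.9    final    0.750          2.64
#> 13 nonnative 0.9  initial    0.565          3.25

fit <- effect_model_accuracy(trials)
print(fit, digits = 3)
#>          term estimate    se      z        p
#> 1 (Intercept)    6.567 0.329  19.94 1.74e-88
#> 2   intensity   -4.934 0.330 -14.95 1.47e-50
#> 3     initial   -1.041 0.136  -7.63 2.28e-14
#> 4   nonnative   -0.494 0.132  -3.75 1.78e-04
```

Reading the output: identification accuracy is perfect in the clear and
falls as noise SD rises; word-initial masking hurts more than word-final
(onsets carry more information under the left-aligned code); the
non-native version is consistently below the native one; and the number
of distinct misperceptions per erring word (`unique_errors`; `NaN` when no
word erred) grows exactly where accuracy falls — the
many-additional-competitors signature.  The binomial effect model returns
all three effects with negative signs (accuracy falls with noise
intensity, initial masking, non-nativeness), each with cluster-robust
errors when several trained replications are present.

The online simulation and mechanistic analyses follow the same pattern —
see `run_online_experiment()`, `run_mechanistic()` and the vignette
(`vignettes/recognition-in-noise.Rmd`) for the model's full story, and
`inst/cli/noisylex` for the command-line front end
(`generate-lexicon`, `train`, `simulate-offline`, `simulate-online`,
`mechanistic`, `rsa`, `stats`, `run-all`).

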
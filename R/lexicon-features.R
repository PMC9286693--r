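# Phoneme feature table: a fixed inventory of SAMPA-style symbols, each with
# a 22-bit articulatory feature row (consonant place/manner/voicing, vowel
# height/backness/length).  The table ships with the package as a TSV so the
# encoding scheme is inspectable and overridable.

.noisylex <- new.env(parent = emptyenv())

#' Phoneme feature table
#'
#' Returns the phoneme inventory used by the phonological encoder: one row
#' per SAMPA symbol, a `type` column (`"C"` consonant / `"V"` vowel) and 22
#' binary articulatory feature columns.  Distinct phonemes are guaranteed to
#' have distinct feature rows, and no row is all-zero (so occupied template
#' slots are always distinguishable from empty ones).
#'
#' @param path optional path to an alternative feature TSV with the same
#'   column layout; defaults to the table shipped in `extdata`.
#' @return a data.frame with columns `symbol`, `type` and 22 feature columns.
#' @export
phoneme_features <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.noisylex$features)) return(.noisylex$features)
    path <- system.file("extdata", "phoneme_features.tsv", package = "noisylex")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  feat_cols <- setdiff(names(tab), c("symbol", "type"))
  if (length(feat_cols) != 22L)
    stop("feature table must have exactly 22 feature columns, found ",
         length(feat_cols))
  fm <- as.matrix(tab[, feat_cols])
  if (!all(fm %in% c(0, 1))) stop("feature table entries must be 0/1")
  if (anyDuplicated(tab$symbol)) stop("duplicate phoneme symbols in table")
  key <- apply(fm, 1L, paste, collapse = "")
  if (anyDuplicated(key)) stop("feature rows are not injective over phonemes")
  if (any(rowSums(fm) == 0)) stop("all-zero feature row found")
  rownames(fm) <- tab$symbol
  out <- tab
  attr(out, "matrix") <- fm
  if (cache) .noisylex$features <- out
  out
}

# feature matrix (symbols x 22) for fast lookup
feature_matrix <- function(features = phoneme_features()) attr(features, "matrix")

phoneme_type <- function(symbols, features = phoneme_features()) {
  idx <- match(symbols, features$symbol)
  if (anyNA(idx)) {
    bad <- symbols[is.na(idx)][1L]
    stop("unknown phoneme symbol: '", bad, "'")
  }
  features$type[idx]
}

# Layout constants of the 292-bit phonological vector:
# 13 slots x 22 features, then 2 length bits, 2 stress bits, 2 language bits.
PHON_SLOTS <- 13L
PHON_FEATS <- 22L
PHON_BITS <- PHON_SLOTS * PHON_FEATS + 6L  # 292

slot_bits <- function(slot) ((slot - 1L) * PHON_FEATS + 1L):(slot * PHON_FEATS)
LENGTH_BITS <- 287:288
STRESS_BITS <- 289:290
LANG_BITS <- 291:292
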
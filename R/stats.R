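# Comparison machinery: effect models on trial tables, binwise one-tailed
# tests on looking preferences, and overall / factor-focused fit
# correlations between model-based and human condition tables.

#' Effect model for identification accuracy
#'
#' Binomial-family regression of trial correctness on noise intensity
#' (numeric, scaled to [0, 1] over the observed SD grid), noise position
#' (indicator for word-initial masking) and group (indicator for the
#' non-native version), with cluster-robust standard errors by trained
#' replication.  Under this coding all three coefficients are expected to
#' be negative when accuracy falls with noise, with word-initial masking,
#' and in non-native listening.  Single-level factors are dropped with a
#' warning.
#'
#' @param trials trial table from [run_offline_experiment()] (both versions
#'   included for a group effect; version `"native"` is the reference).
#' @return data.frame of coefficients: `term`, `estimate`, `se`, `z`, `p`
#'   (robust errors clustered on replication when >1 replication present).
#' @export
effect_model_accuracy <- function(trials) {
  d <- trials
  d$intensity <- if (max(d$sd) > 0) d$sd / max(d$sd) else d$sd
  d$initial <- as.numeric(d$position == "initial")
  d$nonnative <- as.numeric(d$version != "native")
  terms <- c("intensity", "initial", "nonnative")
  keep <- vapply(terms, function(tm) length(unique(d[[tm]])) > 1L, logical(1))
  if (any(!keep))
    warning("dropping single-level terms: ",
            paste(terms[!keep], collapse = ", "))
  terms <- terms[keep]
  if (!length(terms)) stop("no varying factors in the trial table")
  f <- stats::as.formula(paste("correct ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(f, family = stats::binomial(), data = d)
  if (length(unique(d$replication)) > 1L) {
    # one cluster per trained network (version x replication)
    vc <- sandwich::vcovCL(fit, cluster = interaction(d$version, d$replication))
    ct <- lmtest::coeftest(fit, vcov. = vc)
    out <- data.frame(term = rownames(ct), estimate = ct[, 1L],
                      se = ct[, 2L], z = ct[, 3L], p = ct[, 4L],
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    s <- summary(fit)$coefficients
    out <- data.frame(term = rownames(s), estimate = s[, 1L], se = s[, 2L],
                      z = s[, 3L], p = s[, 4L],
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Binwise one-tailed t-tests on looking preferences
#'
#' Item-based analysis: for each timestep bin, a paired one-tailed t-test
#' compares the per-item looking preferences in that bin with the per-item
#' baseline values (greater-than alternative).  Baseline-corrected series
#' may simply pass a zero baseline.  If all items equal the baseline the
#' bin reports `t = 0, p = 0.5`; other zero-variance cases report `p = NA`.
#'
#' @param items data.frame with columns `target` (item), `t` (bin) and
#'   `preference`; one row per item x bin.
#' @param baseline_t which bin is the baseline (default 0).
#' @return data.frame per non-baseline bin: `t_bin`, `n_items`,
#'   `t_statistic`, `p`, `significant` (at alpha = 0.05).
#' @export
binwise_ttests <- function(items, baseline_t = 0) {
  base <- items[items$t == baseline_t, ]
  if (nrow(base) == 0L) stop("no baseline bin in the item table")
  bins <- setdiff(sort(unique(items$t)), baseline_t)
  rows <- lapply(bins, function(b) {
    cur <- items[items$t == b, ]
    m <- merge(cur[c("target", "preference")], base[c("target", "preference")],
               by = "target", suffixes = c("", "_base"))
    if (nrow(m) < 2L) stop("need >= 2 items per bin")
    diffs <- m$preference - m$preference_base
    if (stats::sd(diffs) == 0) {
      tstat <- if (all(diffs == 0)) 0 else NA_real_
      p <- if (all(diffs == 0)) 0.5 else NA_real_
    } else {
      tt <- stats::t.test(m$preference, m$preference_base, paired = TRUE,
                          alternative = "greater")
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(t_bin = b, n_items = nrow(m), t_statistic = tstat, p = p,
               significant = !is.na(p) & p < 0.05)
  })
  do.call(rbind, rows)
}

check_cells <- function(model_table, human_table, measure) {
  keys <- c("intensity", "position", "group")
  keys <- keys[keys %in% names(model_table) & keys %in% names(human_table)]
  m <- model_table[model_table$measure == measure, , drop = FALSE]
  h <- human_table[human_table$measure == measure, , drop = FALSE]
  mg <- merge(m, h, by = keys, suffixes = c("_model", "_human"))
  list(merged = mg, keys = keys)
}

#' Overall fit of model to human condition means
#'
#' Pearson correlation between model-based and human cell means over all
#' levels of all factors for one measure.
#'
#' @param model_table,human_table tidy tables with factor columns (any of
#'   `intensity`, `position`, `group`), a `measure` column and a `value`
#'   column.
#' @param measure which measure to correlate.
#' @return list with `r`, `p`, `n_cells`.
#' @export
overall_fit <- function(model_table, human_table, measure) {
  cc <- check_cells(model_table, human_table, measure)
  mg <- cc$merged
  if (nrow(mg) < 3L) stop("need at least 3 matched cells, got ", nrow(mg))
  ct <- stats::cor.test(mg$value_model, mg$value_human)
  list(r = unname(ct$estimate), p = ct$p.value, n_cells = nrow(mg))
}

#' Factor-focused fit
#'
#' Correlates the model's and the human's difference vectors for one factor:
#' for each non-baseline level of the factor and each combination of the
#' other factors' levels, the cell value minus the corresponding
#' baseline-level value.  A model difference vector with zero variance
#' (e.g., the Input-based baseline across groups) yields `r = NA` and is
#' reported as a non-capture.
#'
#' @inheritParams overall_fit
#' @param factor_name the factor in focus.
#' @param baseline_level its baseline level.
#' @return list with `r`, `p`, `n_diffs`, `captured` (FALSE when the model
#'   difference vector is constant or the correlation is undefined).
#' @export
factor_focused_fit <- function(model_table, human_table, measure,
                               factor_name, baseline_level) {
  cc <- check_cells(model_table, human_table, measure)
  mg <- cc$merged
  keys <- cc$keys
  if (!factor_name %in% keys) stop("unknown factor: ", factor_name)
  others <- setdiff(keys, factor_name)
  base <- mg[mg[[factor_name]] == baseline_level, , drop = FALSE]
  if (nrow(base) == 0L) stop("baseline level not present: ", baseline_level)
  rest <- mg[mg[[factor_name]] != baseline_level, , drop = FALSE]
  m <- merge(rest, base[, c(others, "value_model", "value_human")],
             by = others, suffixes = c("", "_base"))
  if (nrow(m) < nrow(rest))
    stop("incomplete cells: missing baseline combinations for ",
         paste(setdiff(do.call(paste, rest[others]), do.call(paste, m[others])),
               collapse = "; "))
  dm <- m$value_model - m$value_model_base
  dh <- m$value_human - m$value_human_base
  if (length(dm) < 3L || stats::sd(dm) == 0 || stats::sd(dh) == 0)
    return(list(r = NA_real_, p = NA_real_, n_diffs = length(dm),
                captured = FALSE))
  ct <- stats::cor.test(dm, dh)
  list(r = unname(ct$estimate), p = ct$p.value, n_diffs = length(dm),
       captured = is.finite(ct$estimate) && ct$p.value < 0.05)
}
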
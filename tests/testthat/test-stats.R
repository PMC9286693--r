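# Synthetic trial table with known logit effects, for the effect model.
simulate_trials <- function(n_per_cell, b0 = 2, b_int = -2, b_pos = -0.5,
                            b_grp = -0.4, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(sd = c(0, 0.3, 0.6, 0.9),
                      position = c("initial", "final"),
                      version = c("native", "nonnative"),
                      replication = 1:4, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    eta <- b0 + b_int * (g$sd / 0.9) + b_pos * (g$position == "initial") +
      b_grp * (g$version == "nonnative")
    p <- 1 / (1 + exp(-eta))
    data.frame(version = g$version, replication = g$replication, sd = g$sd,
               position = g$position,
               correct = runif(n_per_cell) < p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("effect model recovers a null group effect", {
  tr <- simulate_trials(300, b_grp = 0, seed = 2)
  fit <- effect_model_accuracy(tr)
  grp <- fit[fit$term == "nonnative", ]
  expect_gt(grp$p, 0.05)
  expect_lt(abs(grp$estimate), 0.3)
})

test_that("effect model matches an independent IRLS implementation", {
  tr <- simulate_trials(25, seed = 3)  # 800 rows
  fit <- effect_model_accuracy(tr)
  # hand-rolled iteratively reweighted least squares for logistic regression
  X <- cbind(1, tr$sd / max(tr$sd), as.numeric(tr$position == "initial"),
             as.numeric(tr$version == "nonnative"))
  y <- as.numeric(tr$correct)
  beta <- rep(0, 4)
  for (i in 1:50) {
    eta <- X %*% beta
    mu <- 1 / (1 + exp(-eta))
    w <- as.numeric(mu * (1 - mu))
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  expect_equal(fit$estimate, as.numeric(beta), tolerance = 1e-6)
})

test_that("effect-model estimates converge to the generating logits", {
  errs <- sapply(c(50, 800), function(n) {
    tr <- simulate_trials(n, seed = 5)
    fit <- effect_model_accuracy(tr)
    sum(abs(fit$estimate[-1L] - c(-2, -0.5, -0.4)))
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.5)
})

test_that("single-level factors are dropped with a warning", {
  tr <- simulate_trials(20, seed = 6)
  tr$version <- "native"
  expect_warning(fit <- effect_model_accuracy(tr), "nonnative")
  expect_false("nonnative" %in% fit$term)
})

test_that("binwise t-tests match the closed form and handle degenerate bins", {
  items <- data.frame(
    target = rep(c("w1", "w2", "w3"), times = 2),
    t = rep(c(0, 1), each = 3),
    preference = c(0, 0, 0, 0.4, 0.1, 0.4))
  got <- binwise_ttests(items)
  x <- c(0.4, 0.1, 0.4)
  t_hand <- mean(x) / (sd(x) / sqrt(3))
  expect_equal(got$t_statistic, t_hand)
  expect_equal(got$p, pt(t_hand, df = 2, lower.tail = FALSE))
  # all items identical to baseline
  flat <- data.frame(target = rep(c("a", "b"), 2), t = rep(c(0, 1), each = 2),
                     preference = rep(0.3, 4))
  gf <- binwise_ttests(flat)
  expect_equal(gf$t_statistic, 0)
  expect_equal(gf$p, 0.5)
  # zero variance but non-zero shift: p missing
  shift <- flat
  shift$preference[shift$t == 1] <- 0.9
  gs <- binwise_ttests(shift)
  expect_true(is.na(gs$p))
})

test_that("overall fit reaches its fixed points and a hand covariance", {
  tab <- expand.grid(intensity = c(0, 0.3, 0.6), position = c("i", "f"),
                     stringsAsFactors = FALSE)
  tab$measure <- "accuracy"
  set.seed(7)
  tab$value <- runif(nrow(tab))
  self <- overall_fit(tab, tab, "accuracy")
  expect_equal(self$r, 1)
  anti <- tab; anti$value <- -tab$value
  expect_equal(overall_fit(tab, anti, "accuracy")$r, -1)
  other <- tab; other$value <- rnorm(nrow(tab))
  got <- overall_fit(tab, other, "accuracy")
  m <- merge(tab, other, by = c("intensity", "position", "measure"))
  r_hand <- sum((m$value.x - mean(m$value.x)) * (m$value.y - mean(m$value.y))) /
    sqrt(sum((m$value.x - mean(m$value.x))^2) *
         sum((m$value.y - mean(m$value.y))^2))
  expect_equal(got$r, r_hand)
  expect_equal(got$n_cells, 6L)
  expect_error(overall_fit(tab[1:2, ], tab[1:2, ], "accuracy"), "3 matched")
})

test_that("fits are invariant to adding a constant to both tables", {
  tab <- expand.grid(intensity = c(0, 0.5, 1), group = c("nat", "non"),
                     stringsAsFactors = FALSE)
  tab$measure <- "m"
  set.seed(8)
  tab$value <- rnorm(6)
  hum <- tab; hum$value <- tab$value * 2 + rnorm(6, sd = 0.1)
  r1 <- overall_fit(tab, hum, "m")$r
  tab2 <- tab; tab2$value <- tab$value + 5
  hum2 <- hum; hum2$value <- hum$value + 5
  expect_equal(overall_fit(tab2, hum2, "m")$r, r1)
  f1 <- factor_focused_fit(tab, hum, "m", "group", "nat")$r
  f2 <- factor_focused_fit(tab2, hum2, "m", "group", "nat")$r
  expect_equal(f1, f2)
})

test_that("factor-focused fit enumerates difference vectors correctly", {
  grid <- expand.grid(intensity = c(0, 1), position = c("i", "f"),
                      group = c("nat", "non"), stringsAsFactors = FALSE)
  grid$measure <- "m"
  model <- grid; model$value <- c(1, 2, 3, 4, 6, 9, 13, 20)
  human <- grid; human$value <- c(2, 4, 6, 8, 10, 12, 15, 22)
  got <- factor_focused_fit(model, human, "m", "group", "nat")
  # hand enumeration over the 4 (intensity x position) combinations
  dm <- model$value[grid$group == "non"] - model$value[grid$group == "nat"]
  dh <- human$value[grid$group == "non"] - human$value[grid$group == "nat"]
  expect_equal(got$n_diffs, 4L)
  expect_equal(got$r, cor(dm, dh))
  # identical tables give r = 1
  expect_equal(factor_focused_fit(model, model, "m", "group", "nat")$r, 1)
  # constant model differences: non-capture
  flat <- model; flat$value <- rep(c(1, 2, 3, 4), 2)
  nc <- factor_focused_fit(flat, human, "m", "group", "nat")
  expect_true(is.na(nc$r))
  expect_false(nc$captured)
})
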
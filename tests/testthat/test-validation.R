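test_that("q2 follows its definitional arithmetic", {
  y <- c(1, 2, 3)
  expect_equal(q2_statistic(y, y), 1)
  expect_equal(q2_statistic(y, rep(mean(y), 3)), 0)
  expect_equal(q2_statistic(y, c(1, 2, 4), y_mean = 2), 0.5)
  expect_error(q2_statistic(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("rpred2 decomposes into PRESS over SD", {
  y <- c(5, 6, 7)
  r <- rpred2_statistic(y, y, train_mean = 5.5)
  expect_equal(r$press, 0)
  expect_equal(r$rpred2, 1)
  r2 <- rpred2_statistic(y, c(5.5, 6, 6.5), train_mean = 5.5)
  expect_equal(r2$press, 0.5)
  expect_equal(r2$sd, 0.25 + 0.25 + 2.25)
  expect_equal(r2$rpred2, 1 - 0.5 / 2.75)
  expect_error(rpred2_statistic(c(5, 5), c(5, 5), 5), "zero SD")
})

test_that("through-origin slopes and rm2 follow their closed forms", {
  set.seed(15)
  y <- rnorm(8, 6, 0.8)
  # identity predictions: every statistic is exactly 1
  g <- golbraikh_tropsha(y, y)
  expect_equal(c(g$r2, g$k, g$k_prime, g$r0_2, g$r0_prime_2, g$rm2),
               rep(1, 6), tolerance = 1e-12)
  # doubled predictions halve k: k = sum(y*2y)/sum((2y)^2) = 1/2
  g2 <- golbraikh_tropsha(y, 2 * y)
  expect_equal(g2$k, 0.5, tolerance = 1e-12)
  expect_equal(g2$k_prime, 2, tolerance = 1e-12)
  # scale law: k(y, c*yhat) = k(y, yhat)/c
  yhat <- y + rnorm(8, sd = 0.3)
  ga <- golbraikh_tropsha(y, yhat)
  gb <- golbraikh_tropsha(y, 3 * yhat)
  expect_equal(gb$k, ga$k / 3, tolerance = 1e-12)
  # reorder invariance of every statistic
  p <- sample(8)
  gp <- golbraikh_tropsha(y[p], yhat[p])
  for (f in c("r2", "k", "k_prime", "r0_2", "r0_prime_2", "rm2"))
    expect_equal(gp[[f]], ga[[f]], tolerance = 1e-12)
  expect_error(golbraikh_tropsha(y[1:2], yhat[1:2]), ">= 3")
  expect_error(golbraikh_tropsha(rep(1, 5), yhat[1:5]), "degenerate")
})

test_that("the rm2 radicand is non-negative because free regression beats through-origin", {
  # R2 (free intercept) can never be smaller than R0^2 (slope-only) over the
  # same denominator, so rm2 is always defined; verified over random pairs
  # including anti-correlated and offset data
  set.seed(19)
  for (rep in 1:50) {
    y <- rnorm(7, sample(c(-10, 0, 10), 1), runif(1, 0.5, 3))
    yp <- sample(c(-1, 1), 1) * y + rnorm(7, sd = runif(1, 0.1, 3))
    g <- golbraikh_tropsha(y, yp)
    expect_gte(g$r2 - g$r0_2, -1e-12)
    expect_true(g$rm2_defined)
    expect_true(is.finite(g$rm2))
  }
})

test_that("the Tropsha battery applies its thresholds and overall rule", {
  set.seed(16)
  y <- rnorm(9, 5.7, 0.8)
  tc <- tropsha_criteria(golbraikh_tropsha(y, y))
  expect_true(tc$overall)
  expect_true(all(vapply(tc$conditions, `[[`, TRUE, "pass")))
  # weakly correlated pairs fail condition 1 (R2 > 0.6)
  pairs <- make_activity_pairs(30, target_r2 = 0.3, seed = 99)
  tc2 <- tropsha_criteria(golbraikh_tropsha(pairs$y_obs, pairs$y_pred))
  expect_false(tc2$conditions$c1$pass)
  expect_false(tc2$overall)
})

test_that("Y-randomization shuffles are seeded permutations of y", {
  set.seed(17)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- as.vector(X %*% c(2, -1, 1, 0.5)) + rnorm(12, sd = 0.2)
  fit_fn <- function(X, y) {
    cv <- loo_cross_validate(X, y, 2)
    list(q2 = cv$q2, r2 = fit_pls(X, y, 2)$r2)
  }
  yr <- y_randomization(fit_fn, X, y, n_iter = 5, seed = 7)
  expect_equal(nrow(yr$iterations), 5)
  for (p in yr$shuffled_y) expect_equal(sort(p), sort(y))
  # deterministic under the same seed
  yr2 <- y_randomization(fit_fn, X, y, n_iter = 5, seed = 7)
  expect_equal(yr$iterations$q2, yr2$iterations$q2)
  # strong signal: no shuffle beats the original internal validation
  orig <- fit_fn(X, y)
  expect_lt(max(yr$iterations$q2), orig$q2)
  expect_error(y_randomization(fit_fn, X, y, n_iter = 5), "seed")
  # per-iteration fit failures are recorded, not fatal
  bad_fn <- function(X, y) stop("boom")
  yrb <- y_randomization(bad_fn, X, y, n_iter = 2, seed = 1)
  expect_true(all(is.na(yrb$iterations$q2)))
  expect_match(yrb$iterations$error[1], "boom")
})

test_that("controlled-correlation pairs hit their target r2", {
  for (target in c(0.3, 0.6, 0.9)) {
    pairs <- make_activity_pairs(40, target, seed = 5)
    expect_lte(abs(cor(pairs$y_obs, pairs$y_pred)^2 - target), 0.05)
  }
  exact <- make_activity_pairs(10, 1, seed = 5)
  expect_identical(exact$y_obs, exact$y_pred)
  expect_error(make_activity_pairs(2, 0.5, seed = 1), "n must")
  expect_error(make_activity_pairs(10, 1.5, seed = 1), "target_r2")
})
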
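test_that("a noiseless linear response is fit exactly with one component", {
  set.seed(2)
  X <- cbind(a = rnorm(10), b = 0, c = 0)
  y <- 2 * X[, 1] + 1
  m <- fit_pls(X, y, 1)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$see, 0, tolerance = 1e-7)
  expect_equal(unname(predict(m, X)), y, tolerance = 1e-10)
})

test_that("a constant response yields the zero model by convention", {
  set.seed(3)
  X <- matrix(rnorm(24), 8, 3)
  m <- fit_pls(X, rep(5, 8), 2)
  expect_equal(m$r2, 0)
  expect_true(all(abs(m$coefficients) < 1e-12))
  expect_equal(unname(predict(m, X)), rep(5, 8))
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(4)
  X <- matrix(rnorm(40), 8, 5)
  y <- rnorm(8)
  m <- fit_pls(X, y, 5)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(m$fitted, as.vector(cbind(1, X) %*% ols$coefficients),
               tolerance = 1e-8)
  # requesting more components than the rank supports errors
  Xr <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fit_pls(Xr, y, 3), "rank")
})

test_that("fit statistics follow their definitions", {
  set.seed(5)
  X <- matrix(rnorm(60), 12, 5)
  y <- X %*% rnorm(5) + rnorm(12, sd = 0.4)
  c_ <- 3
  m <- fit_pls(X, as.vector(y), c_)
  rss <- sum((m$fitted - y)^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(m$r2, 1 - rss / tss)
  expect_equal(m$see, sqrt(rss / (12 - c_ - 1)))
  expect_equal(m$f_value, (m$r2 / c_) / ((1 - m$r2) / (12 - c_ - 1)))
})

test_that("predictions agree with an independent PLS implementation", {
  set.seed(6)
  X <- matrix(rnorm(15 * 9), 15, 9,
              dimnames = list(NULL, paste0("v", 1:9)))
  y <- rnorm(15)
  m <- fit_pls(X, y, 4)
  ref <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  expect_equal(m$fitted,
               as.vector(stats::predict(ref, X)$predict[, , 4]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("prediction is deterministic and order/duplication consistent", {
  set.seed(7)
  X <- matrix(rnorm(50), 10, 5)
  y <- rnorm(10)
  m <- fit_pls(X, y, 2)
  p <- predict(m, X)
  expect_equal(predict(m, X[c(3, 1, 2), ]), p[c(3, 1, 2)])
  expect_equal(predict(m, X[c(4, 4), ]), rep(p[4], 2))
  # hand-computed dot product on a 2-column model
  X2 <- cbind(c(0, 1, 2, 3), c(1, 0, 1, 0))
  y2 <- c(0.5, 1.5, 2.5, 3.5)
  m2 <- fit_pls(X2, y2, 2)
  xnew <- c(1.5, 0.5)
  expect_equal(unname(predict(m2, matrix(xnew, 1))),
               sum(xnew * m2$coefficients) + m2$intercept)
  expect_error(predict(m, X[, 1:3]), "mismatch")
})

test_that("a duplicated collinear column leaves full-rank predictions unchanged", {
  # at the full component count both fits equal the least-squares projection
  # onto the (identical) column space, so predictions must coincide; at
  # smaller counts PLS re-weights the duplicated direction by construction
  set.seed(8)
  X <- matrix(rnorm(48), 12, 4)
  y <- rnorm(12)
  m1 <- fit_pls(X, y, 4)
  m2 <- fit_pls(cbind(X, X[, 2]), y, 4)
  expect_equal(m1$fitted, m2$fitted, tolerance = 1e-6)
})

test_that("q2 and r2 are invariant to row and column permutations", {
  set.seed(9)
  X <- matrix(rnorm(14 * 6), 14, 6)
  y <- X %*% rnorm(6) + rnorm(14, sd = 0.3)
  y <- as.vector(y)
  m <- fit_pls(X, y, 3)
  cv <- loo_cross_validate(X, y, 3)
  prow <- sample(14); pcol <- sample(6)
  m2 <- fit_pls(X[prow, pcol], y[prow], 3)
  cv2 <- loo_cross_validate(X[prow, pcol], y[prow], 3)
  expect_equal(m2$r2, m$r2, tolerance = 1e-10)
  expect_equal(cv2$q2, cv$q2, tolerance = 1e-10)
})

test_that("LOO predictions equal an explicit refit-without-i oracle", {
  set.seed(10)
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- X %*% c(1, -1, 0.5, 0) + rnorm(6, sd = 0.2)
  y <- as.vector(y)
  for (ncomp in 1:2) {
    cv <- loo_cross_validate(X, y, ncomp)
    for (i in 1:6) {
      m_i <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)
      expect_equal(cv$predictions[i, ncomp],
                   unname(predict(m_i, X[i, , drop = FALSE])),
                   tolerance = 1e-10)
    }
  }
})

test_that("LOO q2 is near 1 for noiseless data, low for pure noise", {
  set.seed(11)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- as.vector(X %*% c(2, -1, 1, 0.5, -0.5))
  cv <- loo_cross_validate(X, y, 5)
  expect_gte(cv$q2, 0.999)
  # pure noise: q2 should hover at or below zero (20 repeats)
  q2s <- replicate(20, {
    Xn <- matrix(rnorm(12 * 6), 12, 6)
    loo_cross_validate(Xn, rnorm(12), 3)$q2
  })
  expect_lt(mean(q2s), 0.3)
  expect_lt(min(q2s), 0)
})

test_that("ONC maximises q2 with ties toward fewer components", {
  set.seed(12)
  X <- matrix(rnorm(18 * 6), 18, 6)
  y <- as.vector(X %*% c(1.5, -1, 0, 0, 0, 0)) + rnorm(18, sd = 0.2)
  cv <- loo_cross_validate(X, y, 5)
  expect_equal(unname(cv$onc), unname(which.max(cv$q2_by_ncomp)))
  expect_equal(cv$q2, max(cv$q2_by_ncomp))
  expect_warning(loo_cross_validate(X[1:5, ], y[1:5], 10), "truncated")
})

test_that("cross-validated q2 does not exceed the fitted r2", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    X <- matrix(rnorm(16 * 8), 16, 8)
    y <- as.vector(X %*% rnorm(8)) + rnorm(16, sd = 0.5)
    cv <- loo_cross_validate(X, y, 4)
    m <- fit_pls(X, y, cv$onc)
    expect_lte(cv$q2, m$r2 + 1e-10)
  }
})

test_that("StDev*Coeff contours rank points like a brute-force sort", {
  set.seed(13)
  mols <- setNames(lapply(1:6, function(j) random_molecule(7, paste0("m", j))),
                   paste0("m", 1:6))
  fs <- compute_fields(mols, kinds = "comsia.S")
  blk <- assemble_descriptor_matrix(fs, filtering_sigma = 0.01)
  y <- rnorm(6)
  m <- fit_pls(blk, y, 2)
  ct <- stdev_coeff_contours(m, blk, 0.8, 0.2)
  v <- ct$table$stdev_coeff
  # membership equals the cumulative-contribution ranking recomputed directly
  pos <- order(v, decreasing = TRUE)
  pos <- pos[v[pos] > 0]
  cum <- cumsum(v[pos]) / sum(v[pos])
  expect_setequal(ct$favored_points, pos[seq_len(which(cum >= 0.8)[1])])
  neg <- order(v)
  neg <- neg[v[neg] < 0]
  cumn <- cumsum(-v[neg]) / sum(-v[neg])
  expect_setequal(ct$disfavored_points, neg[seq_len(which(cumn >= 0.2)[1])])
  expect_length(intersect(ct$favored_points, ct$disfavored_points), 0)
  # one dominant positive point is always favoured
  expect_true(which.max(v) %in% ct$favored_points)
  # zero-coefficient model gives empty sets with a warning
  mz <- m
  mz$coefficients[] <- 0
  expect_warning(ctz <- stdev_coeff_contours(mz, blk), "zero")
  expect_length(ctz$favored_points, 0)
  expect_length(ctz$disfavored_points, 0)
})

test_that("field contributions are non-negative shares summing to one", {
  set.seed(14)
  mols <- setNames(lapply(1:8, function(j) random_molecule(8, paste0("m", j))),
                   paste0("m", 1:8))
  fs <- compute_fields(mols, kinds = c("comsia.S", "comsia.H"))
  blk <- assemble_descriptor_matrix(fs, filtering_sigma = 0.01)
  m <- fit_pls(blk, rnorm(8), 2)
  expect_true(all(m$field_contributions >= 0))
  expect_equal(sum(m$field_contributions), 1, tolerance = 1e-6)
  expect_named(m$field_contributions, c("comsia.S", "comsia.H"))
})
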
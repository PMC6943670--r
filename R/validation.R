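#' Cross-validated q2 statistic
#'
#' \code{q2 = 1 - sum((y - y_pred)^2) / sum((y - y_mean)^2)}, where the
#' reference mean is the training-set mean.
#'
#' @param y Observed activities.
#' @param y_pred_cv Cross-validated predictions, same length.
#' @param y_mean Reference mean; defaults to \code{mean(y)}.
#' @return The q2 value (at most 1; can be negative).
#' @export
q2_statistic <- function(y, y_pred_cv, y_mean = mean(y)) {
  if (length(y) != length(y_pred_cv) || length(y) < 2)
    stop("y and y_pred_cv must have equal length >= 2")
  denom <- sum((y - y_mean)^2)
  if (denom < 1e-12) stop("degenerate data: zero variance around y_mean")
  1 - sum((y - y_pred_cv)^2) / denom
}

#' External predictivity statistic rpred2 with PRESS and SD
#'
#' \code{PRESS = sum((y_test - y_pred)^2)}; \code{SD} is the sum of squared
#' deviations of the test-set observations from the training-set mean;
#' \code{rpred2 = 1 - PRESS/SD}.
#'
#' @param y_test Observed test-set activities.
#' @param y_pred_test Predicted test-set activities.
#' @param train_mean Mean activity of the training set.
#' @return List with \code{press}, \code{sd} and \code{rpred2}.
#' @export
rpred2_statistic <- function(y_test, y_pred_test, train_mean) {
  if (length(y_test) != length(y_pred_test))
    stop("y_test and y_pred_test must have equal length")
  press <- sum((y_test - y_pred_test)^2)
  sd_ <- sum((y_test - train_mean)^2)
  if (sd_ <= 0) stop("zero SD: test set has no variance around train_mean")
  list(press = press, sd = sd_, rpred2 = 1 - press / sd_)
}

#' Golbraikh-Tropsha external-validation statistics
#'
#' Computes, over observed/predicted test-set pairs: the squared Pearson
#' correlation R2; the through-origin regression slopes
#' \code{k = sum(yo*yp)/sum(yp^2)} (observed on predicted) and
#' \code{k' = sum(yo*yp)/sum(yo^2)} (predicted on observed); the
#' through-origin determination coefficients
#' \code{R0^2 = 1 - sum((yo - k*yp)^2)/sum((yo - mean(yo))^2)} and
#' \code{R'0^2 = 1 - sum((yp - k'*yo)^2)/sum((yp - mean(yp))^2)}; and
#' \code{rm2 = R2 * (1 - sqrt(R2 - R0^2))}.
#'
#' @param y_obs Observed activities (length >= 3).
#' @param y_pred Predicted activities.
#' @return List of class \code{gt_report} with the statistics, the two
#'   means, and \code{rm2_defined} (FALSE when \code{R2 < R0^2} makes the
#'   radicand negative, in which case \code{rm2} is NA with a diagnostic).
#' @export
golbraikh_tropsha <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 3)
    stop("need >= 3 observed/predicted pairs of equal length")
  if (stats::sd(y_obs) < 1e-12 || stats::sd(y_pred) < 1e-12)
    stop("degenerate variance in observed or predicted values")
  r2 <- stats::cor(y_obs, y_pred)^2
  k <- sum(y_obs * y_pred) / sum(y_pred^2)
  k_prime <- sum(y_obs * y_pred) / sum(y_obs^2)
  r0_2 <- 1 - sum((y_obs - k * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  r0_prime_2 <- 1 - sum((y_pred - k_prime * y_obs)^2) /
    sum((y_pred - mean(y_pred))^2)
  radicand <- r2 - r0_2
  rm2_defined <- radicand >= -1e-12
  rm2 <- if (rm2_defined) r2 * (1 - sqrt(max(radicand, 0))) else NA_real_
  structure(list(r2 = r2, k = k, k_prime = k_prime,
                 r0_2 = r0_2, r0_prime_2 = r0_prime_2,
                 rm2 = rm2, rm2_defined = rm2_defined,
                 y_obs_mean = mean(y_obs), y_pred_mean = mean(y_pred),
                 n = length(y_obs)),
            class = "gt_report")
}

#' @export
print.gt_report <- function(x, ...) {
  cat(sprintf(paste0("golbraikh-tropsha report (n = %d):\n",
                     "  R2 = %.3f  k = %.3f  k' = %.3f\n",
                     "  R0^2 = %.3f  R'0^2 = %.3f  rm2 = %s\n"),
              x$n, x$r2, x$k, x$k_prime, x$r0_2, x$r0_prime_2,
              if (x$rm2_defined) sprintf("%.3f", x$rm2)
              else "undefined (R2 < R0^2)"))
  invisible(x)
}

#' Evaluate the Tropsha acceptance conditions
#'
#' Threshold battery on a [golbraikh_tropsha()] report: (1) R2 > 0.6;
#' (2a/2b) through-origin R0^2 / R'0^2 close to R2, operationalised by
#' (4a) (R2 - R0^2)/R2 < 0.1 and (4b) (R2 - R'0^2)/R2 < 0.1;
#' (3a) 0.85 < k < 1.15 and (3b) 0.85 < k' < 1.15;
#' (5) |R0^2 - R'0^2| < 0.3; (6) rm2 > 0.5.  The model passes overall when
#' condition 1, (2a or 2b), (3a or 3b), (4a or 4b), 5, and 6 all hold.
#'
#' @param report A \code{gt_report}.
#' @return List of class \code{tropsha_check}: per-condition measured
#'   values and pass flags, plus the overall verdict.
#' @export
tropsha_criteria <- function(report) {
  stopifnot(inherits(report, "gt_report"))
  v <- list(
    c1 = list(value = report$r2, pass = report$r2 > 0.6),
    c4a = list(value = (report$r2 - report$r0_2) / report$r2,
               pass = (report$r2 - report$r0_2) / report$r2 < 0.1),
    c4b = list(value = (report$r2 - report$r0_prime_2) / report$r2,
               pass = (report$r2 - report$r0_prime_2) / report$r2 < 0.1),
    c3a = list(value = report$k, pass = report$k > 0.85 && report$k < 1.15),
    c3b = list(value = report$k_prime,
               pass = report$k_prime > 0.85 && report$k_prime < 1.15),
    c5 = list(value = abs(report$r0_2 - report$r0_prime_2),
              pass = abs(report$r0_2 - report$r0_prime_2) < 0.3),
    c6 = list(value = report$rm2,
              pass = report$rm2_defined && report$rm2 > 0.5))
  # conditions 2a/2b ("R0^2 close to R2") are the relative-gap checks 4a/4b
  v$c2a <- v$c4a
  v$c2b <- v$c4b
  overall <- v$c1$pass && (v$c2a$pass || v$c2b$pass) &&
    (v$c3a$pass || v$c3b$pass) && (v$c4a$pass || v$c4b$pass) &&
    v$c5$pass && v$c6$pass
  structure(list(conditions = v, overall = overall),
            class = "tropsha_check")
}

#' @export
print.tropsha_check <- function(x, ...) {
  for (nm in c("c1", "c2a", "c2b", "c3a", "c3b", "c4a", "c4b", "c5", "c6")) {
    cn <- x$conditions[[nm]]
    cat(sprintf("  %-3s value = %8.4f  %s\n", nm, cn$value,
                if (isTRUE(cn$pass)) "pass" else "FAIL"))
  }
  cat("overall:", if (x$overall) "pass" else "FAIL", "\n")
  invisible(x)
}

#' Y-randomization (response permutation) test
#'
#' Refits the model after randomly permuting the response, recording the
#' shuffled q2/r2 per iteration.  Low shuffled statistics relative to the
#' original model indicate the model is not a chance correlation.
#'
#' @param fit_fn Function \code{(X, y) -> list(q2 = , r2 = )} performing the
#'   model fit and cross-validation.
#' @param X Descriptor matrix (unchanged across iterations).
#' @param y Response vector, permuted each iteration.
#' @param n_iter Number of shuffles (default 10).
#' @param seed Mandatory RNG seed.
#' @param original Optional list(q2 = , r2 = ) of the unshuffled model for
#'   comparison.
#' @return Object of class \code{yrand_result}: a per-iteration data frame
#'   (q2, r2, error flag) plus the original statistics.
#' @export
y_randomization <- function(fit_fn, X, y, n_iter = 10, seed,
                            original = NULL) {
  if (missing(seed)) stop("a seed is required for Y-randomization")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (stats::sd(y) < 1e-12)
    warning("constant response: all shuffles are identical, q2 degenerate")
  set.seed(seed)
  rows <- vector("list", n_iter)
  perms <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    y_shuf <- sample(y)
    perms[[it]] <- y_shuf
    res <- tryCatch(fit_fn(X, y_shuf), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[it]] <- data.frame(iteration = it, q2 = NA_real_,
                               r2 = NA_real_, error = conditionMessage(res))
    } else {
      rows[[it]] <- data.frame(iteration = it, q2 = res$q2, r2 = res$r2,
                               error = NA_character_)
    }
  }
  structure(list(iterations = do.call(rbind, rows),
                 shuffled_y = perms, seed = seed,
                 original_q2 = original$q2, original_r2 = original$r2),
            class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf("y_randomization: %d iterations (seed %d)\n",
              nrow(x$iterations), x$seed))
  cat(sprintf("  shuffled q2 in [%.3f, %.3f], r2 in [%.3f, %.3f]\n",
              min(x$iterations$q2, na.rm = TRUE),
              max(x$iterations$q2, na.rm = TRUE),
              min(x$iterations$r2, na.rm = TRUE),
              max(x$iterations$r2, na.rm = TRUE)))
  if (!is.null(x$original_q2))
    cat(sprintf("  original q2 = %.3f, r2 = %.3f\n",
                x$original_q2, x$original_r2))
  invisible(x)
}
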
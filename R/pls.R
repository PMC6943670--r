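# Core PLS1 (single response) NIPALS on already-centred data.  Returns the
# weight/loading matrices for 1..ncomp components; models are nested, so the
# coefficient vector for any smaller component count falls out of the same
# decomposition.
pls1_nipals <- function(Xc, yc, ncomp) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp); TT <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("requested components exceed the effective rank of X (component ",
           a, ")")
    w <- w / nw
    t <- as.vector(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24)
      stop("degenerate score vector at component ", a)
    p_a <- crossprod(Xc, t) / tt
    q_a <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, p_a)
    yc <- yc - t * q_a
    W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a; TT[, a] <- t
  }
  list(W = W, P = P, Q = Q, scores = TT)
}

# regression coefficients (on centred data) for component counts 1..ncomp
pls1_coefficients <- function(fit, ncomp) {
  W <- fit$W[, seq_len(ncomp), drop = FALSE]
  P <- fit$P[, seq_len(ncomp), drop = FALSE]
  Q <- fit$Q[seq_len(ncomp)]
  as.vector(W %*% solve(crossprod(P, W), Q))
}

#' Fit a PLS regression model on field descriptors
#'
#' Deterministic NIPALS PLS1 fit.  X and y are mean-centred on the training
#' data; individual columns are not autoscaled (block scaling, if any, is
#' applied when the descriptor matrix is assembled).  Reported statistics:
#' \code{r2 = 1 - RSS/TSS}, \code{SEE = sqrt(RSS/(n - c - 1))},
#' \code{F = (r2/c) / ((1 - r2)/(n - c - 1))}, and per-field-kind
#' contributions as the normalised share of \code{sum(|coef_j| * sd_j)}.
#'
#' @param X Descriptor matrix (compounds x columns), or a
#'   \code{field_block} (its retained columns are used).
#' @param y Activity vector (pIC50), one value per row of X.
#' @param ncomp Number of latent components.
#' @param column_kinds Optional character vector assigning each column of X
#'   to a field kind (for the contribution breakdown); taken from the block
#'   when X is a \code{field_block}.
#' @return Object of class \code{pls_model}.
#' @export
fit_pls <- function(X, y, ncomp, column_kinds = NULL) {
  block <- NULL
  if (inherits(X, "field_block")) {
    block <- X
    column_kinds <- block$columns$kind[block$mask]
    X <- descriptor_matrix(block)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (n < ncomp + 2)
    stop("need at least ncomp + 2 compounds (n = ", n, ", ncomp = ",
         ncomp, ")")
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_means)
  yc <- y - y_mean
  tss <- sum(yc^2)
  if (tss < 1e-12) {
    # constant response: zero model by convention
    beta <- rep(0, ncol(X))
    fitted <- rep(y_mean, n)
    r2 <- 0; see <- 0; fval <- NA_real_
  } else {
    fit <- pls1_nipals(Xc, yc, ncomp)
    beta <- pls1_coefficients(fit, ncomp)
    fitted <- as.vector(Xc %*% beta) + y_mean
    rss <- sum((y - fitted)^2)
    r2 <- 1 - rss / tss
    see <- sqrt(rss / (n - ncomp - 1))
    fval <- (r2 / ncomp) / ((1 - r2) / (n - ncomp - 1))
  }
  contributions <- NULL
  if (!is.null(column_kinds)) {
    sds <- apply(X, 2, stats::sd)
    share <- tapply(abs(beta) * sds, column_kinds, sum)
    tot <- sum(share)
    contributions <- if (tot > 0) share / tot else share
    contributions <- contributions[unique(column_kinds)]
  }
  structure(list(n_components = ncomp,
                 coefficients = setNames(beta, colnames(X)),
                 intercept = y_mean - sum(x_means * beta),
                 x_means = x_means, y_mean = y_mean,
                 fitted = fitted, y = y,
                 r2 = r2, see = see, f_value = fval,
                 field_contributions = contributions,
                 column_names = colnames(X),
                 training_ids = rownames(X),
                 block = block),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d components, n = %d, r2 = %.3f, SEE = %.3f, F = %.1f\n",
              x$n_components, length(x$y), x$r2, x$see, x$f_value))
  if (!is.null(x$field_contributions)) {
    cat("field contributions:\n")
    print(round(x$field_contributions, 3))
  }
  invisible(x)
}

#' Predict activities for new compounds
#'
#' @param object A \code{pls_model}.
#' @param newdata Matrix with the same retained columns the model was fitted
#'   on (or a \code{field_block} sharing the model's block geometry).
#' @param ... Unused.
#' @return Vector of predicted activities, invariant to row order.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "field_block")) newdata <- descriptor_matrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("column count mismatch: model has ", length(object$coefficients),
         " retained columns, newdata has ", ncol(newdata))
  if (!is.null(colnames(newdata)) && !is.null(object$column_names) &&
      !identical(colnames(newdata), object$column_names))
    stop("column names of newdata do not match the model's columns")
  as.vector(newdata %*% object$coefficients) + object$intercept
}

#' Leave-one-out cross-validation with component selection
#'
#' Every compound is predicted by a model refitted without it, for each
#' candidate component count; \code{q2 = 1 - PRESS / sum((y - mean(y))^2)}
#' with the full training mean as reference.  The optimum number of
#' components (ONC) maximises q2, with ties broken toward fewer components.
#'
#' @param X Descriptor matrix or \code{field_block}.
#' @param y Activity vector.
#' @param max_components Largest component count to consider; silently
#'   truncated (with a warning) to \code{n - 2}.
#' @return Object of class \code{crossval_result} with \code{q2},
#'   \code{onc}, \code{q2_by_ncomp}, and the LOO predictions at the ONC.
#' @export
loo_cross_validate <- function(X, y, max_components = 10) {
  if (inherits(X, "field_block")) X <- descriptor_matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 compounds for LOO cross-validation")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (max_components >= n - 1) {
    warning("max_components truncated to n - 2 = ", n - 2)
    max_components <- n - 2
  }
  max_components <- max(1L, as.integer(max_components))
  preds <- matrix(NA_real_, n, max_components)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    Xc <- sweep(Xi, 2, xm); yc <- yi - ym
    a_max <- max_components
    fit <- tryCatch(pls1_nipals(Xc, yc, a_max), error = function(e) NULL)
    while (is.null(fit) && a_max > 1) {
      a_max <- a_max - 1
      fit <- tryCatch(pls1_nipals(Xc, yc, a_max), error = function(e) NULL)
    }
    if (is.null(fit)) stop("PLS fit failed in LOO fold ", i)
    xc_new <- X[i, ] - xm
    for (a in seq_len(a_max)) {
      beta <- pls1_coefficients(fit, a)
      preds[i, a] <- sum(xc_new * beta) + ym
    }
    if (a_max < max_components)
      preds[i, (a_max + 1):max_components] <- preds[i, a_max]
  }
  y_mean <- mean(y)
  tss <- sum((y - y_mean)^2)
  if (tss < 1e-12) stop("degenerate (constant) response")
  q2s <- 1 - colSums((y - preds)^2) / tss
  onc <- which.max(q2s)         # first maximum = fewest components on ties
  structure(list(q2 = q2s[onc], onc = onc, q2_by_ncomp = q2s,
                 predictions = preds,
                 per_fold = data.frame(y = y, y_pred = preds[, onc]),
                 y_mean = y_mean, max_components = max_components),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("crossval_result: q2 = %.3f at ONC = %d (max %d components)\n",
              x$q2, x$onc, x$max_components))
  invisible(x)
}

#' Extract StDev*Coeff contour regions from a fitted model
#'
#' For every retained grid column the product of the training-set standard
#' deviation and the PLS coefficient is computed.  The favoured set collects
#' the largest positive values until their cumulative share of the total
#' positive contribution reaches \code{favored_fraction} (80% by
#' convention); the disfavoured set analogously collects the largest-
#' magnitude negative values up to \code{disfavored_fraction} (20%).
#'
#' @param model A \code{pls_model} fitted on \code{block}.
#' @param block The \code{field_block} the model was fitted on (defaults to
#'   the block stored in the model).
#' @param favored_fraction,disfavored_fraction Cumulative contribution
#'   levels in (0, 1].
#' @return Object of class \code{contour_set}: a per-column table
#'   (kind, x, y, z, stdev_coeff, set membership) plus the two thresholds.
#' @export
stdev_coeff_contours <- function(model, block = model$block,
                                 favored_fraction = 0.8,
                                 disfavored_fraction = 0.2) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(block)) stop("model carries no field_block; pass block=")
  X <- descriptor_matrix(block)
  tr <- match(block$train_ids, block$compound_ids)
  sds <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  v <- sds * model$coefficients
  meta <- block$columns[block$mask, , drop = FALSE]
  tab <- data.frame(meta, stdev_coeff = v, set = "none",
                    row.names = NULL, stringsAsFactors = FALSE)
  pick <- function(vals, fraction) {
    idx <- which(vals > 0)
    if (!length(idx)) return(integer())
    ord <- idx[order(vals[idx], decreasing = TRUE)]
    cs <- cumsum(vals[ord])
    take <- which(cs >= fraction * cs[length(cs)] - 1e-12)[1]
    ord[seq_len(take)]
  }
  fav <- pick(v, favored_fraction)
  dis <- pick(-v, disfavored_fraction)
  if (all(v == 0)) warning("all StDev*Coeff values are zero; empty contours")
  tab$set[fav] <- "favored"
  tab$set[dis] <- "disfavored"
  structure(list(table = tab,
                 favored_points = fav, disfavored_points = dis,
                 favored_threshold = if (length(fav)) min(v[fav]) else NA_real_,
                 disfavored_threshold = if (length(dis)) max(v[dis]) else NA_real_,
                 favored_fraction = favored_fraction,
                 disfavored_fraction = disfavored_fraction),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set: %d favored, %d disfavored points (levels %g/%g)\n",
              length(x$favored_points), length(x$disfavored_points),
              x$favored_fraction, x$disfavored_fraction))
  invisible(x)
}

#' Serialize a PLS model to JSON
#'
#' @param model A \code{pls_model}.
#' @param path Output path.
#' @export
write_pls_model <- function(model, path) {
  obj <- model[c("n_components", "coefficients", "intercept", "x_means",
                 "y_mean", "r2", "see", "f_value", "field_contributions",
                 "column_names", "training_ids")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
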
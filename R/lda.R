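#' Fit a two-class linear discriminant model
#'
#' Gaussian class-conditional model with shared (pooled within-class)
#' covariance and empirical priors. Features are z-scored internally using
#' training statistics; a ridge term lambda = 1e-6 * trace(S)/p is added to
#' the pooled covariance so the model remains defined when p exceeds n.
#' The positive class is `"high"`.
#'
#' @param X Numeric n x p feature matrix.
#' @param y Labels coercible to character with values `"low"`/`"high"`.
#' @param ridge Ridge multiplier on trace(S)/p (default 1e-6).
#' @return List of class `lda_model`.
#' @export
fit_lda <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) < 4L) stop("need at least 4 training samples")
  classes <- c("low", "high")
  if (!all(y %in% classes)) stop("labels must be 'low' or 'high'")
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  p <- ncol(Z)
  i0 <- y == "low"; i1 <- y == "high"
  mu0 <- colMeans(Z[i0, , drop = FALSE])
  mu1 <- colMeans(Z[i1, , drop = FALSE])
  S0 <- crossprod(sweep(Z[i0, , drop = FALSE], 2, mu0))
  S1 <- crossprod(sweep(Z[i1, , drop = FALSE], 2, mu1))
  S <- (S0 + S1) / (nrow(Z) - 2)
  lambda <- ridge * sum(diag(S)) / p
  if (lambda <= 0) lambda <- ridge
  S <- S + diag(lambda, p)
  wvec <- solve(S, mu1 - mu0)
  prior1 <- mean(i1)
  b <- -0.5 * sum((mu1 + mu0) * wvec) + log(prior1 / (1 - prior1))
  structure(list(w = wvec, b = b, center = ctr, scale = scl,
                 mu0 = mu0, mu1 = mu1, cov = S, lambda = lambda,
                 priors = c(low = 1 - prior1, high = prior1),
                 features = colnames(X)),
            class = "lda_model")
}

#' Posterior probability of the high-risk class
#' @param model A [fit_lda()] model.
#' @param X New n x p matrix (same columns as training).
#' @return Numeric vector of P(high | x).
#' @export
predict_lda <- function(model, X) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  eta <- drop(Z %*% model$w) + model$b
  1 / (1 + exp(-eta))
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC, computed via its Mann--Whitney identity (midranks, ties
#' counted one half).
#'
#' @param scores Numeric scores (larger = more "high").
#' @param y Labels `"low"`/`"high"` (positive class `"high"`).
#' @return Az in \[0, 1\].
#' @export
roc_az <- function(scores, y) {
  y <- as.character(y)
  pos <- y == "high"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Positive and negative predictive values at a posterior threshold
#'
#' Predictions call `"high"` when the score exceeds `threshold`. An
#' undefined ratio (no positive or no negative predictions) is returned as
#' `NA` rather than a silent 0.
#'
#' @param scores Posterior probabilities of the high class.
#' @param y Labels `"low"`/`"high"`.
#' @param threshold Decision threshold (default 0.5).
#' @return Named vector `c(ppv = , npv = )`, possibly `NA`.
#' @export
ppv_npv <- function(scores, y, threshold = 0.5) {
  y <- as.character(y)
  pred <- scores > threshold
  pos <- y == "high"
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  c(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Relative standard deviation (percent)
#'
#' The classifier-stability measure: 100 * sd(x) / mean(x) over the per-repeat
#' Az values. Higher values indicate lower stability.
#'
#' @param az_values Numeric vector with positive mean.
#' @return RSD in percent.
#' @export
rsd <- function(az_values) {
  if (!length(az_values)) stop("empty input")
  m <- mean(az_values)
  if (m <= 0) stop("RSD undefined for non-positive mean")
  100 * stats::sd(az_values) / m
}

#' Spearman rank correlation of a feature with the class label
#'
#' Midrank-based rank correlation against the binary label (low = 0,
#' high = 1), with the p-value from the t approximation. A constant feature
#' yields a flagged `NA` correlation.
#'
#' @param x Feature values (n >= 5).
#' @param y Labels `"low"`/`"high"` (or 0/1).
#' @return Named vector `c(rho = , p = )`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) < 5L) stop("need at least 5 observations")
  ynum <- if (is.numeric(y)) y else as.numeric(as.character(y) == "high")
  if (stats::sd(x) < 1e-15 || stats::sd(ynum) < 1e-15)
    return(c(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(x, ynum, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Select high-accuracy, high-stability features
#'
#' Applies the top-half ranking rule to a list of per-feature evaluation
#' results: keep the features whose mean Az is strictly above the grand-mean
#' Az and whose RSD is strictly below the grand-mean RSD.
#'
#' @param results List of [repeated_cv()] results (each with `name`,
#'   `az_mean`, `rsd`); at least 2.
#' @return Character vector of selected feature-set names (possibly empty).
#' @export
rank_stable_features <- function(results) {
  if (length(results) < 2L) stop("need at least 2 evaluation results")
  az <- vapply(results, function(r) r$az_mean, numeric(1))
  rs <- vapply(results, function(r) r$rsd, numeric(1))
  nm <- vapply(results, function(r) r$name, character(1))
  nm[az > mean(az) & rs < mean(rs)]
}

#' Column subset for joint classification
#'
#' Selected features are passed jointly and unweighted to the classifier
#' (standardisation happens inside [fit_lda()] from training statistics).
#'
#' @param X Feature matrix.
#' @param subset Column indices or names (non-empty).
#' @return The reduced matrix.
#' @export
combine_features <- function(X, subset) {
  if (!length(subset)) stop("empty feature subset")
  as.matrix(X)[, subset, drop = FALSE]
}
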
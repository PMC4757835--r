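#' Repeated stratified two-fold cross-validation of an LDA classifier
#'
#' Each repeat draws a seeded stratified random split into two halves,
#' trains on each half and scores the other; the pooled out-of-fold
#' posteriors give that repeat's Az, PPV, NPV and error rate. Reported are
#' the means with 95% percentile confidence intervals (2.5/97.5 percentiles
#' over repeats), the RSD of the Az values, and the per-repeat Az vector.
#'
#' @param X Numeric n x p feature matrix (n >= 8).
#' @param y Labels `"low"`/`"high"`.
#' @param repeats Number of repeats (default 100).
#' @param seed Integer seed driving all splits.
#' @param name Optional identifier stored in the result.
#' @return List of class `eval_result`.
#' @export
repeated_cv <- function(X, y, repeats = 100L, seed = 1L, name = "featureset") {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  if (n < 8L) stop("need at least 8 samples for repeated 2-fold CV")
  i0 <- which(y == "low"); i1 <- which(y == "high")
  if (length(i0) < 2L || length(i1) < 2L)
    stop("need at least 2 samples per class")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  az <- ppv <- npv <- err <- numeric(repeats)
  for (r in seq_len(repeats)) {
    for (attempt in 1:20) {
      f0 <- sample(rep_len(1:2, length(i0)))
      f1 <- sample(rep_len(1:2, length(i1)))
      fold <- integer(n)
      fold[i0] <- f0; fold[i1] <- f1
      ok <- all(vapply(1:2, function(k)
        length(unique(y[fold == k])) == 2L, logical(1)))
      if (ok) break
      if (attempt == 20) stop("could not draw a stratified split with both classes per fold")
    }
    scores <- numeric(n)
    for (k in 1:2) {
      tr <- fold != k
      m <- fit_lda(X[tr, , drop = FALSE], y[tr])
      scores[!tr] <- predict_lda(m, X[!tr, , drop = FALSE])
    }
    az[r] <- roc_az(scores, y)
    pn <- ppv_npv(scores, y)
    ppv[r] <- pn["ppv"]; npv[r] <- pn["npv"]
    err[r] <- mean((scores > 0.5) != (y == "high"))
  }
  ci <- function(v) unname(stats::quantile(v, c(0.025, 0.975), na.rm = TRUE))
  structure(list(name = name,
                 az_mean = mean(az), az_ci = ci(az),
                 ppv_mean = mean(ppv, na.rm = TRUE), ppv_ci = ci(ppv),
                 npv_mean = mean(npv, na.rm = TRUE), npv_ci = ci(npv),
                 err = mean(err), rsd = rsd(az),
                 az_values = az, repeats = repeats, seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: Az %.3f (%.3f, %.3f), PPV %.3f, NPV %.3f, RSD %.2f%%, err %.3f [%d repeats]\n",
              x$name, x$az_mean, x$az_ci[1], x$az_ci[2],
              x$ppv_mean, x$npv_mean, x$rsd, x$err, x$repeats))
  invisible(x)
}

#' Classification error versus training-set size
#'
#' Splits off a fixed stratified held-out test set (25%), then for each
#' requested training size draws `reps` seeded stratified subsamples of the
#' remaining pool, trains LDA and records the test error; errors are
#' averaged per size.
#'
#' @param X Feature matrix.
#' @param y Labels `"low"`/`"high"`.
#' @param sizes Training sizes (each <= pool size).
#' @param reps Subsamples per size (default 50).
#' @param seed Integer seed.
#' @return List with `sizes` and `err` (mean test error per size).
#' @export
learning_curve <- function(X, y, sizes, reps = 50L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  i0 <- which(y == "low"); i1 <- which(y == "high")
  t0 <- sample(i0, max(1L, round(length(i0) / 4)))
  t1 <- sample(i1, max(1L, round(length(i1) / 4)))
  test <- c(t0, t1)
  pool0 <- setdiff(i0, t0); pool1 <- setdiff(i1, t1)
  npool <- length(pool0) + length(pool1)
  if (max(sizes) > npool)
    stop("requested training size exceeds the training pool")
  frac1 <- length(pool1) / npool
  err <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    nsz <- sizes[si]
    n1 <- min(max(2L, round(nsz * frac1)), length(pool1), nsz - 2L)
    n0 <- nsz - n1
    if (n0 > length(pool0)) { n0 <- length(pool0); n1 <- nsz - n0 }
    e <- numeric(reps)
    for (r in seq_len(reps)) {
      tr <- c(sample(pool0, n0), sample(pool1, n1))
      m <- fit_lda(X[tr, , drop = FALSE], y[tr])
      s <- predict_lda(m, X[test, , drop = FALSE])
      e[r] <- mean((s > 0.5) != (y[test] == "high"))
    }
    err[si] <- mean(e)
  }
  list(sizes = sizes, err = err, test_index = test)
}

#' Fit the inverse power-law learning curve
#'
#' Constrained least squares of \eqn{err(n) = a n^{-\alpha} + \epsilon}
#' (a = learning rate, alpha = decay rate, epsilon = Bayes error) with
#' bounds a > 0, alpha in (0, 2], epsilon in \[0, 0.5\], from 8 multi-starts
#' on a log grid of (a, alpha).
#'
#' @param sizes Training sizes (>= 4 distinct values).
#' @param err Error rates in [0, 1], one per size.
#' @return List of class `power_law_fit` with `a`, `alpha`, `epsilon`,
#'   `residual`, `converged` and `fitted`.
#' @export
fit_power_law <- function(sizes, err) {
  sizes <- as.numeric(sizes)
  if (length(unique(sizes)) < 4L) stop("need at least 4 distinct sizes")
  if (any(err < 0 | err > 1)) stop("error rates must lie in [0, 1]")
  lower <- c(1e-8, 1e-6, 0)
  upper <- c(100, 2, 0.5)
  obj <- function(p) sum((p[1] * sizes^(-p[2]) + p[3] - err)^2)
  grad <- function(p) {
    np <- sizes^(-p[2])
    r <- p[1] * np + p[3] - err
    c(2 * sum(r * np),
      -2 * p[1] * sum(r * np * log(sizes)),
      2 * sum(r))
  }
  starts <- expand.grid(a = c(0.1, 1, 5, 20), alpha = c(0.2, 1))
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$a[i], starts$alpha[i],
            max(0, min(0.5, min(err))))
    fit <- tryCatch(
      stats::optim(p0, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 1000, factr = 10, pgtol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("power-law fit failed from all starts")
  p <- best$par
  structure(list(a = p[1], alpha = p[2], epsilon = p[3],
                 residual = best$value, converged = any_conv,
                 fitted = p[1] * sizes^(-p[2]) + p[3], sizes = sizes),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> err(n) = %.4g * n^-%.4g + %.4g (RSS %.3g)\n",
              x$a, x$alpha, x$epsilon, x$residual))
  invisible(x)
}
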
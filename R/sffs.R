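#' Sequential floating forward feature selection (SFFS)
#'
#' Pudil-style wrapper selection with the repeated-CV Az of the LDA
#' classifier as the criterion J(S). Each iteration adds the single best
#' feature, then conditionally removes features while removal improves on
#' the best criterion recorded for the smaller subset size. The criterion
#' uses fewer CV repeats than final reporting to bound runtime; all
#' evaluations share one seed so subsets are compared on identical splits.
#' Ties are broken towards the lower feature index.
#'
#' @param X Feature matrix (p >= 2 columns).
#' @param y Labels `"low"`/`"high"`.
#' @param max_k Largest subset size considered (default 10).
#' @param seed Integer seed for the criterion CV splits.
#' @param repeats CV repeats inside the criterion (default 25).
#' @return List of class `sffs_result`: `subset` (column indices of the best
#'   subset found, in selection order), `criterion` (its J), `best_by_size`
#'   (list of best subsets per size), `J_by_size`.
#' @export
sffs_select <- function(X, y, max_k = 10L, seed = 1L, repeats = 25L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) stop("SFFS needs at least 2 candidate features")
  max_k <- min(max_k, p)
  cache <- new.env(parent = emptyenv())
  J <- function(S) {
    key <- paste(sort(S), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- repeated_cv(X[, S, drop = FALSE], y, repeats = repeats,
                       seed = seed)$az_mean
    cache[[key]] <- val
    val
  }
  best_by_size <- vector("list", max_k)
  J_by_size <- rep(-Inf, max_k)
  S <- integer(0)
  iter <- 0L
  while (length(S) < max_k && iter < 40L * max_k) {
    iter <- iter + 1L
    # forward: best single addition (ties -> lower index)
    cand <- setdiff(seq_len(p), S)
    jc <- vapply(cand, function(f) J(c(S, f)), numeric(1))
    f_add <- cand[which.max(jc)]
    S <- c(S, f_add)
    k <- length(S)
    if (jc[match(f_add, cand)] > J_by_size[k]) {
      J_by_size[k] <- jc[match(f_add, cand)]
      best_by_size[[k]] <- S
    }
    # conditional backward: drop while it beats the best smaller subset
    while (length(S) > 2L) {
      jr <- vapply(seq_along(S), function(i) J(S[-i]), numeric(1))
      i_rm <- which.max(jr)
      k1 <- length(S) - 1L
      if (jr[i_rm] > J_by_size[k1]) {
        S <- S[-i_rm]
        J_by_size[k1] <- jr[i_rm]
        best_by_size[[k1]] <- S
      } else break
    }
  }
  kbest <- which.max(J_by_size)
  structure(list(subset = best_by_size[[kbest]],
                 criterion = J_by_size[kbest],
                 best_by_size = best_by_size,
                 J_by_size = J_by_size,
                 seed = seed, repeats = repeats),
            class = "sffs_result")
}

#' @export
print.sffs_result <- function(x, ...) {
  cat(sprintf("<sffs_result> best subset (J = %.3f): %s\n",
              x$criterion, paste(x$subset, collapse = ", ")))
  invisible(x)
}
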
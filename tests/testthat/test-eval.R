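test_that("LDA matches the closed-form discriminant on a fixed 2-D example", {
  set.seed(5)
  n <- 200
  X <- rbind(matrix(rnorm(n, -1, 1), n / 2, 2),
             matrix(rnorm(n, 1, 1), n / 2, 2))
  y <- rep(c("low", "high"), each = n / 2)
  m <- fit_lda(X, y, ridge = 0)
  # oracle on the internally z-scored data
  Z <- scale(X)
  mu0 <- colMeans(Z[y == "low", ]); mu1 <- colMeans(Z[y == "high", ])
  Sp <- (crossprod(sweep(Z[y == "low", ], 2, mu0)) +
           crossprod(sweep(Z[y == "high", ], 2, mu1))) / (n - 2)
  w_oracle <- solve(Sp, mu1 - mu0)
  expect_equal(unname(m$w), unname(w_oracle), tolerance = 1e-10)
  # posterior at the class-mean midpoint is 0.5 under equal priors
  mid <- (colMeans(X[y == "low", ]) + colMeans(X[y == "high", ])) / 2
  expect_equal(predict_lda(m, matrix(mid, 1)), 0.5, tolerance = 1e-10)
  expect_error(fit_lda(X, rep("low", n)), "single class")
})

test_that("LDA decision boundary sits near zero for symmetric 1-D classes", {
  set.seed(7)
  x <- matrix(c(rnorm(400, -1), rnorm(400, 1)), ncol = 1)
  y <- rep(c("low", "high"), each = 400)
  m <- fit_lda(x, y)
  boundary <- -m$b / m$w * m$scale + m$center  # back to original units
  expect_lt(abs(boundary), 0.1)
})

test_that("LDA posteriors rank identically to MASS::lda on a well-posed problem", {
  skip_if_not_installed("MASS")
  set.seed(11)
  g <- gaussian_cohort(30, 4, delta = 1.5, informative = 1:2, seed = 11)
  m <- fit_lda(g$X, g$y)
  s1 <- predict_lda(m, g$X)
  ref <- MASS::lda(g$X, grouping = g$y)
  s2 <- predict(ref, g$X)$posterior[, "high"]
  expect_equal(roc_az(s1, g$y), roc_az(s2, g$y), tolerance = 1e-9)
  expect_gt(stats::cor(s1, s2, method = "spearman"), 0.999)
})

test_that("roc_az equals the O(n^2) pairwise oracle, ties counted one half", {
  az_oracle <- function(s, y) {
    pos <- s[y == "high"]; neg <- s[y == "low"]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(17)
  for (rep in 1:5) {
    s <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # forced ties
    y <- sample(c("low", "high"), 50, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    expect_equal(roc_az(s, y), az_oracle(s, y), tolerance = 1e-12)
  }
  expect_equal(roc_az(c(1, 2, 3, 4), c("low", "low", "high", "high")), 1)
  expect_equal(roc_az(rep(1, 10), rep(c("low", "high"), 5)), 0.5)
  skip_if_not_installed("pROC")
  set.seed(18)
  s <- rnorm(40); y <- rep(c("low", "high"), 20)
  expect_equal(roc_az(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, levels = c("low", "high"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("PPV/NPV follow the confusion-matrix arithmetic with flagged NAs", {
  # TP=7, FP=3, TN=8, FN=2 at threshold 0.5
  scores <- c(rep(0.9, 7), rep(0.8, 3), rep(0.1, 8), rep(0.2, 2))
  y <- c(rep("high", 7), rep("low", 3), rep("low", 8), rep("high", 2))
  expect_equal(unname(ppv_npv(scores, y)), c(0.7, 0.8))
  perfect <- ppv_npv(c(0.9, 0.9, 0.1, 0.1),
                     c("high", "high", "low", "low"))
  expect_equal(unname(perfect), c(1, 1))
  allpos <- ppv_npv(rep(0.9, 4), c("high", "low", "high", "low"))
  expect_true(is.na(allpos[["npv"]]))
})

test_that("RSD is the percent coefficient of variation and scale invariant", {
  expect_equal(rsd(c(0.8, 0.8, 0.8)), 0)
  expect_equal(rsd(c(0.7, 0.8, 0.9)), 12.5)
  v <- c(0.55, 0.72, 0.64, 0.81)
  expect_equal(rsd(3 * v), rsd(v), tolerance = 1e-12)
  expect_error(rsd(numeric(0)), "empty")
})

test_that("Spearman correlation matches an explicit rank-formula oracle", {
  x <- c(2.3, 1.1, 5.4, 3.3, 4.8, 0.2, 6.1, 2.9)
  y <- c("low", "low", "high", "low", "high", "low", "high", "high")
  got <- spearman_rho(x, y)
  oracle <- stats::cor(rank(x), rank(as.numeric(y == "high")))
  expect_equal(got[["rho"]], oracle, tolerance = 1e-12)
  # feature identical to the label ranks rho = 1
  expect_equal(spearman_rho(as.numeric(y == "high"), y)[["rho"]], 1)
  expect_true(is.na(spearman_rho(rep(1, 8), y)[["rho"]]))
  # null feature: |rho| small with high probability
  set.seed(3)
  r <- spearman_rho(rnorm(200), rep(c("low", "high"), 100))
  expect_lt(abs(r[["rho"]]), 0.2)
})

test_that("repeated CV is seed-deterministic and calibrated on null cohorts", {
  g <- gaussian_cohort(15, 3, seed = 23)
  r1 <- repeated_cv(g$X, g$y, repeats = 30, seed = 42)
  r2 <- repeated_cv(g$X, g$y, repeats = 30, seed = 42)
  expect_identical(r1$az_values, r2$az_values)
  expect_true(r1$az_ci[1] <= 0.5 && 0.5 <= r1$az_ci[2])
  expect_equal(r1$rsd, 100 * stats::sd(r1$az_values) / mean(r1$az_values))
})

test_that("a strongly separated cohort reaches the analytic AUC regime", {
  # delta = 3 sigma on 2 features: Bayes AUC ~ Phi(3*sqrt(2)/sqrt(2)) > 0.98
  g <- gaussian_cohort(30, 2, delta = 3, informative = 1:2, seed = 29)
  r <- repeated_cv(g$X, g$y, repeats = 50, seed = 1)
  expect_gt(r$az_mean, 0.95)
})

test_that("percentile CI for the null Az covers 0.5 at near-nominal rate", {
  set.seed(101)
  cover <- replicate(200, {
    g <- gaussian_cohort(20, 2, seed = sample.int(1e6, 1))
    r <- repeated_cv(g$X, g$y, repeats = 50, seed = sample.int(1e6, 1))
    r$az_ci[1] <= 0.5 && 0.5 <= r$az_ci[2]
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("SFFS equals exhaustive search at p = 2 and recovers planted signal", {
  g <- gaussian_cohort(25, 2, delta = 1.2, informative = 1, seed = 31)
  sel <- sffs_select(g$X, g$y, max_k = 2, seed = 5, repeats = 15)
  J <- function(S) repeated_cv(g$X[, S, drop = FALSE], g$y,
                               repeats = 15, seed = 5)$az_mean
  cand <- list(1L, 2L, 1:2)
  js <- vapply(cand, J, numeric(1))
  expect_equal(sort(sel$subset), sort(cand[[which.max(js)]]))
  expect_equal(sel$criterion, max(js), tolerance = 1e-12)
  # planted informative pair among permuted noise copies
  set.seed(33)
  g2 <- gaussian_cohort(50, 8, delta = 1.5, informative = 1:2, seed = 33)
  g2$X[, 3:8] <- apply(g2$X[, 3:8], 2, sample)  # destroy any structure
  sel2 <- sffs_select(g2$X, g2$y, max_k = 4, seed = 5, repeats = 15)
  expect_true(all(1:2 %in% sel2$subset))
  # determinism
  sel3 <- sffs_select(g2$X, g2$y, max_k = 4, seed = 5, repeats = 15)
  expect_identical(sel2$subset, sel3$subset)
})

test_that("combine_features passes columns jointly; z-scoring leaves Az invariant", {
  g <- gaussian_cohort(20, 5, delta = 1, informative = 1:2, seed = 41)
  expect_identical(combine_features(g$X, 3), g$X[, 3, drop = FALSE])
  expect_error(combine_features(g$X, integer(0)), "empty")
  r1 <- repeated_cv(combine_features(g$X, 1:2), g$y, repeats = 20, seed = 9)
  Xs <- scale(g$X)
  r2 <- repeated_cv(combine_features(Xs, 1:2), g$y, repeats = 20, seed = 9)
  expect_equal(r1$az_values, r2$az_values, tolerance = 1e-9)
  # column order is irrelevant to the joint classifier
  r3 <- repeated_cv(combine_features(g$X, 2:1), g$y, repeats = 20, seed = 9)
  expect_equal(r1$az_values, r3$az_values, tolerance = 1e-9)
})

test_that("the stability rule keeps accurate-and-stable features only", {
  mk <- function(name, az, rs) list(name = name, az_mean = az, rsd = rs)
  res <- list(mk("a", 0.9, 5), mk("b", 0.6, 9))
  expect_identical(rank_stable_features(res), "a")
  res3 <- list(mk("a", 0.9, 5), mk("b", 0.6, 9), mk("c", 0.75, 7.2))
  expect_true("a" %in% rank_stable_features(res3))
  same <- list(mk("a", 0.7, 6), mk("b", 0.7, 6))
  expect_length(rank_stable_features(same), 0L)
})

test_that("no single feature is systematically 'stable' under the null", {
  set.seed(59)
  p <- 25; reps <- 8
  hits <- matrix(FALSE, reps, p)
  for (i in seq_len(reps)) {
    g <- gaussian_cohort(12, p, seed = 600 + i)
    rs <- lapply(seq_len(p), function(j)
      repeated_cv(g$X[, j, drop = FALSE], g$y, repeats = 30, seed = 7,
                  name = paste0("f", j)))
    sel <- rank_stable_features(rs)
    hits[i, ] <- paste0("f", seq_len(p)) %in% sel
  }
  # selection frequency stays near the chance rate for every feature
  expect_lt(max(colMeans(hits)), 0.9)
  expect_lt(mean(hits), 0.5)
})

test_that("power-law fits invert noiseless data and stay monotone", {
  n <- c(10, 20, 40, 80, 160)
  err <- 0.5 * n^(-0.5) + 0.1
  f <- fit_power_law(n, err)
  expect_equal(c(f$a, f$alpha, f$epsilon), c(0.5, 0.5, 0.1), tolerance = 1e-4)
  expect_lt(f$residual, 1e-10)
  expect_true(all(diff(f$fitted) < 1e-12))
  # constant error degenerates to epsilon = err with a vanishing power term
  fc <- fit_power_law(n, rep(0.3, 5))
  expect_equal(fc$a * min(n)^(-fc$alpha) + fc$epsilon, 0.3, tolerance = 1e-3)
  expect_lt(fc$a * min(n)^(-fc$alpha), 1e-3)
  expect_error(fit_power_law(c(10, 10, 20, 20), c(.1, .1, .2, .2)), "distinct")
  expect_error(fit_power_law(n, err + 1), "\\[0, 1\\]")
})

test_that("learning curves decrease on separable data and are seeded", {
  g <- gaussian_cohort(60, 2, delta = 2, informative = 1:2, seed = 71)
  lc1 <- learning_curve(g$X, g$y, sizes = c(8, 16, 32, 64), reps = 30, seed = 3)
  lc2 <- learning_curve(g$X, g$y, sizes = c(8, 16, 32, 64), reps = 30, seed = 3)
  expect_identical(lc1$err, lc2$err)
  expect_true(all(lc1$err >= 0 & lc1$err <= 1))
  expect_lt(lc1$err[4], lc1$err[1])  # overall decreasing trend
  expect_error(learning_curve(g$X, g$y, sizes = 200), "exceeds")
})
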
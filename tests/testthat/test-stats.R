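test_that("stepwise selection finds a perfect predictor and follows the greedy path", {
  set.seed(10)
  x <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, c("A", "B", "C")))
  fit <- suppressWarnings(stepwise_select(x[, "B"], x))
  expect_equal(fit$selected[1], "B")
  expect_equal(unname(fit$coefficients["B"]), 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # greedy path equals an exhaustive best-single-term oracle at each step
  y <- 0.8 * x[, "A"] - 0.5 * x[, "C"] + rnorm(50, 0, 0.5)
  fit2 <- stepwise_select(y, x)
  chosen <- character(0)
  remaining <- colnames(x)
  repeat {
    ps <- vapply(remaining, function(v) {
      full <- lm(y ~ x[, c(chosen, v), drop = FALSE])
      reduced <- if (length(chosen)) lm(y ~ x[, chosen, drop = FALSE])
                 else lm(y ~ 1)
      anova(reduced, full)[2, "Pr(>F)"]
    }, numeric(1))
    if (min(ps) >= 0.05) break
    chosen <- c(chosen, names(which.min(ps)))
    remaining <- setdiff(remaining, chosen)
    if (!length(remaining)) break
  }
  expect_equal(fit2$selected, chosen)
  expect_error(stepwise_select(rep(1, 50), x), "zero-variance")
})

test_that("MANCOVA Wilks lambda matches stats::manova and the eigen oracle", {
  set.seed(4)
  n <- 12
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "pred"))
  Y <- cbind(y1 = 0.5 * X[, 1] + rnorm(n),
             y2 = -0.3 * X[, 1] + rnorm(n))
  res <- mancova(Y, X)

  sm <- summary(manova(Y ~ X), test = "Wilks")$stats
  expect_equal(res$wilks_lambda, sm["X", "Wilks"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$f_stat, sm["X", "approx F"], tolerance = 1e-8,
               ignore_attr = TRUE)

  # brute force: lambda = prod 1/(1 + theta_i), theta_i eigen of E^-1 H
  fitlm <- lm(Y ~ X)
  E <- crossprod(residuals(fitlm))
  H <- crossprod(sweep(Y, 2, colMeans(Y))) - E
  theta <- Re(eigen(solve(E) %*% H)$values)
  expect_equal(res$wilks_lambda, prod(1 / (1 + theta)), tolerance = 1e-10)

  # single-root effect size identity
  expect_equal(res$partial_eta_sq, 1 - res$wilks_lambda, tolerance = 1e-12)
  expect_equal(partial_eta_sq(0.79), 0.21, tolerance = 1e-12)

  # perfect fit drives lambda to zero
  X2 <- cbind(X, z = rnorm(n))
  Yp <- X2 %*% matrix(c(1, 0.5, -1, 2), 2, 2) +
    1e-8 * matrix(rnorm(2 * n), n)
  expect_lt(mancova(Yp, X2)$wilks_lambda, 1e-6)
})

test_that("MANCOVA per-term tests agree with sequential Wilks for the last term", {
  set.seed(8)
  n <- 40
  a <- rnorm(n); b <- rnorm(n)
  Y <- cbind(y1 = a + rnorm(n), y2 = rnorm(n), y3 = -b + rnorm(n))
  res <- mancova(Y, cbind(a = a, b = b))
  # in a sequential decomposition the last term's Wilks equals the
  # drop-one (type III) value our per-term test computes
  tab_b <- anova(lm(Y ~ a + b), test = "Wilks")
  expect_equal(res$terms$wilks_lambda[res$terms$term == "b"],
               tab_b["b", "Wilks"], tolerance = 1e-8)
  tab_a <- anova(lm(Y ~ b + a), test = "Wilks")
  expect_equal(res$terms$wilks_lambda[res$terms$term == "a"],
               tab_a["a", "Wilks"], tolerance = 1e-8)
})

test_that("canonical correlations match cancor and reduce to Pearson", {
  set.seed(5)
  n <- 30
  X <- matrix(rnorm(n * 3), n)
  # self-correlation: r1 = 1
  expect_equal(canonical_analysis(X, X)$correlations[1], 1,
               tolerance = 1e-8)

  # univariate reduction
  x1 <- rnorm(n); y1 <- 0.6 * x1 + rnorm(n)
  expect_equal(canonical_analysis(cbind(x1), cbind(y1))$correlations,
               abs(cor(x1, y1)), tolerance = 1e-10)

  # oracle equivalence on a small fixture
  Y <- matrix(rnorm(n * 2), n)
  ours <- canonical_analysis(X, Y)
  ref <- cancor(X, Y)
  expect_equal(ours$correlations, ref$cor, tolerance = 1e-8)

  # invariance to invertible affine re-parameterization of either side
  A <- matrix(c(2, 1, 0, 1, 3, 0, 0, 1, 1), 3)
  B <- matrix(c(1, 2, 0, 1), 2)
  trans <- canonical_analysis(X %*% A, sweep(Y %*% B, 2, c(5, -2), "+"))
  expect_equal(trans$correlations, ours$correlations, tolerance = 1e-8)

  # canonical score pairs within a side are uncorrelated
  cc <- cor(ours$left_scores)
  expect_equal(cc, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("k-means elbow recovers point masses and is seed-deterministic", {
  pts <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c(5, 5), 12), ncol = 2, byrow = TRUE),
               matrix(rep(c(-5, 8), 9), ncol = 2, byrow = TRUE))
  res <- suppressMessages(
    kmeans_elbow(pts, k_candidates = 2:4, seed = 3, standardize = FALSE))
  expect_equal(res$k, 3)
  expect_equal(unname(res$wss[["3"]]), 0)
  expect_equal(length(unique(res$codes[1:10])), 1)
  expect_equal(length(unique(res$codes[11:22])), 1)

  set.seed(77)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 4), ncol = 2),
             matrix(rnorm(60, c(8, -4)), ncol = 2))
  r1 <- kmeans_elbow(x, seed = 11)
  r2 <- kmeans_elbow(x, seed = 11)
  expect_identical(r1$codes, r2$codes)
  expect_identical(r1$k, r2$k)
  expect_true(all(diff(r1$wss) <= 1e-8))
  expect_error(kmeans_elbow(x[1:4, ], k_candidates = 2:6), "exceeds")
})

test_that("ANOVA/Tukey-Kramer matches hand computation and the printed effect size", {
  # identical groups: no between-group variance
  null <- anova_tukey(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(null$f_stat, 0)
  expect_equal(null$eta_sq, 0)

  # eta^2 implied by F(2, 104) = 5.83 is 0.1 at one decimal
  expect_equal(round(eta_sq_from_f(5.83, 2, 104), 1), 0.1)

  # 3-group toy table vs explicit formulas (unequal n)
  vals <- c(4.1, 3.8, 4.5, 4.0, 5.2, 5.6, 4.9, 6.1, 6.4, 6.0, 6.6)
  grp <- rep(c("g1", "g2", "g3"), c(4, 3, 4))
  res <- anova_tukey(vals, grp)
  m <- tapply(vals, grp, mean); ns <- tapply(vals, grp, length)
  ssb <- sum(ns * (m - mean(vals))^2)
  sse <- sum((vals - m[grp])^2)
  df1 <- 2; df2 <- length(vals) - 3
  f_hand <- (ssb / df1) / (sse / df2)
  expect_equal(res$f_stat, f_hand, tolerance = 1e-10)
  expect_equal(res$eta_sq, ssb / (ssb + sse), tolerance = 1e-10)
  mse <- sse / df2
  for (i in seq_len(nrow(res$pairwise))) {
    ab <- strsplit(res$pairwise$pair[i], "-")[[1]]
    q_hand <- abs(m[ab[1]] - m[ab[2]]) /
      sqrt(mse / 2 * (1 / ns[ab[1]] + 1 / ns[ab[2]]))
    expect_equal(res$pairwise$q[i], unname(q_hand), tolerance = 1e-10)
    expect_equal(res$pairwise$p_adj[i],
                 ptukey(q_hand, 3, df2, lower.tail = FALSE),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.031), 0.031)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # hand step-up oracle on random vectors
  set.seed(9)
  for (i in 1:5) {
    p <- runif(7)
    o <- order(p)
    m <- length(p)
    stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- pmin(1, stepup)[order(o)]
    adj <- bh_adjust(p)
    expect_equal(adj, oracle, tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})
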
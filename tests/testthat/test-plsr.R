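rand_xy <- function(n, k, seed, rank = NULL, noise = 0.1) {
  set.seed(seed)
  if (is.null(rank)) rank <- min(n, k)
  S <- matrix(rnorm(n * rank), n, rank)
  L <- matrix(rnorm(rank * k), rank, k)
  X <- S %*% L + matrix(rnorm(n * k, 0, noise), n, k)
  y <- drop(S %*% rnorm(rank)) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("exact rank-1 data are fitted perfectly by one component", {
  set.seed(1)
  t1 <- rnorm(20)
  p1 <- rnorm(8)
  X <- tcrossprod(t1, p1)
  m <- fit_plsr(X, t1, 1)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_equal(predict(m, X), t1, tolerance = 1e-8)
})

test_that("full-component PLSR equals ordinary least squares", {
  d <- rand_xy(30, 6, seed = 2, noise = 0.5)
  m <- fit_plsr(d$X, d$y, 6, scale = FALSE)
  # oracle: normal equations on centered data
  Xc <- scale(d$X, scale = FALSE)
  yc <- d$y - mean(d$y)
  beta <- solve(crossprod(Xc), crossprod(Xc, yc))
  expect_equal(predict(m, d$X), drop(Xc %*% beta) + mean(d$y),
               tolerance = 1e-8)
})

test_that("model structure invariants hold across random instances", {
  for (s in 1:200) {
    d <- rand_xy(12, 6, seed = s, rank = 3, noise = 0.2)
    m <- fit_plsr(d$X, d$y, 3)
    expect_true(all(abs(colSums(m$W^2) - 1) < 1e-9))
    G <- crossprod(m$T)
    off <- abs(G[upper.tri(G)]) / sqrt(diag(G)[1] * diag(G)[2])
    expect_true(all(off < 1e-8))
    expect_true(all(m$ss >= -1e-12))
    expect_true(all(diff(cumsum(m$ss)) >= -1e-12))
    # sign convention: largest-magnitude weight entry positive
    for (j in seq_len(ncol(m$W)))
      expect_gt(m$W[which.max(abs(m$W[, j])), j], 0)
  }
})

test_that("per-component SS matches independent deflation bookkeeping", {
  d <- rand_xy(20, 10, seed = 5, rank = 3, noise = 0.3)
  m <- fit_plsr(d$X, d$y, 3)
  # oracle: residual response sum of squares before/after each deflation
  ys <- (d$y - mean(d$y)) / sd(d$y)
  f <- ys
  ss_oracle <- numeric(3)
  for (n in 1:3) {
    tn <- m$T[, n]
    qn <- sum(tn * f) / sum(tn^2)
    res <- f - tn * qn
    ss_oracle[n] <- sum(f^2) - sum(res^2)
    f <- res
  }
  expect_equal(m$ss, ss_oracle, tolerance = 1e-8)
  expect_equal(sum(m$ss) / m$tss, m$r2, tolerance = 1e-12)
})

test_that("joint row permutation leaves coefficients and SS unchanged", {
  d <- rand_xy(25, 8, seed = 6, rank = 2)
  m1 <- fit_plsr(d$X, d$y, 2)
  set.seed(7)
  perm <- sample(25)
  m2 <- fit_plsr(d$X[perm, ], d$y[perm], 2)
  expect_equal(m1$B, m2$B, tolerance = 1e-10)
  expect_equal(m1$ss, m2$ss, tolerance = 1e-10)
})

test_that("duplicated predictor columns barely change predictions", {
  # with noiseless low-rank data the fit is exact, so the duplicate is
  # fully redundant and the prediction is unchanged
  d <- rand_xy(25, 8, seed = 8, rank = 3, noise = 0)
  m1 <- fit_plsr(d$X, d$y, 3)
  X2 <- cbind(d$X, d$X[, 1])
  m2 <- fit_plsr(X2, d$y, 3)
  expect_lt(max(abs(predict(m1, d$X) - predict(m2, X2))), 1e-6)
})

test_that("degenerate inputs are rejected or truncated", {
  d <- rand_xy(10, 4, seed = 9)
  expect_error(fit_plsr(d$X, rep(1, 10), 2), "zero response variance")
  expect_warning(m <- fit_plsr(d$X, d$y, 9), "truncated")
  expect_lte(m$n_components, 4)
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  d <- rand_xy(30, 10, seed = 10, rank = 3, noise = 0.3)
  colnames(d$X) <- paste0("V", 1:10)
  m <- fit_plsr(d$X, d$y, 3)
  om <- mixOmics::pls(d$X, d$y, ncomp = 3, mode = "regression",
                      scale = TRUE)
  op <- predict(om, d$X)$predict[, 1, 3]
  expect_equal(unname(predict(m, d$X)), unname(op), tolerance = 1e-6)
})

test_that("cross-validation matches a hand-rolled fold loop", {
  d <- rand_xy(8, 4, seed = 42, rank = 2, noise = 0.2)
  cv <- cross_validate(d$X, d$y, 2, n_folds = 4, seed = 42)
  folds <- make_folds(8, 4, seed = 42)
  expect_identical(cv$fold_assignment, folds)
  pred <- numeric(8)
  for (k in 1:4) {
    te <- folds == k
    fit <- fit_plsr(d$X[!te, ], d$y[!te], 2)
    pred[te] <- predict(fit, d$X[te, , drop = FALSE])
  }
  press <- sum((d$y - pred)^2)
  tss <- sum((d$y - mean(d$y))^2)
  expect_equal(cv$q2, 1 - press / tss, tolerance = 1e-10)
  expect_equal(cv$mspe_percent, 100 * press / tss, tolerance = 1e-10)
  # determinism: same seed, same partition, bit-identical Q2
  expect_identical(cv$q2, cross_validate(d$X, d$y, 2, 4, seed = 42)$q2)
})

test_that("noiseless linear data are perfectly predictable; noise is not", {
  d <- rand_xy(35, 10, seed = 11, rank = 2, noise = 0)
  cv <- cross_validate(d$X, d$y, 2, n_folds = 10, seed = 3)
  expect_gte(cv$q2, 0.999)
  # y independent of X: cross-validated prediction cannot beat the mean,
  # so PRESS exceeds TSS in expectation and Q2 is almost always <= 0
  q2s <- vapply(1:200, function(s) {
    set.seed(s + 5000)
    X <- matrix(rnorm(35 * 10), 35, 10)
    y <- rnorm(35)
    cross_validate(X, y, 2, 10, seed = s)$q2
  }, numeric(1))
  expect_lt(mean(q2s), 0)
  expect_gte(mean(q2s <= 0), 0.9)
})

test_that("component selection finds the generative rank", {
  d <- rand_xy(35, 15, seed = 12, rank = 2, noise = 0.05)
  sel <- select_ncomp(d$X, d$y, max_components = 5, seed = 4)
  expect_equal(sel$n_components, 2)
  # pure-noise response floors at one component
  set.seed(13)
  Xn <- matrix(rnorm(35 * 10), 35, 10)
  yn <- rnorm(35)
  seln <- select_ncomp(Xn, yn, max_components = 4, seed = 4)
  expect_equal(seln$n_components, 1)
  # zero tolerance returns the Q2 argmax
  sel0 <- select_ncomp(d$X, d$y, max_components = 5, seed = 4,
                       tolerance = 0)
  expect_equal(sel0$n_components, sel0$trace$n[which.max(sel0$trace$q2)])
})

test_that("models serialize and reload through structured text", {
  d <- rand_xy(20, 6, seed = 14, rank = 2)
  m <- fit_plsr(d$X, d$y, 2)
  path <- tempfile(fileext = ".json")
  write_plsr_model(m, path)
  m2 <- read_plsr_model(path)
  expect_equal(m$B, m2$B, tolerance = 1e-12)
  expect_equal(unname(predict(m, d$X)), predict(m2, d$X),
               tolerance = 1e-12)
})
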
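test_that("an exact rank-1 matrix yields one component with r2 = 1", {
  set.seed(2)
  u <- rnorm(15); u <- u - mean(u)
  v <- rnorm(6)
  x <- u %*% t(v)
  fit <- nipals_pca(x, n_components = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residual)), 1e-8)
})

test_that("NIPALS matches a dense SVD on complete matrices", {
  cases <- list(c(20, 10), c(12, 25), c(30, 8))
  for (ci in seq_along(cases)) {
    n <- cases[[ci]][1]; p <- cases[[ci]][2]
    set.seed(100 + ci)
    x <- sweep(matrix(rnorm(n * p), n, p), 2, 0)
    x <- sweep(x, 2, colMeans(x), "-")
    A <- 4
    fit <- nipals_pca(x, n_components = A, tol = 1e-11, max_iter = 5000)
    sv <- svd(x)
    for (a in seq_len(A)) {
      sc <- sv$u[, a] * sv$d[a]
      lo <- sv$v[, a]
      if (sum(lo * fit$loadings[, a]) < 0) { sc <- -sc; lo <- -lo }
      expect_lt(max(abs(sc - fit$scores[, a])), 1e-6)
      expect_lt(max(abs(lo - fit$loadings[, a])), 1e-6)
      expect_equal(fit$r2[a], sv$d[a]^2 / sum(sv$d^2), tolerance = 1e-8)
    }
    # structural invariants: unit-norm loadings, orthogonal scores,
    # sign convention, r2 bounds
    expect_equal(colSums(fit$loadings^2), rep(1, A),
                 ignore_attr = TRUE, tolerance = 1e-8)
    cc <- abs(cor(fit$scores))
    expect_lt(max(cc[upper.tri(cc)]), 1e-6)
    for (a in seq_len(A)) {
      l <- fit$loadings[, a]
      expect_gt(l[which.max(abs(l))], 0)
    }
    expect_true(all(fit$r2 >= 0 & fit$r2 <= 1) && sum(fit$r2) <= 1 + 1e-12)
  }
})

test_that("missing cells have exactly zero residual and no leverage", {
  set.seed(5)
  x <- make_low_rank(40, 12, 2, noise_sd = 0.05, seed = 5)
  xm <- x
  xm[sample(length(x), round(0.1 * length(x)))] <- NA
  fit <- nipals_pca(xm, n_components = 2)
  expect_true(all(fit$residual[is.na(xm)] == 0))
  full <- nipals_pca(x, n_components = 2)
  expect_gte(abs(cor(fit$scores[, 1], full$scores[, 1])), 0.99)
})

test_that("cumulative r2 is monotone and the component cap is enforced", {
  set.seed(6)
  x <- sweep(matrix(rnorm(18 * 7), 18, 7), 2, 0)
  x <- sweep(x, 2, colMeans(x), "-")
  fit <- nipals_pca(x, n_components = 5)
  expect_monotone_nondecreasing(cumsum(fit$r2))
  expect_error(nipals_pca(x, n_components = 8), "exceeds")
  # cum-r2 stopping rule
  auto <- nipals_pca(x, cum_r2 = 0.6)
  expect_gte(sum(auto$r2), 0.6)
  expect_lt(sum(auto$r2[-length(auto$r2)]), 0.6)
})

test_that("jackknife intervals are tight on noise-free data and match a naive loop", {
  x <- make_low_rank(12, 5, 1, noise_sd = 0, seed = 9) +
    matrix(rnorm(60, sd = 1e-9), 12, 5)
  jk0 <- jackknife_loading_ci(x, n_components = 1)
  expect_lt(max(jk0$upper - jk0$lower), 1e-6)

  # naive leave-one-out loop with an SVD refit as the oracle
  set.seed(10)
  x <- make_low_rank(30, 5, 2, noise_sd = 0.4, seed = 10)
  x[, 3] <- x[, 3] * 3                      # one high-variance variable
  jk <- jackknife_loading_ci(x, n_components = 1, level = 0.95, tol = 1e-12)
  full <- svd(sweep(x, 2, colMeans(x), "-"))$v[, 1]
  if (full[which.max(abs(full))] < 0) full <- -full
  reps <- sapply(seq_len(nrow(x)), function(i) {
    xi <- x[-i, ]
    v <- svd(sweep(xi, 2, colMeans(xi), "-"))$v[, 1]
    if (sum(v * full) < 0) v <- -v
    v
  })
  n <- nrow(x)
  se <- sqrt(((n - 1) / n) * rowSums((reps - rowMeans(reps))^2))
  q <- qt(0.975, df = n - 1)
  expect_equal(unname(jk$se[, 1]), se, tolerance = 1e-7)
  expect_equal(unname(jk$lower[, 1]), full - q * se, tolerance = 1e-7)
  expect_equal(unname(jk$upper[, 1]), full + q * se, tolerance = 1e-7)
})

test_that("the bundled sweep table's first component is driven by the small blocks", {
  ex <- strictness_sweep_example()
  fit <- r2xj_table_pca(ex$r2xj, n_components = 1)
  l <- abs(fit$loadings[, 1])
  top2 <- names(sort(l, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("alva_add", "QM"))
})
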
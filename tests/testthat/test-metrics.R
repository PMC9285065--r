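test_that("score correlation matrices are 1 on the diagonal and NA off-membership", {
  fit <- fit_default(1)$fit
  mats <- score_correlation_matrix(fit)
  expect_gt(length(mats), 0)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    idx <- as.integer(sub("c", "", nm))
    cmp <- fit$components[[idx]]
    expect_equal(unname(diag(m)[cmp$blocks]), rep(1, length(cmp$blocks)))
    non <- setdiff(rownames(m), cmp$blocks)
    if (length(non)) expect_true(all(is.na(m[non, ])))
    # brute-force recomputation from the stored score vectors
    for (a in cmp$blocks) for (b in cmp$blocks)
      expect_equal(m[a, b], cor(cmp$scores[[a]], cmp$scores[[b]]),
                   tolerance = 1e-12)
  }
})

test_that("identical blocks correlate perfectly on every joint component", {
  set.seed(21)
  X <- matrix(rnorm(80 * 8), 80, 8) %*% diag(sqrt(seq(3, 1, length.out = 8)))
  fit <- moca(multiblock(list(block_matrix(X, "b1"), block_matrix(X, "b2"))))
  for (m in score_correlation_matrix(fit))
    expect_equal(abs(m["b1", "b2"]), 1, tolerance = 1e-8)
  # and the redundancy of either block equals its joint explained variance
  expect_equal(redundancy(fit, "b1"), unname(fit$r2xj["b1"]), tolerance = 1e-6)
})

test_that("redundancy and predictivity handle edge cases and bad input", {
  # blocks with no joint structure at all
  set.seed(22)
  b1 <- block_matrix(matrix(rnorm(200 * 120), 200, 120), "x1")
  b2 <- block_matrix(matrix(rnorm(200 * 130), 200, 130), "x2")
  fit <- moca(multiblock(list(b1, b2)))
  expect_identical(redundancy(fit, "x1"), 0)
  expect_identical(predictivity(fit, "x1", "x2"), 0)
  expect_error(redundancy(fit, "nope"), "unknown target")
  expect_error(predictivity(fit, "x1", "nope"), "unknown target")
})

test_that("self-predictivity from per-component contributions sums exactly", {
  expect_equal(predictivity_contributions(c(0.52, 0.17, 0.09), c(1, 1, 1)),
               0.78, tolerance = 1e-12)
  expect_equal(predictivity_contributions(numeric(0), numeric(0)), 0)
})

test_that("metric identities and bounds hold on fitted models", {
  for (s in 1:3) {
    fit <- fit_default(s)$fit
    for (tg in fit$block_names) {
      rt <- redundancy(fit, tg)
      expect_gte(rt, 0)
      expect_lte(rt, fit$r2xj[[tg]] + 1e-8)
      expect_equal(predictivity(fit, tg, tg), unname(fit$r2xj[tg]),
                   tolerance = 1e-8)
      for (a in fit$block_names)
        expect_lte(predictivity(fit, a, tg), fit$r2xj[[tg]] + 1e-8)
    }
  }
})

test_that("predictivity recovers a planted imperfect score correlation", {
  # block A carries the target's single joint latent at planted correlation
  # rho = 0.9, so P(A, target) should equal R2Xj(target) * 0.9
  devs <- sapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 200
    base <- make_score_set(n, 2, seed = 400 + s)
    z <- base[, 1]
    zc <- 0.9 * z + sqrt(1 - 0.81) * base[, 2]
    A <- z %*% t(rnorm(30)) + matrix(rnorm(n * 30, sd = 0.25), n, 30)
    Tg <- zc %*% t(rnorm(25)) + matrix(rnorm(n * 25, sd = 0.25), n, 25)
    fit <- moca(multiblock(list(block_matrix(A, "A"),
                                block_matrix(Tg, "target"))),
                strictness = -0.5)
    predictivity(fit, "A", "target") - fit$r2xj[["target"]] * 0.9
  })
  expect_lt(max(abs(devs)), 0.05)
})

test_that("absolute-value correlations never lose to signed ones", {
  fit <- fit_default(2)$fit
  for (tg in fit$block_names) {
    signed_r <- 0
    for (cmp in fit$components) {
      if (cmp$kind == "unique" || !(tg %in% cmp$blocks)) next
      others <- setdiff(cmp$blocks, tg)
      if (!length(others)) next
      signed_r <- signed_r + cmp$r2[[tg]] *
        max(vapply(others, function(a) cor(cmp$scores[[a]], cmp$scores[[tg]]), 0))
    }
    expect_lte(signed_r, redundancy(fit, tg) + 1e-12)
  }
})

test_that("redundancy is invariant to block and observation order", {
  sim <- default_sim(5)
  fit <- moca(sim$data, strictness = -0.2)
  perm <- multiblock(list(sim$data$B, sim$data$C, sim$data$A))
  fitp <- moca(perm, strictness = -0.2)
  for (tg in c("A", "B", "C"))
    expect_equal(redundancy(fitp, tg), redundancy(fit, tg), tolerance = 1e-8)
})

test_that("the r2 overview table reproduces the model totals", {
  fit <- fit_default(1)$fit
  ov <- r2_overview(fit)
  for (b in fit$block_names) {
    per_comp <- ov[ov$block == b & !is.na(ov$component), ]
    expect_equal(sum(per_comp$r2[per_comp$kind != "unique"]),
                 unname(fit$r2xj[b]), tolerance = 1e-10)
    expect_equal(sum(per_comp$r2[per_comp$kind == "unique"]),
                 unname(fit$r2xu[b]), tolerance = 1e-10)
    expect_equal(ov$r2[ov$block == b & ov$kind == "residual"],
                 unname(fit$r2_residual[b]), tolerance = 1e-12)
  }
  # a model with no joint components has only unique and total rows
  set.seed(23)
  b1 <- block_matrix(matrix(rnorm(200 * 120), 200, 120), "x1")
  b2 <- block_matrix(matrix(rnorm(200 * 130), 200, 130), "x2")
  fit0 <- moca(multiblock(list(b1, b2)))
  ov0 <- r2_overview(fit0)
  expect_true(all(ov0$kind[!is.na(ov0$component)] == "unique"))
})

test_that("block metrics assemble into a tidy table with a target column", {
  out <- fit_default(3)
  data <- out$sim$data
  attr(data, "target") <- "C"
  fit <- moca(data, strictness = -0.2)
  bm <- block_metrics(fit)
  expect_identical(bm$block, c("A", "B", "C"))
  expect_equal(bm$predictivity[bm$block == "C"], unname(fit$r2xj["C"]),
               tolerance = 1e-8)
  tmp <- tempfile(fileext = ".tsv")
  long <- write_metrics_tsv(fit, tmp)
  tab <- read.delim(tmp)
  expect_setequal(unique(tab$metric),
                  c("r2xj", "r2xu", "redundancy", "predictivity"))
  expect_equal(nrow(tab), nrow(long))
})
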
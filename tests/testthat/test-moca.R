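test_that("planted global/local/unique structure is recovered", {
  for (s in 1:3) {
    out <- fit_default(s)
    fit <- out$fit
    kinds <- vapply(fit$components, `[[`, "", "kind")
    expect_identical(sum(kinds == "global"), 1L)
    expect_identical(sum(kinds == "local"), 1L)
    loc <- fit$components[[which(kinds == "local")]]
    expect_setequal(loc$blocks, c("A", "B"))
    # every block carries at least one unique component
    ub <- unlist(lapply(fit$components[kinds == "unique"], `[[`, "blocks"))
    expect_setequal(unique(ub), c("A", "B", "C"))
    rr <- recovery_report(fit, out$sim$truth)
    joint <- rr$kind_planted != "unique"
    expect_true(all(rr$cor[joint] >= 0.95))
    expect_true(all(rr$kind_match[joint]))
    # unique factors recovered as unique components at the empirical level
    expect_true(all(rr$cor[!joint] >= 0.85))
  }
})

test_that("two identical blocks are fully joint", {
  set.seed(42)
  X <- matrix(rnorm(100 * 12), 100, 12) %*% diag(sqrt(seq(4, 1, length.out = 12)))
  fit <- moca(multiblock(list(block_matrix(X, "b1"), block_matrix(X, "b2"))))
  expect_true(all(fit$r2xu <= 0.02))
  expect_true(all(vapply(fit$components, `[[`, "", "kind") == "global"))
  expect_true(all(fit$r2xj >= 0.95))
})

test_that("variance decomposition is conserved and monotone in strictness", {
  svals <- c(-0.01, -0.03, -0.05, -0.1, -0.2, -0.5)
  sim <- default_sim(2)
  sw <- strictness_sweep(sim$data, svals)
  for (s in svals) {
    fit <- moca(sim$data, strictness = s)
    expect_equal(unname(fit$r2xj + fit$r2xu + fit$r2_residual),
                 rep(1, 3), tolerance = 1e-6)
    # the sweep reproduces the standalone fit
    expect_equal(sw$table[sprintf("%g", s), ], fit$r2xj, tolerance = 1e-10)
  }
  for (b in colnames(sw$table)) expect_monotone_nondecreasing(sw$table[, b])
  expect_true(all(sw$table >= 0 & sw$table <= 1))
})

test_that("classification accepts or rejects by consensus correlation", {
  # three blocks whose matched directions correlate ~0.97 with the
  # consensus: rejected at strictness -0.01 (0.97 < 0.99), accepted at -0.5
  n <- 400
  base <- make_score_set(n, 7, seed = 8)
  z <- base[, 1]
  rho <- 0.955
  mk <- function(e) {
    v <- rho * z + sqrt(1 - rho^2) * e
    v / sqrt(sum(v^2))
  }
  bases <- list(b1 = cbind(mk(base[, 2])), b2 = cbind(mk(base[, 3])),
                b3 = cbind(mk(base[, 4])))
  strict <- classify_joint(bases, -0.01)
  expect_length(strict$components, 0)
  expect_identical(sum(vapply(strict$rejected, ncol, 0L)), 3L)
  lax <- classify_joint(bases, -0.5)
  expect_length(lax$components, 1)
  expect_identical(lax$components[[1]]$kind, "global")
  ccor <- lax$components[[1]]$consensus_cor
  expect_true(all(ccor >= 0.96 & ccor < 0.99))
})

test_that("every joint component meets the member-consensus bound post fit", {
  for (s in c(-0.2, -0.05)) {
    fit <- fit_default(1, strictness = s)$fit
    for (cmp in fit$components) {
      if (cmp$kind == "unique") next
      cd <- consensus_and_disagreement(cmp)
      for (b in cmp$blocks)
        expect_gte(abs(cor(cmp$scores[[b]], cd$consensus)), 1 + s - 0.02)
    }
  }
})

test_that("consensus and disagreement behave as an RMS deviation", {
  z <- drop(make_score_set(60, 1, seed = 3)) * 3
  cd <- consensus_and_disagreement(list(z, 2 * z, -z))   # sign/scale aligned
  expect_equal(max(cd$disagreement), 0, tolerance = 1e-10)
  expect_gte(abs(cor(cd$consensus, z)), 1 - 1e-10)

  # a single deviating observation dominates the disagreement
  s1 <- z / sd(z); s2 <- s1
  s2[17] <- s2[17] + 2
  cd2 <- consensus_and_disagreement(list(s1, s2))
  expect_identical(which.max(cd2$disagreement), 17L)

  # closed form: members = latent + noise sd sigma -> mean RMS ~ sigma*sqrt(2/3)
  # (exactly: times E[chi_2]/sqrt(2) for the root of an averaged chi-square
  # with 2 df, and 1/sqrt(1+sigma^2) for the unit-variance scaling)
  set.seed(12)
  sigma <- 0.3
  dis <- replicate(50, {
    zz <- rnorm(100)
    mean(consensus_and_disagreement(
      lapply(1:3, function(i) zz + rnorm(100, sd = sigma)))$disagreement)
  })
  approx_form <- sigma * sqrt(2 / 3)
  exact_form <- approx_form * (sqrt(pi) / 2) / sqrt(1 + sigma^2)
  expect_equal(mean(dis), exact_form, tolerance = 0.03)
  expect_lt(abs(mean(dis) - approx_form) / approx_form, 0.16)
})

test_that("block order and observation order are equivariances", {
  sim <- default_sim(4)
  fit <- moca(sim$data, strictness = -0.2)
  # permuted block order
  perm <- multiblock(list(sim$data$C, sim$data$A, sim$data$B))
  fitp <- moca(perm, strictness = -0.2)
  expect_equal(fitp$r2xj[names(fit$r2xj)], fit$r2xj, tolerance = 1e-8)
  expect_equal(fitp$r2xu[names(fit$r2xu)], fit$r2xu, tolerance = 1e-8)
  # permuted observation order
  set.seed(99)
  ord <- sample(length(attr(sim$data, "obs_ids")))
  blocks2 <- lapply(sim$data, function(b)
    block_matrix(b$values[ord, ], b$name, b$var_names, b$obs_ids[ord]))
  fito <- moca(multiblock(blocks2), strictness = -0.2)
  g1 <- fit$components[[1]]$consensus
  g2 <- fito$components[[1]]$consensus
  expect_gte(abs(cor(g1[ord], g2)), 1 - 1e-8)
  expect_equal(fito$r2xj, fit$r2xj, tolerance = 1e-8)
})

test_that("step functions handle empty and full bases", {
  set.seed(13)
  x <- scale(matrix(rnorm(40 * 6), 40, 6))
  # empty basis: everything is residual
  sp <- split_joint_unique(x, matrix(0, 0, 0))
  expect_equal(sp$residual, unname(x), ignore_attr = TRUE)
  expect_true(all(sp$joint == 0))
  # full-rank basis: nothing is residual
  B <- qr.Q(qr(x))
  spf <- split_joint_unique(x, B)
  expect_lt(sqrt(sum(spf$residual^2)) / sqrt(sum(x^2)), 1e-8)
  # compression of redundant copies of one latent from 3 partners
  z <- make_score_set(40, 1, seed = 14)
  ps <- lapply(1:3, function(i) {
    structure(list(block_a = "x", block_b = paste0("p", i), n_joint = 1L,
                   scores_a = z, scores_b = z), class = "pairwise_joint")
  })
  basis <- collect_and_compress("x", ps)
  expect_identical(ncol(basis), 1L)
  expect_gte(abs(cor(basis[, 1], z[, 1])), 1 - 1e-10)
  # two distinct shared latents survive compression
  z2 <- make_score_set(40, 2, seed = 15)
  ps2 <- list(structure(list(block_a = "x", block_b = "p1", n_joint = 1L,
                             scores_a = z2[, 1, drop = FALSE]), class = "pairwise_joint"),
              structure(list(block_a = "x", block_b = "p2", n_joint = 1L,
                             scores_a = 0.6 * z2[, 2, drop = FALSE]), class = "pairwise_joint"))
  expect_identical(ncol(collect_and_compress("x", ps2)), 2L)
  # no pairwise sets at all
  expect_identical(ncol(collect_and_compress("x", list())), 0L)
})

test_that("pure-noise residuals produce no unique components", {
  zeros <- sapply(1:20, function(s) {
    set.seed(2000 + s)
    r <- scale(matrix(rnorm(200 * 20), 200, 20), scale = FALSE)
    length(extract_unique(r)$r2) == 0
  })
  expect_gte(sum(zeros), 18)
  # while a planted factor above the noise floor is still found
  set.seed(77)
  z <- make_score_set(200, 1, seed = 77)
  r <- z %*% t(rnorm(20)) + matrix(rnorm(200 * 20), 200, 20)
  r <- scale(r, scale = FALSE)
  ex <- extract_unique(r)
  expect_gte(length(ex$r2), 1)
  expect_gte(abs(cor(ex$scores[, 1], z[, 1])), 0.9)
})

test_that("sweep edge cases and input validation", {
  sim <- default_sim(1)
  expect_warning(sw1 <- strictness_sweep(sim$data, -0.1), "meta-PCA skipped")
  expect_identical(nrow(sw1$table), 1L)
  expect_null(sw1$pca)
  expect_error(moca_options(strictness = 0.1), "strictness")
  expect_error(moca_options(strictness = -1.5), "strictness")
  expect_error(moca(multiblock(list(sim$data$A))), "at least 2 blocks")
  zb <- block_matrix(matrix(0, 10, 3), "flat")
  zb$preprocessing <- "centered"
  ok <- block_matrix(scale(matrix(rnorm(30), 10, 3)), "ok")
  ok$preprocessing <- "centered"
  expect_error(moca(multiblock(list(zb, ok))), "zero variance")
})
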
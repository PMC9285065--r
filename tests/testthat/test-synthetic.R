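test_that("generation is deterministic and latents are orthogonal unit variance", {
  spec <- synthetic_spec(seed = 7)
  s1 <- generate_multiblock(spec)
  s2 <- generate_multiblock(spec)
  expect_identical(s1$data$A$values, s2$data$A$values)
  expect_identical(s1$truth$latents, s2$truth$latents)
  Z <- s1$truth$latents
  G <- crossprod(Z)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, ncol(Z)), tolerance = 1e-12)
  # generation does not disturb the caller's RNG stream
  set.seed(31); before <- rnorm(3)
  set.seed(31); invisible(generate_multiblock(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the noise-free single-global limit is exactly rank one", {
  sim <- generate_multiblock(synthetic_spec(
    n_obs = 50, blocks = c(a = 6, b = 9), global = 1, local = list(),
    unique = c(a = 0, b = 0), noise_sd = 0, seed = 3))
  for (b in sim$data) {
    sv <- svd(sweep(b$values, 2, colMeans(b$values), "-"))$d
    expect_lt(sv[2] / sv[1], 1e-10)
  }
  fit <- moca(sim$data)
  expect_identical(vapply(fit$components, `[[`, "", "kind"), "global")
  expect_equal(unname(fit$r2xj), c(1, 1), tolerance = 1e-6)
})

test_that("realized variance fractions match the design at moderate n", {
  sim <- generate_multiblock(synthetic_spec(
    n_obs = 500, blocks = c(a = 40, b = 40), global = 1, local = list(),
    unique = c(a = 0, b = 0), design_r2 = list(global = 0.5, local = 0, unique = 0),
    noise_sd = 0.4, seed = 5))
  for (f in sim$truth$realized_r2[[1]])
    expect_lt(abs(f - 0.5), 0.05)
  # and fractions tighten as n grows
  dev_at <- function(n) {
    s <- generate_multiblock(synthetic_spec(
      n_obs = n, blocks = c(a = 40, b = 40), global = 1, local = list(),
      unique = c(a = 0, b = 0), design_r2 = list(global = 0.5, local = 0, unique = 0),
      noise_sd = 0.4, seed = 11))
    max(abs(unlist(s$truth$realized_r2) - 0.5))
  }
  expect_lt(dev_at(2000), 0.05)
})

test_that("impossible factor layouts are rejected", {
  expect_error(generate_multiblock(synthetic_spec(
    n_obs = 30, blocks = c(a = 2, b = 50),
    global = 3, local = list(), unique = c(a = 0, b = 0),
    design_r2 = list(global = 0.2, local = 0, unique = 0))),
    "more latent factors")
  expect_error(synthetic_spec(local = list("A")), "size >= 2")
  expect_error(synthetic_spec(design_r2 = list(global = 0.9, local = 0.2,
                                               unique = 0.15)),
               "sum to >= 1")
})

test_that("recovery matching agrees with exhaustive assignment on small cases", {
  out <- fit_default(1)
  rr <- recovery_report(out$fit, out$sim$truth)
  # exhaustive best one-to-one assignment over the joint components
  comp_scores <- lapply(out$fit$components, function(cmp)
    if (!is.null(cmp$consensus)) cmp$consensus else cmp$scores[[1]])
  L <- ncol(out$sim$truth$latents); K <- length(comp_scores)
  cmat <- matrix(0, L, K)
  for (l in 1:L) for (k in 1:K)
    cmat[l, k] <- abs(cor(out$sim$truth$latents[, l], comp_scores[[k]]))
  perms <- utils::combn(K, L, simplify = FALSE)
  best <- -Inf; best_assign <- NULL
  for (cols in perms) {
    for (pp in .permutations(L)) {
      tot <- sum(cmat[cbind(1:L, cols[pp])])
      if (tot > best) { best <- tot; best_assign <- cols[pp] }
    }
  }
  greedy_total <- sum(rr$cor, na.rm = TRUE)
  expect_equal(greedy_total, best, tolerance = 1e-10)
  expect_identical(rr$component, vapply(best_assign, function(k)
    out$fit$components[[k]]$index, 0L))
})

test_that("the pesticide-like fixture behaves like a noisy endpoint project", {
  px <- pesticide_like_fixture(seed = 1)
  expect_identical(attr(px$data, "target"), "bio")
  expect_equal(mean(is.na(px$data$bio$values)), 0.3, tolerance = 0.05)
  expect_true(all(!is.na(px$data$RDK$values)))

  fit_lax <- moca(px$data, strictness = -0.2)
  fit_strict <- moca(px$data, strictness = -0.01)
  bio_joint <- function(fit) sum(vapply(fit$components, function(cmp)
    cmp$kind != "unique" && "bio" %in% cmp$blocks, TRUE))
  # relaxing strictness pulls the small endpoint block into joint components
  expect_identical(bio_joint(fit_strict), 0L)
  expect_gte(bio_joint(fit_lax), 2L)
  expect_gte(fit_lax$r2xj[["bio"]], 0.6)
  # no planted unique endpoint structure: whatever lands in the bio
  # unique pool is unexplained joint tail, well below the joint fraction
  expect_lt(fit_lax$r2xu[["bio"]], fit_lax$r2xj[["bio"]] / 3)
})
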
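# Shared builders for small in-code fixtures.

# centered matrix with exact low rank r built from orthonormalized factors
make_low_rank <- function(n, p, r, noise_sd = 0, seed = 1) {
  set.seed(seed)
  z <- qr.Q(qr(matrix(rnorm(n * r), n, r)))
  v <- matrix(rnorm(p * r), p, r)
  x <- z %*% t(v)
  if (noise_sd > 0) x <- x + matrix(rnorm(n * p, sd = noise_sd), n, p)
  sweep(x, 2, colMeans(x), "-")
}

# two raw blocks sharing one exact latent plus independent noise
make_shared_pair <- function(n = 120, pa = 15, pb = 20, noise_sd = 0.3,
                             seed = 1) {
  set.seed(seed)
  z <- scale(rnorm(n))
  xa <- z %*% t(rnorm(pa)) + matrix(rnorm(n * pa, sd = noise_sd), n, pa)
  xb <- z %*% t(rnorm(pb)) + matrix(rnorm(n * pb, sd = noise_sd), n, pb)
  list(a = block_matrix(xa, "a"), b = block_matrix(xb, "b"), latent = drop(z))
}

# mean-zero, mutually orthogonal unit-variance score vectors
make_score_set <- function(n, k, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k)
  m <- sweep(m, 2, colMeans(m), "-")
  q <- qr.Q(qr(m))
  sweep(q, 2, apply(q, 2, sd), "/")
}

# default synthetic study conditions used throughout the suite
default_sim <- function(seed) generate_multiblock(synthetic_spec(seed = seed))

fit_default <- function(seed, strictness = -0.2) {
  sim <- default_sim(seed)
  list(sim = sim, fit = moca(sim$data, strictness = strictness))
}

expect_monotone_nondecreasing <- function(x, tol = 1e-8) {
  expect_true(all(diff(x) >= -tol))
}

# all permutations of 1:n (n small), used by the assignment oracle
.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .permutations(n - 1)
    for (r in rest) out[[length(out) + 1]] <- c(i, setdiff(seq_len(n), i)[r])
  }
  out
}
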
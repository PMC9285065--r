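#' Specify a synthetic multiblock dataset with planted structure
#'
#' Builds the factor layout for [generate_multiblock()]: a set of blocks
#' sharing observations, generated from orthogonal latent factors that are
#' globally joint (loading on every block), locally joint (a strict subset
#' of at least two blocks) or unique (one block), plus Gaussian noise.
#' Factor strengths are expressed as design variance fractions: the expected
#' share of a block's total variance attributable to the factor.
#'
#' @param n_obs Number of observations. Default 200.
#' @param blocks Named integer vector of variables per block. Default three
#'   blocks of 30/50/80 variables.
#' @param global Number of globally joint factors. Default 1.
#' @param local List of character vectors, each the member blocks of one
#'   locally joint factor (size >= 2 and < number of blocks).
#' @param unique Named integer vector, unique factors per block.
#' @param design_r2 List with elements `global`, `local`, `unique`: design
#'   variance fraction of each factor kind per member block (recycled over
#'   factors). Defaults 0.4 / 0.2 / 0.15.
#' @param noise_sd Standard deviation of the added Gaussian noise. Default 0.3.
#' @param missing_fraction Fraction of cells masked missing, a scalar or a
#'   named per-block vector. Default 0.
#' @param target_block Optional block to flag as target.
#' @param factors Optional explicit factor list overriding
#'   `global`/`local`/`unique`; each element is
#'   `list(kind =, members =, r2 = named numeric per member)`.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_obs = 200L, blocks = c(A = 30L, B = 50L, C = 80L),
                           global = 1L, local = list(c("A", "B")),
                           unique = c(A = 1L, B = 1L, C = 1L),
                           design_r2 = list(global = 0.4, local = 0.2, unique = 0.15),
                           noise_sd = 0.3, missing_fraction = 0,
                           target_block = NULL, factors = NULL, seed = 1L) {
  stopifnot(!is.null(names(blocks)), all(blocks >= 1), noise_sd >= 0,
            all(missing_fraction >= 0), all(missing_fraction < 1))
  nms <- names(blocks)
  if (is.null(factors)) {
    factors <- list()
    for (g in seq_len(global))
      factors[[length(factors) + 1]] <- list(
        kind = "global", members = nms,
        r2 = stats::setNames(rep(design_r2$global, length(nms)), nms))
    for (mem in local) {
      if (length(mem) < 2 || length(mem) >= length(nms))
        stop("local factor member sets must have size >= 2 and < number of blocks")
      if (!all(mem %in% nms)) stop("unknown block in local factor")
      factors[[length(factors) + 1]] <- list(
        kind = "local", members = mem,
        r2 = stats::setNames(rep(design_r2$local, length(mem)), mem))
    }
    for (b in nms)
      for (u in seq_len(if (b %in% names(unique)) unique[[b]] else 0L))
        factors[[length(factors) + 1]] <- list(
          kind = "unique", members = b,
          r2 = stats::setNames(design_r2$unique, b))
  }
  for (i in seq_along(factors))
    factors[[i]]$name <- sprintf("%s%d", substr(factors[[i]]$kind, 1, 1), i)
  per_block_r2 <- vapply(nms, function(b)
    sum(vapply(factors, function(f)
      if (b %in% f$members) f$r2[[b]] else 0, 0)), 0)
  if (any(per_block_r2 >= 1))
    stop("design variance fractions sum to >= 1 for block(s): ",
         paste(nms[per_block_r2 >= 1], collapse = ", "))
  structure(list(n_obs = as.integer(n_obs), blocks = blocks, factors = factors,
                 noise_sd = noise_sd, missing_fraction = missing_fraction,
                 target_block = target_block, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic multiblock dataset
#'
#' Latent factor scores are drawn as Gaussian vectors, orthogonalized
#' (Gram-Schmidt via QR) and scaled to unit variance. Each block is the sum
#' of its member factors times fixed unit-norm random loading vectors, with
#' amplitudes chosen so each factor's expected variance share equals its
#' design fraction, plus i.i.d. Gaussian noise; cells are then masked
#' missing uniformly at random. Everything is deterministic given
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `data` (a raw [multiblock()]) and `truth` (class
#'   `"synthetic_truth"`: `latents` - n x L matrix of factor scores -,
#'   `factors` - kind and members per factor -, `design_r2` and
#'   `realized_r2` - per factor, named by member block).
#' @examples
#' sim <- generate_multiblock(synthetic_spec(n_obs = 50,
#'   blocks = c(x = 5, y = 6), local = list(), unique = c(x = 0, y = 0),
#'   noise_sd = 0.1, seed = 7))
#' sim$data
#' @export
generate_multiblock <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  n <- spec$n_obs
  L <- length(spec$factors)
  if (L > n) stop("more latent factors than observations")
  Z <- qr.Q(qr(matrix(stats::rnorm(n * L), n, L)))
  Z <- sweep(Z, 2, apply(Z, 2, stats::sd), "/")
  colnames(Z) <- vapply(spec$factors, `[[`, "", "name")
  obs_ids <- sprintf("obs%04d", seq_len(n))
  miss <- spec$missing_fraction
  if (length(miss) == 1 && is.null(names(miss)))
    miss <- stats::setNames(rep(miss, length(spec$blocks)), names(spec$blocks))
  blocks <- list()
  realized <- lapply(spec$factors, function(f) stats::setNames(
    rep(NA_real_, length(f$members)), f$members))
  for (b in names(spec$blocks)) {
    p <- spec$blocks[[b]]
    members <- which(vapply(spec$factors, function(f) b %in% f$members, TRUE))
    if (length(members) > min(n, p))
      stop("block '", b, "': more latent factors than min(n_obs, n_vars)")
    r2s <- vapply(members, function(i) spec$factors[[i]]$r2[[b]], 0)
    X <- matrix(0, n, p)
    contribs <- list()
    if (length(members)) {
      if (spec$noise_sd > 0) {
        amp2 <- r2s * p * spec$noise_sd^2 / (1 - sum(r2s))
      } else {
        amp2 <- r2s / sum(r2s)
      }
      for (k in seq_along(members)) {
        v <- stats::rnorm(p)
        v <- v / sqrt(sum(v^2))
        C <- sqrt(amp2[k]) * Z[, members[k]] %*% t(v)
        contribs[[k]] <- C
        X <- X + C
      }
    }
    if (spec$noise_sd > 0)
      X <- X + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    mb <- if (b %in% names(miss)) miss[[b]] else 0
    if (mb > 0) {
      mask <- matrix(stats::runif(n * p) < mb, n, p)
      ## keep at least 2 observed cells per column
      for (j in which(colSums(!mask) < 2)) mask[1:2, j] <- FALSE
      X[mask] <- NA
    }
    totss <- sum((X - rep(colMeans(X, na.rm = TRUE), each = n))^2, na.rm = TRUE)
    for (k in seq_along(members))
      realized[[members[k]]][b] <- sum(contribs[[k]]^2) / max(totss, 1e-300)
    blocks[[b]] <- block_matrix(X, name = b,
                                var_names = sprintf("%s_v%03d", b, seq_len(p)),
                                obs_ids = obs_ids)
  }
  truth <- structure(list(
    latents = Z,
    factors = lapply(spec$factors, function(f) f[c("name", "kind", "members")]),
    design_r2 = lapply(spec$factors, `[[`, "r2"),
    realized_r2 = realized
  ), class = "synthetic_truth")
  list(data = multiblock(blocks, target = spec$target_block), truth = truth)
}

#' A pesticide-project-like synthetic fixture
#'
#' Emulates the structure of a QSAR project dataset: five descriptor-like
#' blocks plus a small 7-variable biological-endpoint target block with
#' about 30% missing cells (ecotoxicological endpoint tables typically have
#' 10-50% missing per endpoint). Planted structure: one large global factor
#' (size-like, loading on all blocks and strongly on the target), one local
#' factor across the descriptor blocks excluding the target, and two small
#' factors joining the target with subsets of descriptor blocks; the target
#' has no unique factor.
#'
#' @param seed Integer seed.
#' @return As [generate_multiblock()]: list with `data` and `truth`.
#' @export
pesticide_like_fixture <- function(seed = 1L) {
  blocks <- c(RDK = 70L, DRG = 120L, PDL = 90L, CDD = 100L, QM = 40L, bio = 7L)
  desc <- setdiff(names(blocks), "bio")
  factors <- list(
    list(kind = "global", members = names(blocks),
         r2 = c(RDK = 0.3, DRG = 0.3, PDL = 0.3, CDD = 0.3, QM = 0.3, bio = 0.5)),
    list(kind = "local", members = desc,
         r2 = stats::setNames(rep(0.2, 5), desc)),
    list(kind = "local", members = c("bio", "CDD", "PDL"),
         r2 = c(bio = 0.17, CDD = 0.03, PDL = 0.03)),
    list(kind = "local", members = c("bio", "CDD", "DRG"),
         r2 = c(bio = 0.09, CDD = 0.03, DRG = 0.03))
  )
  for (b in desc)
    factors[[length(factors) + 1]] <- list(kind = "unique", members = b,
                                           r2 = stats::setNames(0.1, b))
  spec <- synthetic_spec(
    n_obs = 300L, blocks = blocks, factors = factors, noise_sd = 0.3,
    missing_fraction = c(RDK = 0, DRG = 0, PDL = 0, CDD = 0, QM = 0, bio = 0.3),
    target_block = "bio", seed = seed)
  generate_multiblock(spec)
}

#' Match fitted components to planted factors
#'
#' Greedy one-to-one matching of planted latent factors to fitted
#' components by absolute correlation between the planted factor scores and
#' the fitted component scores (the consensus score for joint components,
#' the block score for unique ones), reporting for each planted factor the
#' best match, the correlation and whether kind and block membership agree.
#'
#' @param model A fitted [moca()] model.
#' @param truth The `truth` element returned by [generate_multiblock()].
#' @return A data frame with one row per planted factor: `factor`,
#'   `kind_planted`, `members_planted`, `component` (fitted index, `NA` if
#'   unmatched), `kind_fitted`, `cor`, `kind_match`, `membership_match`.
#' @export
recovery_report <- function(model, truth) {
  stopifnot(inherits(model, "moca"), inherits(truth, "synthetic_truth"))
  comp_scores <- lapply(model$components, function(cmp)
    if (!is.null(cmp$consensus)) cmp$consensus else cmp$scores[[1]])
  L <- ncol(truth$latents)
  K <- length(comp_scores)
  cmat <- matrix(0, L, K)
  for (l in seq_len(L)) for (k in seq_len(K))
    cmat[l, k] <- abs(stats::cor(truth$latents[, l], comp_scores[[k]]))
  match_comp <- rep(NA_integer_, L)
  taken <- rep(FALSE, K)
  if (K > 0) {
    ord <- order(-cmat)
    for (idx in ord) {
      l <- (idx - 1) %% L + 1
      k <- (idx - 1) %/% L + 1
      if (is.na(match_comp[l]) && !taken[k]) {
        match_comp[l] <- k
        taken[k] <- TRUE
      }
      if (all(!is.na(match_comp)) || all(taken)) break
    }
  }
  out <- data.frame(
    factor = vapply(truth$factors, `[[`, "", "name"),
    kind_planted = vapply(truth$factors, `[[`, "", "kind"),
    members_planted = vapply(truth$factors, function(f)
      paste(sort(f$members), collapse = "+"), ""),
    component = NA_integer_, kind_fitted = NA_character_, cor = NA_real_,
    kind_match = FALSE, membership_match = FALSE
  )
  for (l in seq_len(L)) {
    k <- match_comp[l]
    if (is.na(k)) {
      if (K > 0 && any(!taken)) out$cor[l] <- max(cmat[l, !taken])
      next
    }
    cmp <- model$components[[k]]
    out$component[l] <- cmp$index
    out$kind_fitted[l] <- cmp$kind
    out$cor[l] <- cmat[l, k]
    out$kind_match[l] <- identical(cmp$kind, out$kind_planted[l])
    out$membership_match[l] <- identical(paste(sort(cmp$blocks), collapse = "+"),
                                         out$members_planted[l])
  }
  out
}
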
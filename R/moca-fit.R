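#' Options controlling the multiblock decomposition
#'
#' @param strictness Strictness of the joint/unique split, in `[-1, 0)`.
#'   The closer to 0 the stricter: a candidate joint component is accepted
#'   only if member-block score vectors correlate (in absolute value) at
#'   least `1 + strictness`, so `-0.01` demands |r| >= 0.99 while `-0.5`
#'   accepts |r| >= 0.5. Default `-0.03`.
#' @param sv_threshold Retention threshold for pairwise joint components,
#'   see [fit_pairwise_joint()]. Default 0.02.
#' @param compress_r2 Cumulative explained-variance threshold used when
#'   compressing a block's pairwise score vectors into its joint basis.
#'   Default 0.999: the correlation gate of [fit_pairwise_joint()] already
#'   keeps spurious directions out of the collected scores, so the
#'   compression only needs to deduplicate near-copies of the same latent
#'   direction, and a tight threshold preserves weak but genuinely shared
#'   components (small target-block components can carry only about 1% of
#'   a large descriptor block's collected variance).
#' @param unique_r2 Minimum fraction of a block's total observed sum of
#'   squares a unique component must explain to be kept. Default 0.02.
#' @param max_rank Cap on joint components per block pair; `NULL`
#'   (default) leaves the pairwise rank uncapped.
#' @param max_unique Cap on unique components per block. Default 20.
#' @param min_local Minimum number of member blocks for a (locally) joint
#'   component; fixed at 2.
#' @param tol,max_iter NIPALS convergence controls.
#' @return A list of class `"moca_options"`.
#' @export
moca_options <- function(strictness = -0.03, sv_threshold = 0.02,
                         compress_r2 = 0.999, unique_r2 = 0.02,
                         max_rank = NULL, max_unique = 20L, min_local = 2L,
                         tol = 1e-9, max_iter = 500L) {
  .check_strictness(strictness)
  if (min_local != 2L) stop("min_local is fixed at 2")
  structure(list(strictness = strictness, sv_threshold = sv_threshold,
                 compress_r2 = compress_r2, unique_r2 = unique_r2,
                 max_rank = if (!is.null(max_rank)) as.integer(max_rank),
                 max_unique = as.integer(max_unique), min_local = 2L,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "moca_options")
}

.check_strictness <- function(s) {
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s >= 0 || s < -1)
    stop("strictness must lie in [-1, 0)")
  invisible(s)
}

## deflate residual R (mask W) by one score vector v via observed-cell
## regression of every column on v; returns loading and updated residual
.deflate_vector <- function(R, W, v) {
  den <- crossprod(W, v^2)
  den[den == 0] <- 1
  beta <- drop(crossprod(R, v) / den)
  list(R = R - (v %*% t(beta)) * W, loading = beta)
}

#' Compress a block's pairwise score vectors into its joint basis
#'
#' Gathers the block's score vectors from every pairwise joint set it is
#' involved in, then uses PCA (SVD) to keep only the smallest orthonormal
#' basis reaching `r2_threshold` cumulative explained variance. The basis
#' spans the block's joint information.
#'
#' @param block_name Name of the block.
#' @param pairwise_sets List of [fit_pairwise_joint()] results (sets not
#'   involving the block are ignored).
#' @param r2_threshold Cumulative explained-variance cut-off. Default 0.999.
#' @return An n x k matrix with orthonormal columns; k = 0 when the block
#'   shares no joint components with any partner (the block is all-unique).
#' @export
collect_and_compress <- function(block_name, pairwise_sets, r2_threshold = 0.999) {
  cols <- list()
  for (ps in pairwise_sets) {
    if (!inherits(ps, "pairwise_joint")) next
    if (ps$n_joint == 0) next
    if (ps$block_a == block_name) cols <- c(cols, list(ps$scores_a))
    else if (ps$block_b == block_name) cols <- c(cols, list(ps$scores_b))
  }
  if (!length(cols)) return(matrix(0, 0, 0))
  S <- do.call(cbind, cols)
  sv <- svd(S)
  pos <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(pos) >= r2_threshold)[1]
  if (is.na(k)) k <- length(pos)
  k <- min(k, sum(sv$d > sv$d[1] * 1e-8))
  B <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                  # deterministic sign
    s <- sign(B[which.max(abs(B[, j])), j])
    if (s < 0) B[, j] <- -B[, j]
  }
  B
}

#' Split a block into its joint part and a residual
#'
#' Projects the block onto its joint score basis: loadings are observed-cell
#' regressions of each variable on the basis vectors, the joint part is the
#' reconstruction `basis %*% loadings`, and the residual is the remainder
#' with missing cells forced to zero residual.
#'
#' @param block Preprocessed [block_matrix()] or centered matrix.
#' @param basis n x k orthonormal score basis (possibly k = 0).
#' @return List with `joint` (n x p), `residual` (n x p, 0 at missing cells)
#'   and `loadings` (k x p).
#' @export
split_joint_unique <- function(block, basis) {
  xw <- .xw(block)
  R <- xw$x; W <- xw$w
  k <- if (length(basis)) ncol(basis) else 0L
  loadings <- matrix(0, k, ncol(R))
  for (j in seq_len(k)) {
    d <- .deflate_vector(R, W, basis[, j])
    loadings[j, ] <- d$loading
    R <- d$R
  }
  list(joint = xw$x - R, residual = R, loadings = loadings)
}

#' Extract unique components from a residual block
#'
#' Runs NIPALS PCA on the residual left after the joint part of a block is
#' removed. A component is kept only if it explains at least `r2_threshold`
#' of the *original* block's observed sum of squares AND exceeds the noise
#' floor: the sum of squares the leading principal component of an
#' i.i.d.-noise matrix of the same size would capture (the Marchenko-Pastur
#' edge, `(sqrt(n) + sqrt(p))^2 / (n p)` of the current residual), times a
#' small safety factor. Without the floor, small residual blocks would
#' always emit "unique" components - the top noise eigenvalue of a 7-column
#' residual carries about 20% of its variance - which real data analyses
#' of small endpoint blocks contradict.
#'
#' @param residual n x p residual matrix (zeros at missing cells).
#' @param mask 0/1 observed-cell matrix matching `residual` (1 = observed);
#'   defaults to all observed.
#' @param orig_ss Total observed sum of squares of the original centered
#'   block; defaults to `sum(residual^2)`.
#' @param r2_threshold Minimum explained fraction per component. Default 0.02.
#' @param noise_factor Safety factor on the noise floor. Default 1.05.
#' @param max_components Extraction cap. Default 20.
#' @param tol,max_iter NIPALS convergence controls.
#' @return List with `scores` (n x m, unit-norm columns), `loadings`
#'   (p x m), `r2` (relative to `orig_ss`) and `residual`.
#' @export
extract_unique <- function(residual, mask = NULL, orig_ss = NULL,
                           r2_threshold = 0.02, noise_factor = 1.05,
                           max_components = 20L,
                           tol = 1e-9, max_iter = 500L) {
  R <- as.matrix(residual)
  W <- if (is.null(mask)) matrix(1, nrow(R), ncol(R)) else mask
  if (is.null(orig_ss)) orig_ss <- sum(R^2)
  p <- ncol(R)
  n_eff <- mean(colSums(W))
  edge_frac <- (sqrt(n_eff) + sqrt(p))^2 / (n_eff * p)
  scores <- matrix(0, nrow(R), 0)
  loadings <- matrix(0, ncol(R), 0)
  r2 <- numeric(0)
  while (ncol(scores) < max_components) {
    ss_cur <- sum(R^2)
    comp <- .nipals_component(R, W, tol, max_iter)
    if (is.null(comp)) break
    Rnew <- R - (comp$t %*% t(comp$p)) * W
    drop_ss <- ss_cur - sum(Rnew^2)
    drop_frac <- drop_ss / orig_ss
    if (drop_frac < r2_threshold) break
    if (drop_ss < noise_factor * edge_frac * ss_cur) break
    R <- Rnew
    nrm <- max(sqrt(sum(comp$t^2)), .Machine$double.eps)
    scores <- cbind(scores, comp$t / nrm)
    loadings <- cbind(loadings, comp$p * nrm)   # unit-norm score convention
    r2 <- c(r2, drop_frac)
  }
  list(scores = scores, loadings = loadings, r2 = r2, residual = R)
}

#' Classify joint bases into globally and locally joint components
#'
#' Iteratively extracts consensus directions across all blocks' joint bases.
#' Each round starts from the leading principal direction of the pooled
#' remaining basis vectors as the candidate consensus score. Every block
#' then contributes its best-matching direction *within the span* of its
#' remaining joint basis (the normalized projection of the consensus onto
#' the span; the compression step fixes only the subspace, not the
#' orientation of individual basis vectors, so matching must be
#' rotation-invariant). Consensus and matched directions are re-estimated
#' until stable over the blocks passing a fixed internal relevance gate
#' (`|r| >= 0.5`, or `1 + strictness` if smaller), and every gated block's
#' matched direction is then deflated from its basis, so the candidate
#' components and per-block variance splits do not depend on the strictness
#' setting. Strictness only controls the labeling: blocks whose matched
#' direction correlates with the consensus at `|r| >= 1 + strictness`
#' become members; a candidate is globally joint when all blocks join,
#' locally joint with 2 or more members, and the directions of gated
#' non-member blocks (or of a candidate carried by fewer than 2 blocks) are
#' routed to the blocks' unique pools. Relaxing strictness can therefore
#' only add members to a candidate, which makes the per-block joint
#' explained variance non-decreasing as strictness is relaxed. The
#' strictness test is always against the consensus (final loading) vector,
#' so pairwise member correlations can fall somewhat below `1 + strictness`
#' for heterogeneous members.
#'
#' @param bases Named list (one entry per block) of n x k orthonormal basis
#'   matrices from [collect_and_compress()].
#' @param strictness Strictness parameter in `[-1, 0)`; see [moca_options()].
#' @return List with `components` (each: `blocks`, `vectors` - named list of
#'   member score vectors -, `kind` and `consensus_cor`) and `rejected`
#'   (named list of n x m matrices of basis directions routed to the unique
#'   pools).
#' @export
classify_joint <- function(bases, strictness) {
  .check_strictness(strictness)
  thr <- 1 + strictness
  gate <- min(thr, 0.5)
  block_names <- names(bases)
  n_blocks <- length(bases)
  pools <- lapply(bases, function(b) if (length(b)) b else matrix(0, 0, 0))
  rejected <- lapply(bases, function(b) NULL)
  ## best-matching unit direction within a block's joint span
  project <- function(B, c1) {
    v <- drop(B %*% crossprod(B, c1))
    nrm <- sqrt(sum(v^2))
    if (nrm < 1e-12) return(NULL)
    v / nrm
  }
  ## remove direction v from the span of B (orthonormal deflation)
  deflate_basis <- function(B, v) {
    Bn <- B - v %*% crossprod(v, B)
    sv <- svd(Bn)
    keep <- sv$d > 1e-8
    sv$u[, keep, drop = FALSE]
  }
  comps <- list()
  repeat {
    sizes <- vapply(pools, function(m) if (length(m)) ncol(m) else 0L, 0L)
    if (sum(sizes) == 0) break
    S <- do.call(cbind, pools[sizes > 0])
    c1 <- svd(S)$u[, 1]
    ## refine consensus and matched directions over the gated blocks
    vecs <- NULL; cors <- NULL
    for (it in 1:25) {
      vecs <- lapply(pools, function(B)
        if (length(B) && ncol(B)) project(B, c1) else NULL)
      cors <- vapply(seq_len(n_blocks), function(i)
        if (is.null(vecs[[i]])) NA_real_
        else abs(stats::cor(vecs[[i]], c1)), 0)
      active <- which(!is.na(cors) & cors >= gate)
      if (length(active) < 2) break
      M <- vapply(active, function(i) {
        v <- vecs[[i]]
        if (sum(v * c1) < 0) -v else v
      }, numeric(length(c1)))
      c_new <- svd(M)$u[, 1]
      if (sum(c_new * c1) < 0) c_new <- -c_new
      if (abs(sum(c_new * c1)) > 1 - 1e-12) { c1 <- c_new; break }
      c1 <- c_new
    }
    active <- which(!is.na(cors) & cors >= gate)
    if (length(active) >= 2) {
      ## membership statistic: correlation with the refined consensus (the
      ## final loading vector). The consensus is estimated over the gated
      ## active set, not the member set, so the statistic does not depend
      ## on the strictness setting and relaxing strictness can only add
      ## members. Spurious directions cannot exploit the self-inflation of
      ## this statistic because the pairwise correlation gate already keeps
      ## them out of the bases.
      members <- active[cors[active] >= thr]
      if (length(members) >= 2) {
        mvecs <- vecs[members]
        names(mvecs) <- block_names[members]
        kind <- if (length(members) == n_blocks) "global" else "local"
        comps[[length(comps) + 1]] <- list(
          blocks = block_names[members], vectors = mvecs, kind = kind,
          consensus_cor = stats::setNames(cors[members], block_names[members]))
      }
      for (i in active) {
        if (!(length(members) >= 2 && i %in% members))
          rejected[[block_names[i]]] <- cbind(rejected[[block_names[i]]],
                                              vecs[[i]])
        pools[[i]] <- deflate_basis(pools[[i]], vecs[[i]])
      }
      next
    }
    ## no viable candidate: discard the direction most aligned with the
    ## candidate consensus to its block's unique pool (guarantees progress)
    i <- which.max(cors)
    v <- vecs[[i]]
    rejected[[block_names[i]]] <- cbind(rejected[[block_names[i]]], v)
    pools[[i]] <- deflate_basis(pools[[i]], v)
  }
  list(components = comps, rejected = rejected)
}

#' Consensus score and per-observation disagreement of a joint component
#'
#' Member score vectors are scaled to unit variance and sign-aligned to the
#' first member; the consensus is their element-wise mean and the
#' disagreement of observation i is the root-mean-square deviation of the
#' member scores from the consensus at i. Zero disagreement everywhere means
#' the blocks describe the observations identically on this component.
#'
#' @param scores A joint component (list with element `scores`) or a list of
#'   member score vectors.
#' @return List with `consensus` and `disagreement` (both length n,
#'   `disagreement >= 0`).
#' @export
consensus_and_disagreement <- function(scores) {
  if (is.list(scores) && !is.null(scores$scores)) scores <- scores$scores
  stopifnot(is.list(scores), length(scores) >= 1)
  M <- vapply(scores, function(s) s / stats::sd(s), numeric(length(scores[[1]])))
  if (ncol(M) > 1)
    for (j in 2:ncol(M))
      if (stats::cor(M[, j], M[, 1]) < 0) M[, j] <- -M[, j]
  consensus <- rowMeans(M)
  disagreement <- sqrt(rowMeans((M - consensus)^2))
  list(consensus = consensus, disagreement = disagreement)
}

## steps 1-2: pairwise models for all block pairs, then per-block joint bases
.moca_steps <- function(data, options) {
  nms <- names(data)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  psets <- lapply(pairs, function(pr)
    fit_pairwise_joint(data[[pr[1]]], data[[pr[2]]],
                       sv_threshold = options$sv_threshold,
                       max_rank = options$max_rank))
  bases <- lapply(nms, function(b)
    collect_and_compress(b, psets, r2_threshold = options$compress_r2))
  names(bases) <- nms
  list(pairwise = psets, bases = bases)
}

## steps 3-5 for one strictness value: classify, account variance, assemble
.moca_finalize <- function(data, steps, options) {
  nms <- names(data)
  cls <- classify_joint(steps$bases, options$strictness)
  n_joint <- length(cls$components)

  ## per-block variance accounting by sequential deflation
  acc <- list()
  for (b in nms) {
    xw <- .xw(data[[b]])
    R <- xw$x; W <- xw$w
    ss0 <- sum(R^2)
    if (ss0 <= 0) stop("block '", b, "' has zero variance")
    joint_r2 <- numeric(0); joint_load <- list()
    for (ci in seq_len(n_joint)) {
      comp <- cls$components[[ci]]
      pos <- match(b, comp$blocks)
      if (is.na(pos)) { joint_r2 <- c(joint_r2, NA_real_); joint_load <- c(joint_load, list(NULL)); next }
      ss_before <- sum(R^2)
      d <- .deflate_vector(R, W, comp$vectors[[pos]])
      R <- d$R
      joint_r2 <- c(joint_r2, (ss_before - sum(R^2)) / ss0)
      joint_load <- c(joint_load, list(d$loading))
    }
    ## variance along rejected basis directions stays in the residual, so
    ## the unique extraction below sees each unique factor in one piece
    uniq_scores <- list(); uniq_load <- list(); uniq_r2 <- numeric(0)
    ## systematic unique structure via NIPALS on the residual
    ex <- extract_unique(R, W, orig_ss = ss0, r2_threshold = options$unique_r2,
                         max_components = options$max_unique,
                         tol = options$tol, max_iter = options$max_iter)
    for (m in seq_along(ex$r2)) {
      uniq_scores <- c(uniq_scores, list(drop(ex$scores[, m])))
      uniq_load <- c(uniq_load, list(drop(ex$loadings[, m])))
    }
    if (length(ex$r2)) {
      uniq_r2 <- c(uniq_r2, ex$r2)
      R <- ex$residual
    }
    acc[[b]] <- list(ss0 = ss0, joint_r2 = joint_r2, joint_load = joint_load,
                     uniq_scores = uniq_scores, uniq_load = uniq_load,
                     uniq_r2 = uniq_r2, residual = R,
                     r2_residual = sum(R^2) / ss0)
  }

  ## assemble components: global then local (each by decreasing mean R2),
  ## then unique per block in input order (by decreasing R2 within block)
  comp_list <- list()
  if (n_joint) {
    mean_r2 <- vapply(seq_len(n_joint), function(ci) {
      comp <- cls$components[[ci]]
      mean(vapply(comp$blocks, function(b) acc[[b]]$joint_r2[ci], 0))
    }, 0)
    kinds <- vapply(cls$components, `[[`, "", "kind")
    ord <- c(order(-mean_r2)[kinds[order(-mean_r2)] == "global"],
             order(-mean_r2)[kinds[order(-mean_r2)] == "local"])
    for (ci in ord) {
      comp <- cls$components[[ci]]
      r2v <- vapply(comp$blocks, function(b) acc[[b]]$joint_r2[ci], 0)
      loads <- lapply(comp$blocks, function(b) acc[[b]]$joint_load[[ci]])
      names(loads) <- comp$blocks
      cd <- consensus_and_disagreement(comp$vectors)
      comp_list[[length(comp_list) + 1]] <- list(
        kind = comp$kind, blocks = comp$blocks, scores = comp$vectors,
        loadings = loads, r2 = r2v, consensus = cd$consensus,
        disagreement = cd$disagreement, consensus_cor = comp$consensus_cor)
    }
  }
  for (b in nms) {
    a <- acc[[b]]
    if (!length(a$uniq_r2)) next
    for (m in order(-a$uniq_r2)) {
      sc <- list(a$uniq_scores[[m]]); names(sc) <- b
      ld <- list(a$uniq_load[[m]]); names(ld) <- b
      r2v <- a$uniq_r2[m]; names(r2v) <- b
      comp_list[[length(comp_list) + 1]] <- list(
        kind = "unique", blocks = b, scores = sc, loadings = ld, r2 = r2v,
        consensus = NULL, disagreement = NULL)
    }
  }
  for (i in seq_along(comp_list)) comp_list[[i]]$index <- i

  r2xj <- vapply(nms, function(b) sum(acc[[b]]$joint_r2, na.rm = TRUE), 0)
  r2xu <- vapply(nms, function(b) sum(acc[[b]]$uniq_r2), 0)
  r2res <- vapply(nms, function(b) acc[[b]]$r2_residual, 0)
  structure(list(
    components = comp_list,
    r2xj = r2xj, r2xu = r2xu, r2_residual = r2res,
    options = options, block_names = nms,
    n_obs = length(attr(data, "obs_ids")), obs_ids = attr(data, "obs_ids"),
    var_names = lapply(data, `[[`, "var_names"),
    target = attr(data, "target"),
    residuals = lapply(acc, `[[`, "residual"),
    pairwise = steps$pairwise
  ), class = "moca")
}

#' Fit a multiblock orthogonal component decomposition
#'
#' Decomposes two or more blocks of variables sharing one observation set
#' into globally joint components (systematic structure present in all
#' blocks), locally joint components (present in a strict subset of at least
#' two blocks) and unique components (one block only), plus an unmodelled
#' residual per block. The algorithm proceeds in five steps: (1) pairwise
#' joint-component estimation for every block pair with equal block
#' weighting, (2) per-block compression of the pairwise score vectors into a
#' joint basis, (3) splitting each block into its joint part and a residual,
#' (4) extraction of unique components from the residuals, and (5)
#' classification of the joint bases into global and local components under
#' the strictness parameter.
#'
#' Raw blocks are mean-centered and scaled to unit variance automatically;
#' preprocessed blocks are used as-is.
#'
#' @param data A [multiblock()] object with at least two blocks.
#' @param strictness Optional override of `options$strictness`.
#' @param options A [moca_options()] list.
#' @return An object of class `"moca"` with elements `components` (each has
#'   `index`, `kind`, `blocks`, per-member `scores`/`loadings`/`r2`, and for
#'   joint components `consensus` and `disagreement`), `r2xj`, `r2xu`,
#'   `r2_residual` (per block; the three always sum to 1), `residuals`,
#'   `options`, `block_names`, `n_obs`, `obs_ids`.
#' @examples
#' sim <- generate_multiblock(synthetic_spec(seed = 1))
#' fit <- moca(sim$data, strictness = -0.2)
#' fit
#' summary(fit)
#' @export
moca <- function(data, strictness = NULL, options = moca_options()) {
  stopifnot(inherits(data, "multiblock"))
  if (length(data) < 2) stop("at least 2 blocks are required")
  if (!is.null(strictness)) {
    .check_strictness(strictness)
    options$strictness <- strictness
  }
  raw <- vapply(data, function(b) b$preprocessing == "raw", TRUE)
  if (any(raw)) {
    for (i in which(raw)) data[[i]] <- center_scale(data[[i]])
  }
  for (b in data)
    if (sum(b$values^2, na.rm = TRUE) <= 0)
      stop("block '", b$name, "' has zero variance")
  steps <- .moca_steps(data, options)
  .moca_finalize(data, steps, options)
}

#' Sweep the strictness parameter of a multiblock decomposition
#'
#' Refits the joint/unique classification for each strictness value (the
#' pairwise and compression steps do not depend on strictness and are
#' computed once), collects the per-block joint explained variance (R2Xj)
#' into a conditions-by-blocks table, and summarizes that table with a
#' mean-center-only PCA. A systematic first component of this meta-PCA
#' indicates that relaxing the strictness grows the joint fraction in a
#' coordinated way across blocks.
#'
#' @param data A [multiblock()] object.
#' @param strictness_values Numeric vector of strictness settings.
#' @param options A [moca_options()] list.
#' @return List of class `"moca_sweep"` with `table` (R2Xj matrix, one row
#'   per strictness), `pca` (a [nipals_pca()] fit of the mean-centered table,
#'   `NULL` with a warning if fewer than 2 rows) and `strictness_values`.
#' @export
strictness_sweep <- function(data, strictness_values, options = moca_options()) {
  stopifnot(inherits(data, "multiblock"), length(strictness_values) >= 1)
  for (s in strictness_values) .check_strictness(s)
  raw <- vapply(data, function(b) b$preprocessing == "raw", TRUE)
  for (i in which(raw)) data[[i]] <- center_scale(data[[i]])
  steps <- .moca_steps(data, options)
  tab <- t(vapply(strictness_values, function(s) {
    opt <- options; opt$strictness <- s
    .moca_finalize(data, steps, opt)$r2xj
  }, numeric(length(data))))
  dimnames(tab) <- list(sprintf("%g", strictness_values), names(data))
  pca <- NULL
  if (nrow(tab) < 2) {
    warning("single strictness value: meta-PCA skipped")
  } else if (sum(sweep(tab, 2, colMeans(tab), "-")^2) < 1e-20) {
    warning("R2Xj table is constant across strictness values: meta-PCA skipped")
  } else {
    pca <- r2xj_table_pca(tab)
  }
  structure(list(table = tab, pca = pca, strictness_values = strictness_values),
            class = "moca_sweep")
}

#' Mean-center-only PCA of an R2Xj table
#'
#' Utility behind [strictness_sweep()], also usable on an externally
#' assembled conditions-by-blocks table of joint-variance fractions. Columns
#' are mean-centered but not scaled (the values share the 0-1 scale and a
#' common mechanism), then a NIPALS PCA is fitted.
#'
#' @param table Numeric matrix, rows = conditions, columns = blocks.
#' @param n_components Number of components; default extracts until 99%
#'   cumulative explained variance.
#' @return A [nipals_pca()] object.
#' @export
r2xj_table_pca <- function(table, n_components = NULL) {
  tab <- as.matrix(table)
  ctr <- sweep(tab, 2, colMeans(tab), "-")
  nipals_pca(ctr, n_components = n_components, cum_r2 = 0.99)
}

#' @export
print.moca_sweep <- function(x, ...) {
  cat("Strictness sweep over", nrow(x$table), "settings,",
      ncol(x$table), "blocks\n")
  print(round(x$table, 3))
  if (!is.null(x$pca))
    cat(sprintf("Meta-PCA: first component explains %.1f%% of the R2Xj table\n",
                100 * x$pca$r2[1]))
  invisible(x)
}
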
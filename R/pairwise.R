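#' Pairwise joint-component estimation for two blocks
#'
#' First step of the multiblock decomposition: for one pair of blocks, decide
#' how many latent directions they share and return paired score vectors.
#' Each block is first scaled to unit total (observed) sum of squares so that
#' blocks enter with equal weight regardless of their size, then the
#' cross-product matrix `Xa' Xb` is decomposed by SVD. Because of the
#' norm-equalization its trace norm is at most 1, so each singular value is
#' directly the fraction of the maximum attainable shared covariance; a
#' component is retained when that fraction exceeds `sv_threshold`. Under
#' independence the largest singular value shrinks as `O(1/sqrt(n))`, so the
#' rule returns zero joint components for unrelated blocks of reasonable
#' size.
#'
#' @param xa,xb Preprocessed [block_matrix()] objects (or centered matrices)
#'   with identical observation sets.
#' @param sv_threshold Retention threshold on the singular value of the
#'   norm-equalized cross-product matrix. Default 0.02.
#' @param cor_gate Minimum absolute correlation between the paired score
#'   vectors for a component to be retained. Overfit cross-covariance
#'   directions of unrelated variables show paired correlations well below
#'   0.5 at reasonable sample sizes, while genuinely shared latent
#'   structure correlates far above it, so this gate keeps spurious
#'   directions out of the joint bases. Default 0.5 (the same relevance
#'   gate used by [classify_joint()]).
#' @param max_rank Cap on the number of joint components per pair;
#'   `NULL` (default) means no cap beyond the rank of the cross-product.
#' @return An object of class `"pairwise_joint"`: `block_a`, `block_b`,
#'   `n_joint`, `scores_a`/`scores_b` (n x k, natural scale: column norms
#'   reflect the covariance each direction carries),
#'   `loadings_a`/`loadings_b`, `sv` (retained singular values),
#'   `correlations` (per-component |Pearson| between the paired scores).
#'   `n_joint = 0` (empty matrices) is a valid result for unrelated blocks.
#' @export
fit_pairwise_joint <- function(xa, xb, sv_threshold = 0.02,
                               cor_gate = 0.5, max_rank = NULL) {
  name_a <- if (inherits(xa, "block_matrix")) xa$name else "a"
  name_b <- if (inherits(xb, "block_matrix")) xb$name else "b"
  aw <- .xw(xa); bw <- .xw(xb)
  n <- nrow(aw$x)
  if (nrow(bw$x) != n) stop("blocks do not share the observation set")
  Xa <- aw$x / sqrt(sum(aw$x^2))
  Xb <- bw$x / sqrt(sum(bw$x^2))
  M <- crossprod(Xa, Xb)
  sv <- svd(M)
  keep <- which(sv$d > sv_threshold)
  if (!is.null(max_rank)) keep <- utils::head(keep, max_rank)
  empty <- function(nr) matrix(0, nr, 0)
  out <- list(block_a = name_a, block_b = name_b, n_joint = 0L,
              scores_a = empty(n), scores_b = empty(n),
              loadings_a = empty(ncol(Xa)), loadings_b = empty(ncol(Xb)),
              sv = numeric(0), correlations = numeric(0))
  if (length(keep)) {
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
    for (k in seq_along(keep)) {       # sign: largest-|loading| element positive
      s <- sign(U[which.max(abs(U[, k])), k])
      if (s < 0) { U[, k] <- -U[, k]; V[, k] <- -V[, k] }
    }
    Ta <- Xa %*% U
    Tb <- Xb %*% V
    cors <- abs(diag(stats::cor(Ta, Tb)))
    ## retained pairs must share actual observation-level structure, not
    ## just cross-covariance picked up by the SVD
    ok <- cors >= cor_gate
    Ta <- Ta[, ok, drop = FALSE]; Tb <- Tb[, ok, drop = FALSE]
    U <- U[, ok, drop = FALSE]; V <- V[, ok, drop = FALSE]
    out$n_joint <- sum(ok)
    ## scores keep their natural scale (norm reflects the covariance the
    ## direction carries), so downstream compression is variance-weighted
    out$scores_a <- Ta; out$scores_b <- Tb
    out$loadings_a <- U; out$loadings_b <- V
    out$sv <- sv$d[keep][ok]
    out$correlations <- cors[ok]
  }
  out$n_joint <- as.integer(out$n_joint)
  class(out) <- "pairwise_joint"
  out
}

#' @export
print.pairwise_joint <- function(x, ...) {
  cat(sprintf("Pairwise joint set %s ~ %s: %d component(s)\n",
              x$block_a, x$block_b, x$n_joint))
  if (x$n_joint)
    print(round(rbind(sv = x$sv, `|corr|` = x$correlations), 4))
  invisible(x)
}
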
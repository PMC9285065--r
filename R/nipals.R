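#' NIPALS principal component analysis with missing values
#'
#' Sequential power-iteration extraction of principal components with
#' deflation. Missing cells are skipped in every inner product, so they have
#' zero residual and no leverage on the estimated scores and loadings; on
#' complete data the result coincides with the singular value decomposition.
#'
#' The model is `X = T P' + E` for a column-centered `X`. Explained variance
#' per component is the drop in observed-cell residual sum of squares divided
#' by the total observed sum of squares of the centered matrix.
#'
#' @param x A centered [block_matrix()] or a numeric matrix already centered
#'   column-wise (`NA` = missing).
#' @param n_components Number of components to extract. If `NULL`, components
#'   are extracted until the cumulative explained variance reaches `cum_r2`
#'   (capped at `min(n_obs, n_vars)`).
#' @param cum_r2 Cumulative explained-variance stop threshold used when
#'   `n_components` is `NULL`. Default 0.95.
#' @param tol Convergence tolerance: relative change of the score vector
#'   between iterations, `||t_new - t_old|| / ||t_new||`. Default `1e-9`.
#' @param max_iter Maximum NIPALS iterations per component. Default 500.
#' @return An object of class `"nipals_pca"` with elements `scores` (n x A),
#'   `loadings` (p x A, unit-norm columns, sign fixed so the largest-|loading|
#'   element is positive), `r2` (per component), `residual` (exactly 0 at
#'   missing cells), `totss`, `n_iterations`, `converged`.
#' @examples
#' x <- scale(matrix(rnorm(50), 10, 5), scale = FALSE)
#' fit <- nipals_pca(x, n_components = 2)
#' fit$r2
#' @export
nipals_pca <- function(x, n_components = NULL, cum_r2 = 0.95,
                       tol = 1e-9, max_iter = 500L) {
  if (inherits(x, "block_matrix") && x$preprocessing == "raw")
    stop("block must be centered before nipals_pca(); see center_scale()")
  xw <- .xw(x)
  X <- xw$x; W <- xw$w
  n <- nrow(X); p <- ncol(X)
  if (any(rowSums(W) == 0)) stop("observation(s) with no observed cells")
  if (any(colSums(W) == 0)) stop("variable(s) with no observed cells")
  kmax <- min(n, p)
  if (!is.null(n_components)) {
    if (n_components > kmax)
      stop("n_components (", n_components, ") exceeds min(n_obs, n_vars) = ", kmax)
    kmax <- n_components
  }
  totss <- sum(X^2)
  if (totss <= 0) stop("matrix has no variance")
  scores <- matrix(0, n, 0)
  loadings <- matrix(0, p, 0)
  r2 <- numeric(0); iters <- integer(0); conv <- logical(0)
  ss_prev <- totss
  for (a in seq_len(kmax)) {
    res <- .nipals_component(X, W, tol, max_iter)
    if (is.null(res)) break
    X <- X - (res$t %*% t(res$p)) * W
    ss_new <- sum(X^2)
    scores <- cbind(scores, res$t)
    loadings <- cbind(loadings, res$p)
    r2 <- c(r2, (ss_prev - ss_new) / totss)
    iters <- c(iters, res$iter)
    conv <- c(conv, res$converged)
    if (!res$converged)
      warning("component ", a, " did not converge in ", max_iter, " iterations")
    ss_prev <- ss_new
    if (is.null(n_components) && sum(r2) >= cum_r2) break
    if (ss_new / totss < 1e-12) break
  }
  rownames(scores) <- rownames(xw$x)
  rownames(loadings) <- colnames(xw$x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, loadings = loadings, r2 = r2,
                 residual = X, totss = totss,
                 means = if (inherits(x, "block_matrix")) x$col_means else NULL,
                 n_iterations = iters, converged = conv),
            class = "nipals_pca")
}

## one NIPALS component on (X, W); returns NULL if X is numerically zero
.nipals_component <- function(X, W, tol, max_iter) {
  cssq <- colSums(X^2)
  if (max(cssq) <= 0) return(NULL)
  t_vec <- X[, which.max(cssq)]
  if (sum(t_vec^2) == 0) t_vec <- rowSums(X)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    den_p <- crossprod(W, t_vec^2)
    den_p[den_p == 0] <- 1
    p_vec <- crossprod(X, t_vec) / den_p
    nrm <- sqrt(sum(p_vec^2))
    if (nrm == 0) return(NULL)
    p_vec <- p_vec / nrm
    den_t <- W %*% p_vec^2
    den_t[den_t == 0] <- 1
    t_new <- (X %*% p_vec) / den_t
    delta <- sqrt(sum((t_new - t_vec)^2)) / max(sqrt(sum(t_new^2)), .Machine$double.eps)
    t_vec <- drop(t_new)
    if (delta <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  p_vec <- drop(p_vec)
  ## sign convention: largest-|loading| element positive
  s <- sign(p_vec[which.max(abs(p_vec))])
  if (s < 0) { p_vec <- -p_vec; t_vec <- -t_vec }
  list(t = t_vec, p = p_vec, iter = iter, converged = converged)
}

#' @export
print.nipals_pca <- function(x, ...) {
  cat(sprintf("NIPALS PCA: %d components, cumulative R2 = %.4f\n",
              ncol(x$scores), sum(x$r2)))
  print(round(rbind(r2 = x$r2, cumulative = cumsum(x$r2)), 4))
  invisible(x)
}

#' Jackknife confidence intervals for PCA loadings
#'
#' Refits the NIPALS PCA once per left-out observation, sign-aligns every
#' refit's loadings to the full-data model, and forms per-variable intervals
#' `loading +/- t-quantile * jackknife standard error`.
#'
#' @inheritParams nipals_pca
#' @param n_components Number of components (required).
#' @param level Confidence level, default 0.95.
#' @return A list with `loadings`, `lower`, `upper`, `se` (all p x A
#'   matrices), `level` and `n_failed` (refits excluded for non-convergence).
#' @export
jackknife_loading_ci <- function(x, n_components, level = 0.95,
                                 tol = 1e-9, max_iter = 500L) {
  xm <- if (inherits(x, "block_matrix")) x$values else as.matrix(x)
  n <- nrow(xm)
  if (n < 3) stop("jackknife requires at least 3 observations")
  ## operate on a column-centered copy; each leave-one-out refit re-centers
  full <- nipals_pca(sweep(xm, 2, colMeans(xm, na.rm = TRUE), "-"),
                     n_components = n_components, tol = tol, max_iter = max_iter)
  p <- nrow(full$loadings); A <- ncol(full$loadings)
  reps <- array(NA_real_, c(p, A, n))
  failed <- 0L
  for (i in seq_len(n)) {
    xi <- xm[-i, , drop = FALSE]
    xi <- sweep(xi, 2, colMeans(xi, na.rm = TRUE), "-")
    fit_i <- tryCatch(
      suppressWarnings(nipals_pca(xi, n_components = n_components,
                                  tol = tol, max_iter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit_i) || !all(fit_i$converged) || ncol(fit_i$loadings) < A) {
      failed <- failed + 1L
      next
    }
    L <- fit_i$loadings
    for (a in seq_len(A))                      # sign-align to the full model
      if (sum(L[, a] * full$loadings[, a]) < 0) L[, a] <- -L[, a]
    reps[, , i] <- L
  }
  if (failed > 0)
    warning(failed, " jackknife refit(s) failed to converge and were excluded")
  m <- n - failed
  if (m < 2) stop("too few successful jackknife refits")
  se <- matrix(0, p, A, dimnames = dimnames(full$loadings))
  for (a in seq_len(A)) {
    La <- reps[, a, ]
    ok <- !apply(is.na(La), 2, any)
    mu <- rowMeans(La[, ok, drop = FALSE])
    se[, a] <- sqrt(((m - 1) / m) * rowSums((La[, ok, drop = FALSE] - mu)^2))
  }
  q <- stats::qt(1 - (1 - level) / 2, df = m - 1)
  list(loadings = full$loadings, lower = full$loadings - q * se,
       upper = full$loadings + q * se, se = se, level = level, n_failed = failed)
}
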
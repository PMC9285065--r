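#' Two-block PLS regression (NIPALS PLS2)
#'
#' Fits `X = T P' + E`, `Y = U C' + F` with the inner relation `U ~ T`
#' (so `Y = T C' + G`), using NIPALS with the same missing-value contract as
#' [nipals_pca()]: missing cells are skipped in all inner products and carry
#' zero residual. Handles a single-column or multi-column `Y`.
#'
#' @param X,Y Preprocessed [block_matrix()] objects (or centered matrices)
#'   sharing observations.
#' @param n_components Number of latent variables.
#' @param cv Logical; compute 7-fold cross-validated `q2` (default `TRUE`).
#' @param cv_folds Number of cross-validation folds (contiguous by
#'   observation order, the deterministic default).
#' @param tol,max_iter NIPALS convergence controls.
#' @return An object of class `"pls_model"`: `x_scores` (T), `x_loadings`
#'   (P), `y_scores` (U), `y_loadings` (C), `weights` (W), `x_residual` (E),
#'   `y_residual` (F), `inner_residual` (G), per-component `r2x`, `r2y`, and
#'   `q2` (cumulative, if `cv`).
#' @export
fit_pls <- function(X, Y, n_components, cv = TRUE, cv_folds = 7L,
                    tol = 1e-9, max_iter = 500L) {
  xw <- .xw(X); yw <- .xw(Y)
  n <- nrow(xw$x)
  stopifnot(nrow(yw$x) == n)
  if (n_components > min(n, ncol(xw$x)))
    stop("n_components exceeds the rank bound min(n_obs, n_x_vars)")
  core <- .pls_core(xw$x, xw$w, yw$x, yw$w, n_components, tol, max_iter)
  q2 <- NULL
  if (cv) q2 <- .pls_q2(xw, yw, n_components, cv_folds, tol, max_iter)
  structure(c(core, list(q2 = q2, n_components = n_components)),
            class = "pls_model")
}

.pls_core <- function(X, Wx, Y, Wy, A, tol, max_iter) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  ssx <- sum(X^2); ssy <- sum(Y^2)
  T_ <- matrix(0, n, 0); U_ <- matrix(0, n, 0)
  P_ <- matrix(0, p, 0); C_ <- matrix(0, q, 0); W_ <- matrix(0, p, 0)
  r2x <- r2y <- numeric(0)
  for (a in seq_len(A)) {
    u <- Y[, which.max(colSums(Y^2))]
    if (sum(u^2) == 0) break
    t_vec <- u
    repeat_count <- 0L
    repeat {
      repeat_count <- repeat_count + 1L
      den <- crossprod(Wx, u^2); den[den == 0] <- 1
      w <- crossprod(X, u) / den
      w <- w / sqrt(sum(w^2))
      den <- Wx %*% w^2; den[den == 0] <- 1
      t_new <- (X %*% w) / den
      den <- crossprod(Wy, t_new^2); den[den == 0] <- 1
      cc <- crossprod(Y, t_new) / den
      den <- Wy %*% cc^2; den[den == 0] <- 1
      u <- drop((Y %*% cc) / den)
      delta <- sqrt(sum((t_new - t_vec)^2)) / max(sqrt(sum(t_new^2)), .Machine$double.eps)
      t_vec <- drop(t_new)
      if (delta <= tol || repeat_count >= max_iter) break
    }
    den <- crossprod(Wx, t_vec^2); den[den == 0] <- 1
    p_vec <- drop(crossprod(X, t_vec) / den)
    ## sign convention on the x-loading
    s <- sign(p_vec[which.max(abs(p_vec))])
    if (s < 0) { p_vec <- -p_vec; t_vec <- -t_vec; w <- -w; cc <- -cc; u <- -u }
    ss_before_x <- if (a == 1) ssx else ssx_prev
    ss_before_y <- if (a == 1) ssy else ssy_prev
    X <- X - (t_vec %*% t(p_vec)) * Wx
    Y <- Y - (t_vec %*% t(drop(cc))) * Wy
    ssx_prev <- sum(X^2); ssy_prev <- sum(Y^2)
    r2x <- c(r2x, (ss_before_x - ssx_prev) / ssx)
    r2y <- c(r2y, (ss_before_y - ssy_prev) / ssy)
    T_ <- cbind(T_, t_vec); U_ <- cbind(U_, u)
    P_ <- cbind(P_, p_vec); C_ <- cbind(C_, drop(cc)); W_ <- cbind(W_, drop(w))
  }
  G <- Y                                  # Y-residual wrt inner relation T C'
  list(x_scores = T_, x_loadings = P_, y_scores = U_, y_loadings = C_,
       weights = W_, x_residual = X, y_residual = Y, inner_residual = G,
       r2x = r2x, r2y = r2y, ssx = ssx, ssy = ssy)
}

## regression coefficients B = W (P'W)^-1 C' for prediction
.pls_coef <- function(fit) {
  A <- ncol(fit$weights)
  if (A == 0) return(NULL)
  fit$weights %*% solve(crossprod(fit$x_loadings, fit$weights), t(fit$y_loadings))
}

#' Predict responses from a fitted PLS model
#'
#' @param object A `"pls_model"`.
#' @param newdata Centered/scaled X matrix on the training preprocessing
#'   scale; missing cells (`NA`) contribute zero, consistent with the
#'   zero-leverage missing-value contract.
#' @param ... Unused.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  B <- .pls_coef(object)
  xn <- as.matrix(newdata)
  xn[is.na(xn)] <- 0
  xn %*% B
}

## 7-fold (default) contiguous cross-validation; q2 = 1 - PRESS/SS
.pls_q2 <- function(xw, yw, A, folds, tol, max_iter) {
  n <- nrow(xw$x)
  folds <- min(folds, n)
  idx <- split(seq_len(n), cut(seq_len(n), folds, labels = FALSE))
  press <- 0; sstot <- 0
  for (f in idx) {
    fit <- .pls_core(xw$x[-f, , drop = FALSE], xw$w[-f, , drop = FALSE],
                     yw$x[-f, , drop = FALSE], yw$w[-f, , drop = FALSE],
                     A, tol, max_iter)
    B <- .pls_coef(fit)
    if (is.null(B)) next
    pred <- xw$x[f, , drop = FALSE] %*% B
    obs_w <- yw$w[f, , drop = FALSE]
    press <- press + sum(((yw$x[f, , drop = FALSE] - pred) * obs_w)^2)
    sstot <- sstot + sum((yw$x[f, , drop = FALSE] * obs_w)^2)
  }
  1 - press / sstot
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d components, R2X = %.3f, R2Y = %.3f",
              ncol(x$x_scores), sum(x$r2x), sum(x$r2y)))
  if (!is.null(x$q2)) cat(sprintf(", Q2 = %.3f", x$q2))
  cat("\n")
  invisible(x)
}

#' Single-response orthogonal PLS (OPLS)
#'
#' Splits the systematic variation of `X` into one predictive component
#' (correlated with `y`) and `n_ortho` orthogonal components (uncorrelated
#' with `y`): `X = t_p p_p' + T_o P_o' + E`, `y = t_p q_p + f`. With a single
#' response there is exactly one predictive component; with `n_ortho = 0` the
#' prediction coincides with a one-component PLS model.
#'
#' @param X Preprocessed [block_matrix()] or centered matrix.
#' @param y Single-column centered response (vector, matrix, or
#'   `block_matrix`).
#' @param n_ortho Number of orthogonal components to extract.
#' @param tol,max_iter Convergence controls (used for the missing-data case).
#' @return An object of class `"opls_model"` with `predictive_score` (t_p),
#'   `predictive_loading` (p_p), `predictive_y_loading` (q_p), `ortho_scores`
#'   (T_o), `ortho_loadings` (P_o), `ortho_weights`, `x_residual` (E),
#'   `y_residual` (f), `r2x_pred`, `r2x_ortho` (per component), `r2y`.
#' @export
fit_opls <- function(X, y, n_ortho = 0L, tol = 1e-9, max_iter = 500L) {
  xw <- .xw(X)
  yv <- if (inherits(y, "block_matrix")) y$values else as.matrix(y)
  if (ncol(yv) != 1) stop("fit_opls() requires a single-column y")
  if (anyNA(yv)) stop("missing values in y are not supported")
  y0 <- drop(yv)
  if (stats::sd(y0) == 0) stop("y is constant")
  Xc <- xw$x; Wx <- xw$w
  n <- nrow(Xc); p <- ncol(Xc)
  ssx <- sum(Xc^2)
  ## predictive weight from the y-covariance direction
  den <- crossprod(Wx, y0^2); den[den == 0] <- 1
  w <- drop(crossprod(Xc, y0) / den)
  w <- w / sqrt(sum(w^2))
  To <- matrix(0, n, 0); Po <- matrix(0, p, 0); Wo <- matrix(0, p, 0)
  r2x_ortho <- numeric(0)
  ss_prev <- ssx
  for (k in seq_len(n_ortho)) {
    den <- Wx %*% w^2; den[den == 0] <- 1
    t_vec <- drop((Xc %*% w) / den)
    den <- crossprod(Wx, t_vec^2); den[den == 0] <- 1
    p_vec <- drop(crossprod(Xc, t_vec) / den)
    w_o <- p_vec - drop(crossprod(w, p_vec)) * w
    if (sqrt(sum(w_o^2)) < 1e-10) break          # no orthogonal variation left
    w_o <- w_o / sqrt(sum(w_o^2))
    den <- Wx %*% w_o^2; den[den == 0] <- 1
    t_o <- drop((Xc %*% w_o) / den)
    den <- crossprod(Wx, t_o^2); den[den == 0] <- 1
    p_o <- drop(crossprod(Xc, t_o) / den)
    Xc <- Xc - (t_o %*% t(p_o)) * Wx
    ss_new <- sum(Xc^2)
    r2x_ortho <- c(r2x_ortho, (ss_prev - ss_new) / ssx)
    ss_prev <- ss_new
    To <- cbind(To, t_o); Po <- cbind(Po, p_o); Wo <- cbind(Wo, w_o)
  }
  den <- Wx %*% w^2; den[den == 0] <- 1
  t_p <- drop((Xc %*% w) / den)
  den <- crossprod(Wx, t_p^2); den[den == 0] <- 1
  p_p <- drop(crossprod(Xc, t_p) / den)
  q_p <- sum(y0 * t_p) / sum(t_p^2)
  f <- y0 - t_p * q_p
  E <- Xc - (t_p %*% t(p_p)) * Wx
  structure(list(
    predictive_score = t_p, predictive_loading = p_p,
    predictive_y_loading = q_p, predictive_weight = w,
    ortho_scores = To, ortho_loadings = Po, ortho_weights = Wo,
    x_residual = E, y_residual = f,
    r2x_pred = (ss_prev - sum(E^2)) / ssx,
    r2x_ortho = r2x_ortho,
    r2y = 1 - sum(f^2) / sum(y0^2)
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS model: 1 predictive + %d orthogonal component(s)\n  R2X(pred) = %.3f, R2X(ortho) = %.3f, R2Y = %.3f\n",
    ncol(x$ortho_scores), x$r2x_pred, sum(x$r2x_ortho), x$r2y))
  invisible(x)
}

#' Predict the response from a fitted OPLS model
#'
#' Orthogonal variation is removed from the new observations before the
#' predictive score is formed.
#'
#' @param object An `"opls_model"`.
#' @param newdata Matrix on the training preprocessing scale.
#' @param ... Unused.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  xn <- as.matrix(newdata)
  xn[is.na(xn)] <- 0
  ko <- ncol(object$ortho_scores)
  for (k in seq_len(ko)) {
    t_o <- xn %*% object$ortho_weights[, k]
    xn <- xn - t_o %*% t(object$ortho_loadings[, k])
  }
  drop(xn %*% object$predictive_weight) * object$predictive_y_loading
}
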
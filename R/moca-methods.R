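#' @export
print.moca <- function(x, ...) {
  kinds <- vapply(x$components, `[[`, "", "kind")
  cat(sprintf("Multiblock orthogonal component model: %d blocks, %d observations\n",
              length(x$block_names), x$n_obs))
  cat(sprintf("  strictness %.3g: %d global, %d local, %d unique component(s)\n",
              x$options$strictness, sum(kinds == "global"),
              sum(kinds == "local"), sum(kinds == "unique")))
  tab <- rbind(R2Xj = x$r2xj, R2Xu = x$r2xu, residual = x$r2_residual)
  print(round(tab, 3))
  invisible(x)
}

#' Summarize a fitted multiblock decomposition
#'
#' @param object A fitted [moca()] model.
#' @param ... Unused.
#' @return A list of class `"summary.moca"` with a per-block variance table
#'   and a per-component table (index, kind, member blocks, mean explained
#'   variance).
#' @export
summary.moca <- function(object, ...) {
  comps <- data.frame(
    index = vapply(object$components, `[[`, 0L, "index"),
    kind = vapply(object$components, `[[`, "", "kind"),
    blocks = vapply(object$components, function(cmp)
      paste(cmp$blocks, collapse = "+"), ""),
    mean_r2 = vapply(object$components, function(cmp) mean(cmp$r2), 0)
  )
  blocks <- data.frame(
    block = object$block_names,
    r2xj = unname(object$r2xj),
    r2xu = unname(object$r2xu),
    r2_residual = unname(object$r2_residual)
  )
  structure(list(blocks = blocks, components = comps,
                 strictness = object$options$strictness),
            class = "summary.moca")
}

#' @export
print.summary.moca <- function(x, ...) {
  cat("Per-block explained variance (strictness", format(x$strictness), "):\n")
  print(x$blocks, row.names = FALSE, digits = 3)
  cat("\nComponents:\n")
  print(x$components, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Component scores of a fitted decomposition
#'
#' @param model A fitted [moca()] model.
#' @param consensus For joint components, return the consensus score instead
#'   of per-block scores. Default `TRUE`.
#' @return A data frame of observations by components; per-block columns are
#'   named `c<index>_<block>`, consensus columns `c<index>_consensus`.
#' @export
moca_scores <- function(model, consensus = TRUE) {
  stopifnot(inherits(model, "moca"))
  out <- list()
  for (cmp in model$components) {
    if (!is.null(cmp$consensus) && consensus)
      out[[sprintf("c%d_consensus", cmp$index)]] <- cmp$consensus
    for (b in cmp$blocks)
      out[[sprintf("c%d_%s", cmp$index, b)]] <- cmp$scores[[b]]
  }
  df <- as.data.frame(out, check.names = FALSE)
  rownames(df) <- model$obs_ids
  df
}

#' @export
#' @rdname moca_scores
#' @param object,... Method arguments; `coef` returns per-block loadings.
coef.moca <- function(object, ...) {
  out <- lapply(object$block_names, function(b) {
    cols <- list()
    for (cmp in object$components)
      if (b %in% cmp$blocks)
        cols[[sprintf("c%d", cmp$index)]] <- cmp$loadings[[b]]
    if (!length(cols)) return(matrix(0, length(object$var_names[[b]]), 0,
                                     dimnames = list(object$var_names[[b]], NULL)))
    m <- do.call(cbind, cols)
    rownames(m) <- object$var_names[[b]]
    m
  })
  names(out) <- object$block_names
  out
}

#' @export
residuals.moca <- function(object, ...) object$residuals

#' @export
fitted.moca <- function(object, ...) {
  out <- list()
  for (b in object$block_names) {
    p <- length(object$var_names[[b]])
    rec <- matrix(0, object$n_obs, p,
                  dimnames = list(object$obs_ids, object$var_names[[b]]))
    for (cmp in object$components)
      if (b %in% cmp$blocks)
        rec <- rec + cmp$scores[[b]] %*% t(cmp$loadings[[b]])
    out[[b]] <- rec
  }
  out
}

#' Plot the explained-variance overview of a decomposition
#'
#' Stacked per-block bars of explained variance, joint components in green
#' and unique components in blue, mirroring the customary R2 overview of
#' multiblock models.
#'
#' @param x A fitted [moca()] model.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.moca <- function(x, ...) {
  nb <- length(x$block_names)
  ncmp <- length(x$components)
  mat <- matrix(0, ncmp, nb, dimnames = list(NULL, x$block_names))
  cols <- character(ncmp)
  for (i in seq_len(ncmp)) {
    cmp <- x$components[[i]]
    for (b in cmp$blocks) mat[i, b] <- cmp$r2[[b]]
    cols[i] <- if (cmp$kind == "unique") "#4477cc" else "#44aa55"
  }
  graphics::barplot(mat, col = cols, border = "grey30",
                    ylab = "explained variance (R2)", ylim = c(0, 1), ...)
  graphics::legend("topright", fill = c("#44aa55", "#4477cc"),
                   legend = c("joint", "unique"), bty = "n")
  invisible(x)
}
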
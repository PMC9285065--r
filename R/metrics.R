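#' Per-component score correlation matrices between blocks
#'
#' For every joint component, the Pearson correlations between the member
#' blocks' score vectors. Entries for blocks that are not members of a
#' component are `NA` (absent, not zero).
#'
#' @param model A fitted [moca()] model.
#' @return Named list (one entry per joint component, `"c<index>"`) of
#'   blocks-by-blocks correlation matrices.
#' @export
score_correlation_matrix <- function(model) {
  stopifnot(inherits(model, "moca"))
  nms <- model$block_names
  out <- list()
  for (cmp in model$components) {
    if (cmp$kind == "unique") next
    m <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
    S <- do.call(cbind, cmp$scores)
    cc <- stats::cor(S)
    m[cmp$blocks, cmp$blocks] <- cc
    out[[sprintf("c%d", cmp$index)]] <- m
  }
  out
}

## per-component contribution of a (block, target) pair:
## R2Xj of the target times |corr| of the two blocks' scores
.joint_contributions <- function(model, block, target) {
  rows <- list()
  for (cmp in model$components) {
    if (cmp$kind == "unique") next
    if (!(target %in% cmp$blocks)) next
    others <- setdiff(cmp$blocks, target)
    r2t <- cmp$r2[[target]]
    if (identical(block, target)) {
      rows[[length(rows) + 1]] <- c(index = cmp$index, r2 = r2t, corr = 1)
    } else if (block %in% others) {
      rho <- abs(stats::cor(cmp$scores[[block]], cmp$scores[[target]]))
      rows[[length(rows) + 1]] <- c(index = cmp$index, r2 = r2t, corr = rho)
    }
  }
  if (!length(rows)) return(data.frame(index = integer(), r2 = numeric(),
                                       corr = numeric()))
  as.data.frame(do.call(rbind, rows))
}

.check_block <- function(model, name, what = "block") {
  if (!name %in% model$block_names)
    stop("unknown ", what, " '", name, "'")
  invisible(name)
}

#' Redundancy of a target block
#'
#' `R_T = sum_j R2Xj(T) * max_A |corr(t_jA, t_jT)|`, summed over the joint
#' components the target belongs to; the correlation is maximized in
#' absolute value over the *other* member blocks A. It estimates how well
#' the target block's joint information is already covered by the
#' best-correlated other block: a block with high redundancy can be dropped
#' from descriptor calculation with little loss.
#'
#' Correlations enter in absolute value because score signs are arbitrary
#' up to a convention. `0 <= R_T <= R2Xj(T)` always holds.
#'
#' @param model A fitted [moca()] model.
#' @param target Name of the target block.
#' @return A single number.
#' @export
redundancy <- function(model, target) {
  stopifnot(inherits(model, "moca"))
  .check_block(model, target, "target")
  total <- 0
  for (cmp in model$components) {
    if (cmp$kind == "unique") next
    if (!(target %in% cmp$blocks)) next
    others <- setdiff(cmp$blocks, target)
    if (!length(others)) next           # sole-member components contribute 0
    rho <- max(abs(vapply(others, function(a)
      stats::cor(cmp$scores[[a]], cmp$scores[[target]]), 0)))
    total <- total + cmp$r2[[target]] * rho
  }
  total
}

#' Predictivity score of a descriptor block for a target block
#'
#' `P_A = sum_j R2Xj(T) * |corr(t_jA, t_jT)|`, summed over the joint
#' components in which both blocks are members. It estimates the fraction of
#' the target block's variance that block A could explain in a regression
#' model, without fitting one per block. Self-predictivity equals the
#' target's joint explained variance: `P(T, T) = R2Xj(T)`, since the
#' self-correlation is 1.
#'
#' @param model A fitted [moca()] model.
#' @param block Name of the descriptor block A.
#' @param target Name of the target block T.
#' @return A single number.
#' @seealso [predictivity_contributions()] for the bare sum applied to
#'   per-component explained variances and correlations obtained elsewhere.
#' @export
predictivity <- function(model, block, target) {
  stopifnot(inherits(model, "moca"))
  .check_block(model, block)
  .check_block(model, target, "target")
  contrib <- .joint_contributions(model, block, target)
  predictivity_contributions(contrib$r2, contrib$corr)
}

#' Predictivity from per-component contributions
#'
#' The predictivity sum `sum_j r2_j * |corr_j|` applied directly to a vector
#' of per-component target explained variances and the matching score
#' correlations, e.g. values read off a fitted model report.
#'
#' @param r2 Per-component explained variance of the target block.
#' @param corr Per-component score correlations between the descriptor and
#'   target block (absolute value is taken).
#' @return A single number.
#' @examples
#' predictivity_contributions(c(0.52, 0.17, 0.09), c(1, 1, 1))  # 0.78
#' @export
predictivity_contributions <- function(r2, corr) {
  stopifnot(length(r2) == length(corr))
  sum(r2 * abs(corr))
}

#' Tidy overview of explained variance per block and component
#'
#' @param model A fitted [moca()] model.
#' @return A data frame with columns `block`, `component`, `kind`, `r2`,
#'   one row per (block, component) membership, followed by per-block total
#'   rows (`kind` = `joint_total`, `unique_total`, `residual`, with
#'   `component` `NA`).
#' @export
r2_overview <- function(model) {
  stopifnot(inherits(model, "moca"))
  rows <- list()
  for (cmp in model$components)
    for (b in cmp$blocks)
      rows[[length(rows) + 1]] <- data.frame(
        block = b, component = cmp$index, kind = cmp$kind, r2 = cmp$r2[[b]])
  for (b in model$block_names) {
    rows[[length(rows) + 1]] <- data.frame(
      block = b, component = NA_integer_, kind = "joint_total",
      r2 = unname(model$r2xj[b]))
    rows[[length(rows) + 1]] <- data.frame(
      block = b, component = NA_integer_, kind = "unique_total",
      r2 = unname(model$r2xu[b]))
    rows[[length(rows) + 1]] <- data.frame(
      block = b, component = NA_integer_, kind = "residual",
      r2 = unname(model$r2_residual[b]))
  }
  do.call(rbind, rows)
}

#' Block-level metric table
#'
#' Assembles per-block joint/unique explained variance, redundancy (each
#' block in turn as target) and, when a target block is given, the
#' predictivity of every block for that target.
#'
#' @param model A fitted [moca()] model.
#' @param target Optional target block name (defaults to the multiblock
#'   object's designated target, if any).
#' @return A data frame with one row per block.
#' @export
block_metrics <- function(model, target = NULL) {
  stopifnot(inherits(model, "moca"))
  if (is.null(target)) target <- model$target
  nms <- model$block_names
  out <- data.frame(
    block = nms,
    r2xj = unname(model$r2xj[nms]),
    r2xu = unname(model$r2xu[nms]),
    redundancy = vapply(nms, function(b) redundancy(model, b), 0)
  )
  if (!is.null(target)) {
    .check_block(model, target, "target")
    out$predictivity <- vapply(nms, function(b)
      predictivity(model, b, target), 0)
    attr(out, "target") <- target
  }
  out
}

#' Write block metrics as a tidy TSV
#'
#' Long format with columns `metric`, `block`, `target`, `value`.
#'
#' @param model A fitted [moca()] model.
#' @param path Output path.
#' @param target Optional target block, see [block_metrics()].
#' @return The long-format data frame, invisibly.
#' @export
write_metrics_tsv <- function(model, path, target = NULL) {
  bm <- block_metrics(model, target)
  tg <- attr(bm, "target")
  long <- rbind(
    data.frame(metric = "r2xj", block = bm$block, target = NA, value = bm$r2xj),
    data.frame(metric = "r2xu", block = bm$block, target = NA, value = bm$r2xu),
    data.frame(metric = "redundancy", block = bm$block, target = bm$block,
               value = bm$redundancy))
  if (!is.null(tg))
    long <- rbind(long, data.frame(metric = "predictivity", block = bm$block,
                                   target = tg, value = bm$predictivity))
  long$value <- sprintf("%.6g", long$value)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(long)
}
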
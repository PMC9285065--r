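#' Construct a block of variables
#'
#' A block is one observation-by-variable numeric matrix, typically all
#' descriptors computed by one software package, or a set of biological
#' endpoints. Missing cells are allowed and are carried as `NA`; all model
#' fitting in this package skips missing cells rather than imputing them.
#'
#' @param values Numeric matrix (observations in rows). `NA` marks missing.
#' @param name Block identifier.
#' @param var_names Variable names; defaults to `colnames(values)`.
#' @param obs_ids Observation identifiers; defaults to `rownames(values)`.
#' @return An object of class `"block_matrix"`: a list with elements
#'   `name`, `values`, `var_names`, `obs_ids`, `col_means`, `col_scales`
#'   and `preprocessing` (one of `"raw"`, `"centered"`, `"centered_scaled"`).
#' @examples
#' b <- block_matrix(matrix(rnorm(20), 5, 4), "demo")
#' dim(b)
#' @export
block_matrix <- function(values, name = "block", var_names = NULL, obs_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(var_names)) {
    var_names <- colnames(values)
    if (is.null(var_names)) var_names <- paste0(name, "_v", seq_len(ncol(values)))
  }
  if (is.null(obs_ids)) {
    obs_ids <- rownames(values)
    if (is.null(obs_ids)) obs_ids <- paste0("obs", seq_len(nrow(values)))
  }
  stopifnot(length(var_names) == ncol(values), length(obs_ids) == nrow(values))
  dimnames(values) <- list(obs_ids, var_names)
  structure(list(
    name = name,
    values = values,
    var_names = as.character(var_names),
    obs_ids = as.character(obs_ids),
    col_means = rep(0, ncol(values)),
    col_scales = rep(1, ncol(values)),
    preprocessing = "raw"
  ), class = "block_matrix")
}

#' @export
dim.block_matrix <- function(x) dim(x$values)

#' @export
print.block_matrix <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf("Block '%s': %d observations x %d variables (%s, %.1f%% missing)\n",
              x$name, nrow(x$values), ncol(x$values), x$preprocessing, 100 * miss))
  invisible(x)
}

#' Missingness mask of a block
#'
#' @param block A [block_matrix()].
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(block) is.na(block$values)

## observed-cell column statistics, NA-aware
.col_stats <- function(values) {
  n_obs_col <- colSums(!is.na(values))
  means <- colMeans(values, na.rm = TRUE)
  vars <- apply(values, 2, stats::var, na.rm = TRUE)
  vars[n_obs_col < 2] <- NA_real_
  list(n = n_obs_col, mean = means, var = vars)
}

#' Center and optionally scale a block
#'
#' Column means and standard deviations are estimated over observed cells
#' only (missing cells have no leverage), using the n-1 denominator as is
#' conventional for unit-variance scaling in chemometrics. Missing cells
#' stay missing.
#'
#' @param block A raw [block_matrix()].
#' @param mode `"center_and_uv_scale"` (default, mean-center then scale every
#'   column to unit variance) or `"center_only"`.
#' @return A new `block_matrix` with `preprocessing` updated and the applied
#'   `col_means`/`col_scales` stored.
#' @examples
#' b <- block_matrix(cbind(a = c(1, 2, 3)), "x")
#' center_scale(b)$values
#' @export
center_scale <- function(block, mode = c("center_and_uv_scale", "center_only")) {
  stopifnot(inherits(block, "block_matrix"))
  mode <- match.arg(mode)
  if (block$preprocessing != "raw")
    stop("block '", block$name, "' is already preprocessed (", block$preprocessing, ")")
  st <- .col_stats(block$values)
  if (any(st$n < 2)) {
    bad <- block$var_names[which(st$n < 2)]
    stop("column(s) with fewer than 2 observed cells in block '", block$name,
         "': ", paste(bad, collapse = ", "))
  }
  scales <- rep(1, ncol(block$values))
  if (mode == "center_and_uv_scale") {
    zero <- st$var <= 0
    if (any(zero))
      stop("zero-variance column(s) in block '", block$name, "': ",
           paste(block$var_names[zero], collapse = ", "),
           "; run remove_constant_columns() first")
    scales <- sqrt(st$var)
  }
  out <- block
  out$values <- sweep(sweep(block$values, 2, st$mean, "-"), 2, scales, "/")
  out$col_means <- unname(st$mean)
  out$col_scales <- unname(scales)
  out$preprocessing <- if (mode == "center_only") "centered" else "centered_scaled"
  out
}

#' Drop constant columns from a block
#'
#' @param block A raw [block_matrix()].
#' @param tol Variance tolerance; columns whose observed-cell variance is
#'   `<= tol` are removed. Default `1e-12`.
#' @return A list with elements `block` (the filtered block, column order
#'   preserved) and `removed` (character vector of dropped variable names).
#' @export
remove_constant_columns <- function(block, tol = 1e-12) {
  stopifnot(inherits(block, "block_matrix"))
  if (block$preprocessing != "raw")
    stop("remove_constant_columns() expects a raw block")
  st <- .col_stats(block$values)
  v <- st$var
  const <- is.na(v) | v <= tol
  if (all(const)) stop("block '", block$name, "' empty after filtering")
  removed <- block$var_names[const]
  out <- block
  out$values <- block$values[, !const, drop = FALSE]
  out$var_names <- block$var_names[!const]
  out$col_means <- out$col_means[!const]
  out$col_scales <- out$col_scales[!const]
  list(block = out, removed = removed)
}

#' Logarithmic endpoint transforms
#'
#' Biological endpoint concentrations are conventionally modelled as
#' negative base-10 logarithms of molar quantities (so that larger means
#' more potent); rate-like quantities such as bioconcentration factors are
#' log-transformed without the sign flip.
#'
#' @param values Strictly positive numeric vector.
#' @param mode `"neg_log"` for -log10(x) (default) or `"log_only"` for log10(x).
#' @return Numeric vector of the same length.
#' @examples
#' neg_log_molar(c(1, 0.001))        # 0, 3
#' neg_log_molar(100, "log_only")    # 2
#' @export
neg_log_molar <- function(values, mode = c("neg_log", "log_only")) {
  mode <- match.arg(mode)
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad))
    stop("non-positive value(s) at index ", paste(bad, collapse = ", "))
  if (mode == "neg_log") -log10(values) else log10(values)
}

#' Bundle blocks sharing one observation set
#'
#' @param blocks List of [block_matrix()] objects with identical `obs_ids`.
#' @return An object of class `"multiblock"`: a named list of blocks with
#'   attributes `obs_ids` and (optionally) `target`.
#' @param target Optional name of the target block (e.g. biological
#'   endpoints) used by the redundancy/predictivity metrics.
#' @export
multiblock <- function(blocks, target = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  for (b in blocks) stopifnot(inherits(b, "block_matrix"))
  nms <- vapply(blocks, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate block names")
  names(blocks) <- nms
  ids <- blocks[[1]]$obs_ids
  for (b in blocks)
    if (!identical(b$obs_ids, ids))
      stop("block '", b$name, "' does not share the observation index")
  if (!is.null(target) && !target %in% nms)
    stop("target block '", target, "' not among blocks")
  structure(blocks, class = "multiblock", obs_ids = ids, target = target)
}

#' @export
print.multiblock <- function(x, ...) {
  cat(sprintf("Multiblock data: %d observations, %d blocks\n",
              length(attr(x, "obs_ids")), length(x)))
  for (b in x)
    cat(sprintf("  %-12s %4d variables (%s, %.1f%% missing)\n", b$name,
                ncol(b$values), b$preprocessing, 100 * mean(is.na(b$values))))
  tg <- attr(x, "target")
  if (!is.null(tg)) cat("  target block:", tg, "\n")
  invisible(x)
}

#' Preprocess every block of a multiblock object
#'
#' @param data A [multiblock()] with raw blocks.
#' @param mode Passed to [center_scale()]; a single mode or one per block.
#' @return The preprocessed multiblock.
#' @export
preprocess_blocks <- function(data, mode = "center_and_uv_scale") {
  stopifnot(inherits(data, "multiblock"))
  mode <- rep_len(mode, length(data))
  out <- data
  for (i in seq_along(data)) out[[i]] <- center_scale(data[[i]], mode[i])
  attributes(out) <- attributes(data)
  out
}

## internal: centered values with NA replaced by 0, plus 0/1 observed mask.
## Under the NIPALS missing-value contract a missing cell contributes zero to
## every inner product and has exactly zero residual, which is what zeros in
## the data plus mask-aware denominators implement.
.xw <- function(block) {
  x <- if (inherits(block, "block_matrix")) block$values else as.matrix(block)
  w <- 1 - is.na(x) + 0
  x[is.na(x)] <- 0
  list(x = x, w = w)
}
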
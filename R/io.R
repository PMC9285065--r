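#' Read a block-definition configuration
#'
#' The configuration (YAML or JSON, chosen by file extension) assigns every
#' data column to exactly one named block. Two forms are accepted per block:
#' a plain list of column names / inclusive column ranges (`"first:last"`,
#' by header order), or a mapping with keys `columns`, optional
#' `target: true` (at most one block) and optional `preprocessing`
#' (`center_and_uv_scale` or `center_only`; the file-level key
#' `default_preprocessing` sets the fallback).
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @param columns Character vector of available data column names (header
#'   order), used to expand ranges and validate the assignment.
#' @return List with `blocks` (named list of column-name vectors),
#'   `target` (block name or `NULL`), `preprocessing` (named per block).
#' @export
read_block_config <- function(path, columns) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  if (is.null(cfg$blocks)) stop("config must contain a 'blocks' mapping")
  default_prep <- cfg$default_preprocessing %||% "center_and_uv_scale"
  nms <- names(cfg$blocks)
  if (is.null(nms) || anyDuplicated(nms))
    stop("block names must be present and unique")
  blocks <- list(); target <- NULL
  prep <- stats::setNames(rep(default_prep, length(nms)), nms)
  for (b in nms) {
    entry <- cfg$blocks[[b]]
    if (is.list(entry) && !is.null(entry$columns)) {
      cols <- unlist(entry$columns)
      if (isTRUE(entry$target)) {
        if (!is.null(target)) stop("more than one target block")
        target <- b
      }
      if (!is.null(entry$preprocessing)) prep[b] <- entry$preprocessing
    } else cols <- unlist(entry)
    blocks[[b]] <- .expand_columns(as.character(cols), columns, b)
  }
  assigned <- unlist(blocks)
  dup <- unique(assigned[duplicated(assigned)])
  if (length(dup))
    stop("column(s) assigned to more than one block: ",
         paste(dup, collapse = ", "))
  unassigned <- setdiff(columns, assigned)
  if (length(unassigned))
    stop("unassigned column(s): ", paste(unassigned, collapse = ", "))
  list(blocks = blocks, target = target, preprocessing = prep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.expand_columns <- function(cols, available, block) {
  out <- character(0)
  for (cc in cols) {
    if (grepl(":", cc, fixed = TRUE) && !cc %in% available) {
      parts <- strsplit(cc, ":", fixed = TRUE)[[1]]
      i <- match(parts[1], available); j <- match(parts[2], available)
      if (is.na(i) || is.na(j) || j < i)
        stop("invalid column range '", cc, "' in block '", block, "'")
      out <- c(out, available[i:j])
    } else {
      if (!cc %in% available)
        stop("unknown column '", cc, "' in block '", block, "'")
      out <- c(out, cc)
    }
  }
  out
}

#' Read a multiblock dataset from CSV plus a block configuration
#'
#' The CSV must have a header row; its first column holds unique observation
#' identifiers, and empty cells or `NA` denote missing values. Columns are
#' partitioned into blocks according to the configuration, constant columns
#' are removed per block, and per-block preprocessing is applied. A load
#' report (observations, per-block variables, missingness, removed columns)
#' is emitted via `message()`.
#'
#' @param data_path CSV file path.
#' @param config_path Block configuration path, see [read_block_config()].
#' @param preprocess Apply the configured preprocessing (default `TRUE`;
#'   `FALSE` returns raw blocks).
#' @param constant_tol Variance tolerance for constant-column removal.
#' @return A [multiblock()] object (with `target` attribute if configured).
#' @export
read_dataset <- function(data_path, config_path, preprocess = TRUE,
                         constant_tol = 1e-12) {
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  df <- utils::read.csv(data_path, check.names = FALSE,
                        na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("CSV must have an ID column plus data columns")
  obs_ids <- as.character(df[[1]])
  if (anyDuplicated(obs_ids))
    stop("duplicate observation ID(s): ",
         paste(unique(obs_ids[duplicated(obs_ids)]), collapse = ", "))
  dat <- df[, -1, drop = FALSE]
  for (j in seq_along(dat)) {
    col <- dat[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop("non-numeric value '", col[bad[1]], "' at row ", bad[1],
             ", column '", names(dat)[j], "'")
      dat[[j]] <- num
    }
  }
  cfg <- read_block_config(config_path, names(dat))
  blocks <- list()
  for (b in names(cfg$blocks)) {
    bm <- block_matrix(as.matrix(dat[cfg$blocks[[b]]]), name = b,
                       var_names = cfg$blocks[[b]], obs_ids = obs_ids)
    rc <- remove_constant_columns(bm, tol = constant_tol)
    if (length(rc$removed))
      message("block '", b, "': removed constant column(s) ",
              paste(rc$removed, collapse = ", "))
    bm <- rc$block
    message(sprintf("block '%s': %d variables, %.1f%% missing", b,
                    ncol(bm$values), 100 * mean(is.na(bm$values))))
    if (preprocess)
      bm <- center_scale(bm, mode = unname(cfg$preprocessing[b]))
    blocks[[b]] <- bm
  }
  message(length(obs_ids), " observations, ", length(blocks), " blocks")
  multiblock(blocks, target = cfg$target)
}

#' Write a multiblock dataset as CSV plus a block configuration
#'
#' Inverse of [read_dataset()] for raw blocks; used by the `simulate` CLI
#' subcommand to materialize synthetic datasets.
#'
#' @param data A [multiblock()] with raw blocks.
#' @param data_path Output CSV path.
#' @param config_path Output YAML config path.
#' @return `invisible(NULL)`.
#' @export
write_dataset <- function(data, data_path, config_path) {
  stopifnot(inherits(data, "multiblock"))
  mats <- lapply(data, function(b) b$values)
  wide <- do.call(cbind, mats)
  df <- data.frame(id = attr(data, "obs_ids"), wide, check.names = FALSE)
  utils::write.csv(df, data_path, row.names = FALSE, na = "")
  cfg <- list(blocks = lapply(data, function(b) as.list(b$var_names)))
  tg <- attr(data, "target")
  if (!is.null(tg))
    cfg$blocks[[tg]] <- list(columns = as.list(data[[tg]]$var_names),
                             target = TRUE)
  yaml::write_yaml(cfg, config_path)
  invisible(NULL)
}

#' Serialize a fitted decomposition to a directory
#'
#' Writes `model.json` (options, block metadata, per-component kind, member
#' blocks and explained variance, and the relative paths of the tables),
#' `scores.tsv` (observations by components: per-block scores
#' `c<index>_<block>` and `c<index>_consensus` for joint components) and one
#' `loadings_<block>.tsv` per block. Floats are written with `%.6g`.
#'
#' @param model A fitted [moca()] model.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_moca <- function(model, dir) {
  stopifnot(inherits(model, "moca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) sprintf("%.6g", x)
  sc <- moca_scores(model, consensus = TRUE)
  sc_out <- data.frame(observation = rownames(sc),
                       lapply(sc, fmt), check.names = FALSE)
  utils::write.table(sc_out, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  loadings <- coef.moca(model)
  loading_files <- character(0)
  for (b in model$block_names) {
    L <- loadings[[b]]
    fn <- sprintf("loadings_%s.tsv", b)
    df <- data.frame(variable = rownames(L),
                     apply(L, 2, fmt), check.names = FALSE)
    if (!ncol(L)) df <- data.frame(variable = rownames(L))
    utils::write.table(df, file.path(dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    loading_files <- c(loading_files, fn)
  }
  meta <- list(
    package = "moca",
    options = unclass(model$options),
    blocks = model$block_names,
    target = model$target,
    n_obs = model$n_obs,
    r2xj = as.list(model$r2xj),
    r2xu = as.list(model$r2xu),
    r2_residual = as.list(model$r2_residual),
    components = lapply(model$components, function(cmp) list(
      index = cmp$index, kind = cmp$kind, blocks = as.list(cmp$blocks),
      r2 = as.list(cmp$r2))),
    scores_file = "scores.tsv",
    loading_files = as.list(stats::setNames(loading_files, model$block_names))
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a serialized decomposition
#'
#' Reconstructs a lightweight `"moca"` object (components, scores, explained
#' variances, options) from a directory written by [write_moca()];
#' sufficient for [summary.moca()], [r2_overview()], [redundancy()] and
#' [predictivity()]. Residual matrices are not serialized and are `NULL`.
#'
#' @param dir Directory containing `model.json`.
#' @return A `"moca"` object.
#' @export
read_moca <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"),
                             simplifyVector = FALSE)
  sc <- utils::read.delim(file.path(dir, meta$scores_file),
                          check.names = FALSE)
  comps <- lapply(meta$components, function(cm) {
    blocks <- unlist(cm$blocks)
    scores <- lapply(blocks, function(b)
      sc[[sprintf("c%d_%s", cm$index, b)]])
    names(scores) <- blocks
    cons_col <- sprintf("c%d_consensus", cm$index)
    list(index = cm$index, kind = cm$kind, blocks = blocks,
         scores = scores, loadings = NULL,
         r2 = unlist(cm$r2),
         consensus = if (cons_col %in% names(sc)) sc[[cons_col]] else NULL,
         disagreement = NULL)
  })
  opts <- meta$options
  structure(list(
    components = comps,
    r2xj = unlist(meta$r2xj), r2xu = unlist(meta$r2xu),
    r2_residual = unlist(meta$r2_residual),
    options = structure(opts, class = "moca_options"),
    block_names = unlist(meta$blocks),
    n_obs = meta$n_obs, obs_ids = as.character(sc$observation),
    var_names = NULL, target = meta$target,
    residuals = NULL, pairwise = NULL
  ), class = "moca")
}

#' Bundled strictness-sweep example table
#'
#' A 12-condition by 11-block table of joint-variance fractions (R2Xj) from
#' strictness-sweep MOCA models of eleven molecular-descriptor software
#' blocks computed on a 550-molecule reference set: six strictness settings
#' (-0.01 to -0.5) crossed with an 11-block and a 12-block model setup.
#' Useful as a realistic input for the meta-PCA in [r2xj_table_pca()].
#'
#' @return List with `conditions` (data frame: `n_blocks`, `strictness`) and
#'   `r2xj` (12 x 11 numeric matrix, descriptor blocks in columns).
#' @examples
#' ex <- strictness_sweep_example()
#' fit <- r2xj_table_pca(ex$r2xj)
#' round(fit$r2[1], 3)
#' @export
strictness_sweep_example <- function() {
  path <- system.file("extdata", "strictness_sweep_r2xj.tsv", package = "moca")
  df <- utils::read.delim(path, check.names = FALSE)
  list(conditions = df[, c("n_blocks", "strictness")],
       r2xj = as.matrix(df[, -(1:2)]))
}
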
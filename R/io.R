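#' Write / read a tensor as TSV plus metadata
#'
#' A tensor directory holds `metadata.yaml` (dimensions, mode names,
#' category labels) and `values.tsv`, the mode-1 unfolding under the
#' package's fixed column-ordering convention, with the mode-1 categories
#' as the first column.  `read_tensor()` is the exact inverse.
#'
#' @param tensor A [dense_tensor()].
#' @param dir Directory to create/write into.
#' @return `write_tensor()`: `dir`, invisibly.  `read_tensor()`: the
#'   [dense_tensor()].
#' @export
write_tensor <- function(tensor, dir) {
  stopifnot(inherits(tensor, "dense_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(dims = as.integer(dim(tensor)),
               mode_names = as.list(mode_names(tensor)),
               mode_categories = lapply(mode_categories(tensor), as.list))
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  m <- unfold(tensor, 1)
  df <- data.frame(id = mode_categories(tensor)[[1]], m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(mode_names(tensor)[1], paste0("c", seq_len(ncol(m))))
  readr::write_tsv(df, file.path(dir, "values.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  df <- readr::read_tsv(file.path(dir, "values.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dims <- as.integer(unlist(meta$dims))
  x <- fold(unname(m), 1, dims)
  dense_tensor(x,
               mode_names = unlist(meta$mode_names),
               mode_categories = lapply(meta$mode_categories, unlist))
}

#' Write / read an HOSVD decomposition
#'
#' A decomposition directory holds `metadata.yaml`, one
#' `factor_<mode>.tsv` per mode (categories in rows, singular value
#' vectors in columns `l1, l2, ...`, 1-based), and `core.tsv` in long
#' format with one 1-based index column per mode plus `value`.
#'
#' @param fit A `td_hosvd`.
#' @param dir Directory to create/write into.
#' @return `write_decomposition()`: `dir`, invisibly;
#'   `read_decomposition()`: the `td_hosvd`.
#' @export
write_decomposition <- function(fit, dir) {
  stopifnot(inherits(fit, "td_hosvd"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(dims = as.integer(fit$dims),
               core_dims = as.integer(dim(fit$core)),
               mode_names = as.list(fit$mode_names),
               mode_categories = lapply(fit$mode_categories, as.list))
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  for (k in seq_along(fit$factors)) {
    u <- fit$factors[[k]]
    df <- data.frame(category = fit$mode_categories[[k]], u,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("category", paste0("l", seq_len(ncol(u))))
    readr::write_tsv(df,
                     file.path(dir, paste0("factor_", fit$mode_names[k],
                                           ".tsv")),
                     progress = FALSE)
  }
  core_long <- tidy_core(fit)
  readr::write_tsv(core_long, file.path(dir, "core.tsv"), progress = FALSE)
  invisible(dir)
}

tidy_core <- function(fit) {
  dcore <- dim(fit$core)
  grid <- do.call(expand.grid, lapply(dcore, seq_len))
  names(grid) <- paste0("l_", fit$mode_names)
  grid$value <- as.numeric(fit$core)
  tibble::as_tibble(grid)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  mode_names <- unlist(meta$mode_names)
  dcore <- as.integer(unlist(meta$core_dims))
  factors <- lapply(seq_along(mode_names), function(k) {
    df <- readr::read_tsv(file.path(dir, paste0("factor_", mode_names[k],
                                                ".tsv")),
                          show_col_types = FALSE, progress = FALSE)
    u <- as.matrix(df[, -1, drop = FALSE])
    rownames(u) <- df$category
    colnames(u) <- NULL
    u
  })
  core_long <- readr::read_tsv(file.path(dir, "core.tsv"),
                               show_col_types = FALSE, progress = FALSE)
  core <- array(0, dim = dcore)
  idx <- as.matrix(core_long[, seq_along(dcore), drop = FALSE])
  core[idx] <- core_long$value
  cats <- lapply(meta$mode_categories, unlist)
  names(cats) <- mode_names
  structure(
    list(core = core, factors = factors, mode_names = mode_names,
         mode_categories = cats,
         dims = as.integer(unlist(meta$dims))),
    class = "td_hosvd")
}

#' Write a run manifest
#'
#' Every command-line run records its configuration, seed(s), chosen
#' vector indices, omega set, thresholds and output counts in a YAML
#' manifest, sufficient to re-execute the run bit-identically.
#'
#' @param manifest Named list.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$tool_version <- as.character(utils::packageVersion("tdfe"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Write a selection result to disk
#'
#' Writes `selection.tsv` (gene, statistic, p_raw, p_adjusted, selected)
#' and `selected_genes.txt` (single-column identifiers).
#'
#' @param result A `td_selection` with a `selected` column.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_selection <- function(result, dir) {
  stopifnot(inherits(result, "td_selection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(result), file.path(dir, "selection.tsv"),
                   progress = FALSE)
  writeLines(selected_genes(result), file.path(dir, "selected_genes.txt"))
  invisible(dir)
}
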
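#' Higher-order singular value decomposition
#'
#' Full Tucker-form HOSVD of a dense tensor.  The factor matrix of each mode
#' is the matrix of left singular vectors of that mode's unfolding; the core
#' tensor is the data contracted with every factor transpose.  No
#' optimisation (HOOI) or truncation below the exact multilinear rank is
#' performed: the decomposition reconstructs the input to numerical
#' precision.
#'
#' Each mode's factor is truncated to rank
#' `min(dim[k], prod(dim[-k]))` -- beyond that the singular values of the
#' unfolding are exactly zero, so nothing is lost.  For a gene mode with tens
#' of thousands of genes this keeps the gene factor at (number of samples)
#' columns rather than a square gene-by-gene matrix.
#'
#' The sign of each factor column is fixed so that its largest-magnitude
#' entry is positive (ties broken by the first such entry); the core absorbs
#' the flip.  SVD signs are otherwise arbitrary and the chi-squared selection
#' statistic is sign-invariant, but reported singular value vectors must be
#' reproducible across platforms.
#'
#' @param x A [dense_tensor()] (plain numeric arrays are accepted and
#'   wrapped).
#' @return An object of class `td_hosvd` with elements
#'   \describe{
#'     \item{core}{numeric array `G`, one dimension per mode (possibly
#'       truncated as above);}
#'     \item{factors}{list of factor matrices, columns orthonormal, one per
#'       mode, in tensor mode order;}
#'     \item{mode_names, mode_categories}{carried over from the input;}
#'     \item{dims}{dimensions of the input tensor.}
#'   }
#' @examples
#' x <- dense_tensor(array(rnorm(60), c(3, 4, 5)))
#' fit <- hosvd(x)
#' max(abs(reconstruct(fit) - x))   # ~ 1e-15
#' @export
hosvd <- function(x) {
  if (!inherits(x, "dense_tensor")) x <- dense_tensor(x)
  d <- dim(x)
  m <- length(d)
  factors <- vector("list", m)
  for (k in seq_len(m)) {
    M <- unfold(x, k)
    r <- min(d[k], prod(d[-k]))
    u <- svd(M, nu = r, nv = 0)$u
    u <- fix_column_signs(u)
    rownames(u) <- mode_categories(x)[[k]]
    factors[[k]] <- u
  }
  core <- unclass(x)
  for (k in seq_len(m)) core <- ttm(core, t(factors[[k]]), k)
  structure(
    list(core = core,
         factors = factors,
         mode_names = mode_names(x),
         mode_categories = mode_categories(x),
         dims = d),
    class = "td_hosvd")
}

# deterministic SVD sign convention: largest-|entry| of each column positive
fix_column_signs <- function(u) {
  if (ncol(u) == 0L) return(u)
  flip <- apply(u, 2, function(col) col[which.max(abs(col))] < 0)
  u[, flip] <- -u[, flip, drop = FALSE]
  u
}

#' @export
print.td_hosvd <- function(x, ...) {
  cat("<td_hosvd> tensor ", paste(x$dims, collapse = " x "),
      " -> core ", paste(dim(x$core), collapse = " x "), "\n", sep = "")
  cat("  modes: ", paste(x$mode_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reconstruct a tensor from its HOSVD
#'
#' Computes the multilinear product of the core with every factor matrix,
#' i.e. the sum over all core index tuples of `G * (outer product of factor
#' columns)`.  With the untruncated (full) decomposition this equals the
#' original tensor to numerical precision.
#'
#' @param fit A `td_hosvd` object.
#' @return A [dense_tensor()] with the original mode names and categories.
#' @export
reconstruct <- function(fit) {
  stopifnot(inherits(fit, "td_hosvd"))
  for (k in seq_along(fit$factors)) {
    if (ncol(fit$factors[[k]]) != dim(fit$core)[k]) {
      stop("factor for mode ", k, " has ", ncol(fit$factors[[k]]),
           " columns but core dimension is ", dim(fit$core)[k],
           call. = FALSE)
    }
  }
  x <- fit$core
  for (k in seq_along(fit$factors)) x <- ttm(x, fit$factors[[k]], k)
  dense_tensor(x, fit$mode_names, fit$mode_categories)
}

#' Rank core-tensor entries by magnitude
#'
#' Lists core entries, optionally restricted to fixed indices along some
#' modes, sorted by decreasing absolute value.  Ties in magnitude are broken
#' by lexicographic order of the index tuple (earliest mode first, lowest
#' index first), so the ranking is deterministic.
#'
#' This automates reading off which singular value vector combinations
#' dominate the data: a large `|G(l1, ..., lm)|` means the product of the
#' l1-th, ..., lm-th singular value vectors contributes strongly.
#'
#' @param fit A `td_hosvd` object.
#' @param fixed Named list (mode name or index as name) fixing the core index
#'   along some modes, e.g. `list(treatment = 2, tissue = 4)`.
#' @param n Maximum number of entries to return (default all).
#' @return A tibble with one column `l_<mode>` per mode (1-based core
#'   indices), the core `value`, and its `abs_value`, ordered as described.
#' @export
rank_core <- function(fit, fixed = list(), n = Inf) {
  stopifnot(inherits(fit, "td_hosvd"))
  dcore <- dim(fit$core)
  fixed_idx <- resolve_fixed(fixed, fit$mode_names, dcore)
  keep_list <- lapply(seq_along(dcore), function(k) {
    if (!is.na(fixed_idx[k])) fixed_idx[k] else seq_len(dcore[k])
  })
  idx_grid <- as.matrix(rev(expand.grid(rev(keep_list))))
  colnames(idx_grid) <- NULL
  vals <- fit$core[idx_grid]
  # order: decreasing |G|, ties by lexicographic index tuple
  ord <- do.call(order, c(list(-abs(vals)),
                          lapply(seq_along(dcore), function(k) idx_grid[, k])))
  if (is.finite(n)) ord <- utils::head(ord, n)
  out <- tibble::as_tibble(as.data.frame(idx_grid[ord, , drop = FALSE]))
  names(out) <- paste0("l_", fit$mode_names)
  out$value <- vals[ord]
  out$abs_value <- abs(out$value)
  out
}

resolve_fixed <- function(fixed, mode_names, dims) {
  m <- length(dims)
  out <- rep(NA_integer_, m)
  if (length(fixed) == 0L) return(out)
  keys <- names(fixed)
  if (is.null(keys) || any(keys == "")) {
    stop("`fixed` must be a named list mapping mode -> core index",
         call. = FALSE)
  }
  for (i in seq_along(fixed)) {
    k <- suppressWarnings(as.integer(keys[i]))
    if (is.na(k)) k <- match(keys[i], mode_names)
    if (is.na(k) || k < 1L || k > m) {
      stop("unknown mode '", keys[i], "' in `fixed`", call. = FALSE)
    }
    v <- as.integer(fixed[[i]])
    if (is.na(v) || v < 1L || v > dims[k]) {
      stop("fixed index ", fixed[[i]], " out of range 1..", dims[k],
           " for mode '", mode_names[k], "'", call. = FALSE)
    }
    out[k] <- v
  }
  out
}

#' Find the singular value vector matching a contrast
#'
#' Scores every column of a mode's factor matrix by
#' `|contrast . column| / ||column||` and returns the index of the best
#' match (ties broken to the lowest index).  This automates the visual
#' identification of, e.g., the treatment-difference vector (contrast
#' `c(1, -1)` over control/treated) or a tissue-coexpression vector
#' (membership weights +1 for the tissues of interest, -1 elsewhere).
#'
#' @param fit A `td_hosvd` object.
#' @param mode Mode index or name.
#' @param contrast Numeric weight vector, one weight per category of the
#'   mode.
#' @return Integer index (1-based) of the best-matching factor column.
#' @export
find_contrast_vector <- function(fit, mode, contrast) {
  stopifnot(inherits(fit, "td_hosvd"))
  k <- if (is.character(mode)) {
    idx <- match(mode, fit$mode_names)
    if (is.na(idx)) stop("unknown mode '", mode, "'", call. = FALSE)
    idx
  } else {
    as.integer(mode)
  }
  if (k < 1L || k > length(fit$factors)) {
    stop("mode index out of range", call. = FALSE)
  }
  u <- fit$factors[[k]]
  if (length(contrast) != nrow(u)) {
    stop("contrast length (", length(contrast),
         ") must equal the mode dimension (", nrow(u), ")", call. = FALSE)
  }
  scores <- abs(drop(crossprod(u, contrast))) /
    sqrt(colSums(u^2))
  which.max(scores)  # ties resolved to the lowest index
}

#' @describeIn hosvd Tabular view: the ranked core entries.
#' @param x A `td_hosvd` object.
#' @param ... Passed to [rank_core()].
#' @export
tidy.td_hosvd <- function(x, ...) rank_core(x, ...)

#' @describeIn hosvd One-row summary: dimensions, core norm, reconstruction
#'   error.
#' @param x A `td_hosvd` object.
#' @export
glance.td_hosvd <- function(x, ...) {
  rec <- reconstruct(x)
  nx <- fnorm(rec)
  tibble::tibble(
    n_modes = length(x$dims),
    dims = paste(x$dims, collapse = "x"),
    core_dims = paste(dim(x$core), collapse = "x"),
    core_fnorm = fnorm(x$core),
    recon_fnorm = nx
  )
}

#' Singular value vectors of one mode as a tibble
#'
#' @param fit A `td_hosvd` object.
#' @param mode Mode index or name.
#' @return A tibble in long format: `category`, `vector` (the l index) and
#'   `loading`.
#' @export
factor_tibble <- function(fit, mode) {
  k <- check_mode(array(0, fit$dims), if (is.character(mode)) {
    match(mode, fit$mode_names)
  } else {
    mode
  })
  u <- fit$factors[[k]]
  cats <- fit$mode_categories[[k]]
  tibble::tibble(
    category = rep(cats, times = ncol(u)),
    vector = rep(seq_len(ncol(u)), each = nrow(u)),
    loading = as.numeric(u)
  )
}

#' Plot singular value vectors of a condition mode
#'
#' Bar panels of the loadings of selected singular value vectors of one
#' mode, the standard visual aid for deciding which vectors encode a
#' treatment difference or a tissue coexpression pattern.
#'
#' @param fit A `td_hosvd` object.
#' @param mode Mode index or name.
#' @param vectors Which vector indices to show (default first 4).
#' @return A ggplot object.
#' @export
plot_factor <- function(fit, mode, vectors = 1:4) {
  df <- factor_tibble(fit, mode)
  df <- df[df$vector %in% vectors, , drop = FALSE]
  df$category <- factor(df$category, levels = unique(df$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~vector, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "loading") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
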
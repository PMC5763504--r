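#' Dense labelled tensor
#'
#' Construct a dense m-mode tensor of standardized expression values with
#' named modes and category labels per mode.  This is the container every
#' decomposition and pipeline function in tdfe operates on.
#'
#' @param values Numeric array (or matrix / vector, which is promoted to an
#'   array).  All values must be finite; cells that are structurally missing
#'   in a design are represented as exact zeros, never as `NA`.
#' @param mode_names Character vector, one name per mode (e.g.
#'   `c("gene", "tissue", "treatment")`).  Defaults to `mode1`, `mode2`, ...
#' @param mode_categories List of character vectors, one per mode, giving the
#'   category labels along that mode (e.g. tissue names).  Defaults to
#'   `"1", "2", ...` along each mode.
#'
#' @return An object of class `dense_tensor`: the numeric array with
#'   `dimnames` set to the category labels and the names of `dimnames` set to
#'   the mode names.
#' @examples
#' x <- dense_tensor(array(rnorm(24), c(2, 3, 4)),
#'                   mode_names = c("gene", "tissue", "treatment"))
#' dim(x)
#' mode_names(x)
#' @export
dense_tensor <- function(values, mode_names = NULL, mode_categories = NULL) {
  if (is.null(dim(values))) {
    values <- array(values, dim = length(values))
  }
  values <- as.array(values)
  d <- dim(values)
  m <- length(d)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("tensor values must be finite numerics (zero-fill missing cells)",
         call. = FALSE)
  }
  if (is.null(mode_names)) mode_names <- paste0("mode", seq_len(m))
  if (length(mode_names) != m) {
    stop("need exactly one mode name per mode: got ", length(mode_names),
         " names for ", m, " modes", call. = FALSE)
  }
  if (is.null(mode_categories)) {
    mode_categories <- lapply(d, function(n) as.character(seq_len(n)))
  }
  if (length(mode_categories) != m ||
      !all(lengths(mode_categories) == d)) {
    stop("mode_categories must hold one label per level of each mode",
         call. = FALSE)
  }
  mode_categories <- lapply(mode_categories, as.character)
  names(mode_categories) <- mode_names
  dimnames(values) <- mode_categories
  structure(values, class = c("dense_tensor", "array"))
}

#' @export
print.dense_tensor <- function(x, ...) {
  d <- dim(x)
  cat("<dense_tensor> ", paste(d, collapse = " x "), "\n", sep = "")
  cat("  modes: ", paste(mode_names(x), collapse = ", "), "\n", sep = "")
  cat("  Frobenius norm: ", format(fnorm(x)), "\n", sep = "")
  invisible(x)
}

#' Mode names of a tensor
#' @param x A `dense_tensor`.
#' @return Character vector of mode names.
#' @export
mode_names <- function(x) names(dimnames(x))

#' Category labels of a tensor
#' @param x A `dense_tensor`.
#' @return Named list of character vectors, one per mode.
#' @export
mode_categories <- function(x) dimnames(x)

#' Frobenius norm
#' @param x Numeric array.
#' @return The square root of the sum of squared entries.
#' @export
fnorm <- function(x) sqrt(sum(as.numeric(x)^2))

n_modes <- function(x) length(dim(x))

check_mode <- function(x, mode) {
  m <- n_modes(x)
  if (is.character(mode)) {
    idx <- match(mode, mode_names(x))
    if (is.na(idx)) {
      stop("unknown mode '", mode, "'; modes are: ",
           paste(mode_names(x), collapse = ", "), call. = FALSE)
    }
    return(idx)
  }
  mode <- as.integer(mode)
  if (length(mode) != 1L || is.na(mode) || mode < 1L || mode > m) {
    stop("mode index must be a single integer in 1..", m, call. = FALSE)
  }
  mode
}

#' Mode-k unfolding (matricization)
#'
#' Flattens a tensor into a matrix with the chosen mode as rows.  Columns
#' follow a fixed lexicographic convention over the remaining modes with
#' earlier modes varying slowest: for remaining modes (k1 < k2 < ...), the
#' column index is ordered first by k1, then k2, and so on, with the last
#' remaining mode varying fastest.  The same convention is used everywhere in
#' the package, so `fold(unfold(x, k), k, dim(x))` is an exact inverse.
#'
#' @param x A `dense_tensor` or numeric array.
#' @param mode Mode index (1-based) or mode name to place on the rows.
#' @return A matrix of dimension `dim(x)[mode]` by `prod(dim(x)[-mode])`.
#' @seealso [fold()]
#' @examples
#' x <- array(1:24, c(2, 3, 4))
#' dim(unfold(x, 2))  # 3 x 8
#' @export
unfold <- function(x, mode) {
  k <- check_mode(x, mode)
  d <- dim(x)
  others <- setdiff(seq_along(d), k)
  # column-major flattening makes the first permuted mode vary fastest, so
  # reverse the remaining modes to have the earliest vary slowest
  perm <- c(k, rev(others))
  m <- aperm(unclass(x), perm)
  dim(m) <- c(d[k], prod(d[others]))
  m
}

#' Fold a matrix back into a tensor
#'
#' Inverse of [unfold()] under the package's fixed column-ordering
#' convention.
#'
#' @param m Matrix as produced by [unfold()].
#' @param mode The mode that was placed on the rows.
#' @param dims The dimensions of the target tensor.
#' @return A numeric array with dimensions `dims`.
#' @export
fold <- function(m, mode, dims) {
  k <- check_mode(array(0, dims), mode)
  others <- setdiff(seq_along(dims), k)
  if (!all(dim(m) == c(dims[k], prod(dims[others])))) {
    stop("matrix of dimension ", paste(dim(m), collapse = " x "),
         " does not match an unfolding of a ",
         paste(dims, collapse = " x "), " tensor along mode ", k,
         call. = FALSE)
  }
  perm <- c(k, rev(others))
  dim(m) <- dims[perm]
  aperm(m, order(perm))
}

#' Mode-k tensor-matrix product
#'
#' Contracts mode `mode` of the tensor with the columns of `mat`:
#' the result has `nrow(mat)` levels along that mode.
#'
#' @param x Numeric array.
#' @param mat Matrix with `ncol(mat) == dim(x)[mode]`.
#' @param mode Mode to contract.
#' @return Numeric array.
#' @keywords internal
ttm <- function(x, mat, mode) {
  k <- check_mode(x, mode)
  d <- dim(x)
  if (ncol(mat) != d[k]) {
    stop("matrix columns (", ncol(mat), ") must match mode-", k,
         " dimension (", d[k], ")", call. = FALSE)
  }
  out <- mat %*% unfold(x, k)
  d[k] <- nrow(mat)
  fold(out, k, d)
}

#' Tabular view of a tensor
#'
#' @param x A `dense_tensor`.
#' @param ... Unused.
#' @return A tibble with one row per cell: one column per mode (category
#'   labels) plus `value`.
#' @export
tidy.dense_tensor <- function(x, ...) {
  df <- as.data.frame.table(unclass(x), responseName = "value",
                            stringsAsFactors = FALSE)
  names(df) <- c(mode_names(x), "value")
  tibble::as_tibble(df)
}
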
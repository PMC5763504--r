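#' Define a set of gene singular value vectors
#'
#' The selection statistic is built from a chosen set (often written Omega)
#' of gene singular value vectors -- columns of the gene-mode factor matrix.
#'
#' @param indices Integer vector of gene-vector indices (1-based, distinct).
#' @param provenance `"manual"` if supplied by the analyst, `"core-ranked"`
#'   if chosen by [choose_omega()].
#' @return An `omega_set` object.
#' @export
omega_set <- function(indices, provenance = c("manual", "core-ranked")) {
  provenance <- match.arg(provenance)
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("omega set must be non-empty", call. = FALSE)
  if (anyNA(indices) || any(indices < 1L)) {
    stop("omega indices must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(indices)) {
    stop("omega indices must be distinct", call. = FALSE)
  }
  structure(list(indices = indices, provenance = provenance),
            class = "omega_set")
}

#' @export
print.omega_set <- function(x, ...) {
  cat("<omega_set> {", paste(x$indices, collapse = ", "), "} (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

as_omega <- function(omega) {
  if (inherits(omega, "omega_set")) omega else omega_set(omega)
}

#' Chi-squared outlier statistic for genes
#'
#' For each gene i, computes
#' \deqn{S_i = \sum_{\ell \in \Omega} (x_{\ell,i} / \sigma_\ell)^2,}
#' where \eqn{x_{\ell,i}} is gene i's component of the \eqn{\ell}-th gene
#' singular value vector and \eqn{\sigma_\ell} is that vector's standard
#' deviation over all genes (sample sd, denominator n-1).  Under the null
#' that the standardized components are standard normal, \eqn{S_i} follows a
#' chi-squared distribution with \eqn{|\Omega|} degrees of freedom; the raw
#' P-value is the upper-tail probability at \eqn{S_i}.
#'
#' @param gene_factor Numeric matrix of gene singular value vectors (genes in
#'   rows, vectors in columns), e.g. `fit$factors[[1]]` from [hosvd()].
#'   Row names, if present, are used as gene identifiers.
#' @param omega An [omega_set()] or plain integer vector of column indices.
#' @return A `td_selection` object: a tibble with columns `gene`,
#'   `statistic`, `p_raw` (and, after [adjust_pvalues()] /
#'   [select_genes()], `p_adjusted` and `selected`), carrying the omega
#'   set and per-vector `sigma` as attributes.
#' @examples
#' u <- matrix(rnorm(3000), 1000, 3)
#' res <- score_genes(u, omega_set(1:3))
#' head(tidy(res))
#' @export
score_genes <- function(gene_factor, omega) {
  omega <- as_omega(omega)
  gene_factor <- as.matrix(gene_factor)
  if (max(omega$indices) > ncol(gene_factor)) {
    stop("omega index ", max(omega$indices),
         " exceeds the gene factor rank (", ncol(gene_factor), ")",
         call. = FALSE)
  }
  u <- gene_factor[, omega$indices, drop = FALSE]
  sigma <- apply(u, 2, stats::sd)
  if (any(sigma <= 0 | !is.finite(sigma))) {
    bad <- omega$indices[sigma <= 0 | !is.finite(sigma)]
    stop("gene singular value vector(s) ", paste(bad, collapse = ", "),
         " have zero variance; cannot standardize", call. = FALSE)
  }
  s <- drop(sweep(u, 2, sigma, "/")^2 %*% rep(1, length(sigma)))
  genes <- rownames(gene_factor)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(gene_factor)))
  out <- tibble::tibble(
    gene = genes,
    statistic = s,
    p_raw = stats::pchisq(s, df = length(omega$indices), lower.tail = FALSE)
  )
  new_td_selection(out, omega = omega, sigma = stats::setNames(
    sigma, omega$indices))
}

new_td_selection <- function(df, omega, sigma, threshold = NULL,
                             method = NULL) {
  structure(df,
            class = c("td_selection", "tbl_df", "tbl", "data.frame"),
            omega = omega, sigma = sigma, threshold = threshold,
            adjust_method = method)
}

#' @export
print.td_selection <- function(x, ...) {
  omega <- attr(x, "omega")
  cat("<td_selection> ", nrow(x), " genes, omega = {",
      paste(omega$indices, collapse = ", "), "}", sep = "")
  thr <- attr(x, "threshold")
  if (!is.null(thr) && "selected" %in% names(x)) {
    cat(", ", sum(x$selected), " selected at adjusted P < ", thr, sep = "")
  }
  cat("\n")
  NextMethod()
}

#' Adjust raw P-values for multiplicity
#'
#' `"BH"` (the default and the canonical choice) applies the
#' Benjamini-Hochberg step-up procedure via [stats::p.adjust()].
#' `"local-fdr"` computes an experimental empirical-null local
#' false-discovery-rate estimate based on a Grenander (decreasing) density
#' estimate of the P-value distribution; it is provided for comparison only
#' and is not used for any headline selection.
#'
#' @param p Numeric vector of raw P-values in `[0, 1]`, or a `td_selection`.
#' @param method `"BH"` or `"local-fdr"`.
#' @return For a numeric input, the vector of adjusted values; for a
#'   `td_selection`, the object with a `p_adjusted` column added.
#' @examples
#' adjust_pvalues(c(0.001, 0.01, 0.02, 0.5))
#' @export
adjust_pvalues <- function(p, method = c("BH", "local-fdr")) {
  method <- match.arg(method)
  if (inherits(p, "td_selection")) {
    res <- p
    res$p_adjusted <- adjust_pvalues(res$p_raw, method)
    attr(res, "adjust_method") <- method
    return(res)
  }
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("P-values must lie in [0, 1]", call. = FALSE)
  }
  switch(method,
         "BH" = stats::p.adjust(p, method = "BH"),
         "local-fdr" = local_fdr(p))
}

# Empirical-null local FDR from P-values (experimental).
# f(p) is estimated by the Grenander estimator (slope of the least concave
# majorant of the ECDF); the null proportion eta0 by the mean density on
# the upper half of [0,1].  fdr(p) = min(1, eta0 / f(p)).
local_fdr <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  # least concave majorant of the ECDF over knots (0, p_(1), ..., p_(n), 1)
  xs <- c(0, ps, 1)
  ys <- c(0, seq_len(n) / n, 1)
  # pool-adjacent-violators on slopes to get a decreasing step density
  slopes <- diff(ys) / pmax(diff(xs), .Machine$double.eps)
  widths <- diff(xs)
  i <- 1L
  m <- length(slopes)
  vals <- slopes
  wts <- widths
  idx <- seq_len(m)
  # stack-based LCM: merge adjacent blocks while slope increases
  top <- 0L
  bv <- numeric(m); bw <- numeric(m); bn <- integer(m)
  for (j in seq_len(m)) {
    top <- top + 1L
    bv[top] <- vals[j]; bw[top] <- wts[j]; bn[top] <- 1L
    while (top > 1L && bv[top - 1L] <= bv[top]) {
      w <- bw[top - 1L] + bw[top]
      bv[top - 1L] <- (bv[top - 1L] * bw[top - 1L] + bv[top] * bw[top]) / w
      bw[top - 1L] <- w
      bn[top - 1L] <- bn[top - 1L] + bn[top]
      top <- top - 1L
    }
  }
  dens <- rep(bv[seq_len(top)], times = bn[seq_len(top)])
  # density at each sorted p: slope of the segment ending at that knot
  f_at_p <- dens[seq_len(n)]
  eta0 <- min(1, 2 * mean(p > 0.5))
  fdr_sorted <- pmin(1, eta0 / pmax(f_at_p, .Machine$double.eps))
  # enforce monotone non-decreasing fdr in p
  fdr_sorted <- cummax(fdr_sorted)
  out <- numeric(n)
  out[ord] <- fdr_sorted
  out
}

#' Select genes below an adjusted-P threshold
#'
#' Marks genes with adjusted P strictly less than `threshold` as selected.
#' Ties at exactly the threshold are excluded, and the input gene order is
#' preserved.
#'
#' @param result A `td_selection` (with `p_adjusted`; if absent, BH
#'   adjustment is applied first).
#' @param threshold Adjusted-P cutoff in (0, 1); default 0.01.
#' @return The `td_selection` with logical column `selected` and the
#'   threshold recorded; [selected_genes()] extracts the identifiers.
#' @export
select_genes <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "td_selection"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number in (0, 1)", call. = FALSE)
  }
  if (!"p_adjusted" %in% names(result)) {
    result <- adjust_pvalues(result, "BH")
  }
  result$selected <- result$p_adjusted < threshold
  attr(result, "threshold") <- threshold
  result
}

#' @rdname select_genes
#' @return `selected_genes()`: character vector of selected gene
#'   identifiers, in input order.
#' @export
selected_genes <- function(result) {
  stopifnot(inherits(result, "td_selection"))
  if (!"selected" %in% names(result)) {
    stop("run select_genes() first", call. = FALSE)
  }
  result$gene[result$selected]
}

#' Choose gene singular value vectors by core-tensor ranking
#'
#' Walks the core entries matching `fixed` in decreasing `|G|` (ties broken
#' lexicographically, see [rank_core()]) and collects distinct gene-mode
#' indices until `n_vectors` are found.  This is the automated version of
#' reading the top of a ranked core table to decide which gene vectors are
#' coupled to the condition vectors of interest.
#'
#' @param fit A `td_hosvd` object.
#' @param fixed Named list fixing core indices along condition modes (e.g.
#'   `list(treatment = 2, tissue = 4)`); empty to rank the whole core.
#' @param n_vectors Number of distinct gene vectors to collect.
#' @param gene_mode Index or name of the gene mode (default 1).
#' @return An [omega_set()] with provenance `"core-ranked"`.
#' @export
choose_omega <- function(fit, fixed = list(), n_vectors = 3,
                         gene_mode = 1) {
  stopifnot(inherits(fit, "td_hosvd"))
  if (n_vectors < 1) stop("n_vectors must be >= 1", call. = FALSE)
  gk <- if (is.character(gene_mode)) {
    match(gene_mode, fit$mode_names)
  } else {
    as.integer(gene_mode)
  }
  if (is.na(gk) || gk < 1L || gk > length(fit$dims)) {
    stop("invalid gene mode", call. = FALSE)
  }
  ranked <- rank_core(fit, fixed)
  gene_idx <- ranked[[paste0("l_", fit$mode_names[gk])]]
  distinct_idx <- unique(gene_idx)
  if (length(distinct_idx) < n_vectors) {
    stop("only ", length(distinct_idx), " distinct gene-mode indices ",
         "available, need ", n_vectors, call. = FALSE)
  }
  omega_set(distinct_idx[seq_len(n_vectors)], provenance = "core-ranked")
}

#' @describeIn score_genes Tabular view of a selection result.
#' @param x A `td_selection`.
#' @param ... Unused.
#' @export
tidy.td_selection <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @describeIn score_genes One-row summary of a selection result.
#' @export
glance.td_selection <- function(x, ...) {
  om <- attr(x, "omega")
  tibble::tibble(
    n_genes = nrow(x),
    omega = paste(om$indices, collapse = ","),
    omega_provenance = om$provenance,
    df = length(om$indices),
    adjust_method = attr(x, "adjust_method") %||% NA_character_,
    threshold = attr(x, "threshold") %||% NA_real_,
    n_selected = if ("selected" %in% names(x)) sum(x$selected) else
      NA_integer_
  )
}

#' @describeIn score_genes P-value histogram with the selection threshold.
#' @param object A `td_selection`.
#' @export
autoplot.td_selection <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$p_raw)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.02),
                            fill = "grey40") +
    ggplot2::labs(x = "raw P-value", y = "genes") +
    ggplot2::theme_bw()
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
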
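#' Assemble the five-mode study tensor
#'
#' Maps a standardized expression matrix into the tensor
#' genes x treatment(2) x tissue(10) x duration(2) x rest(3): each cell
#' holds the mean over replicates of that design category, and categories
#' with no samples are exact zeros (e.g. no measurements exist 6 weeks
#' after a 5-day stress period).  Standardization is applied *before*
#' averaging -- the two orders differ and the per-sample order is the one
#' this pipeline fixes.
#'
#' @param expression Expression tibble (first column `probe_id`), already
#'   filtered and standardized.
#' @param design A `study_design` tibble covering every sample column.
#' @return A [dense_tensor()] with modes
#'   `(gene, treatment, tissue, duration, rest)`.
#' @export
assemble_tensor <- function(expression, design) {
  stopifnot(is.data.frame(expression), "probe_id" %in% names(expression))
  sample_ids <- names(expression)[-1]
  missing <- setdiff(sample_ids, design$sample_id)
  if (length(missing) > 0L) {
    stop("samples absent from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lev <- design_levels()
  d <- unname(c(nrow(expression), lengths(lev)))
  x <- array(0, dim = d)
  m <- as.matrix(expression[, -1, drop = FALSE])
  key <- design[match(sample_ids, design$sample_id), ]
  cells <- split(seq_along(sample_ids),
                 interaction(key$j1, key$j2, key$j3, key$j4, drop = TRUE))
  for (cols in cells) {
    j <- key[cols[1], ]
    x[, j$j1, j$j2, j$j3, j$j4] <-
      rowMeans(m[, cols, drop = FALSE])
  }
  dense_tensor(
    x,
    mode_names = c("gene", "treatment", "tissue", "duration", "rest"),
    mode_categories = c(list(expression$probe_id), lev))
}

#' Replicate counts per design cell
#'
#' @param design A `study_design` tibble.
#' @return Tibble with one row per (tissue, duration, rest) combination:
#'   `n_control`, `n_treated`, and `both_present`.
#' @export
design_combination_counts <- function(design) {
  out <- dplyr::summarise(
    dplyr::group_by(design, .data$tissue, .data$duration, .data$rest),
    n_control = sum(.data$treatment == "control"),
    n_treated = sum(.data$treatment == "stress"),
    .groups = "drop")
  out$both_present <- out$n_control > 0 & out$n_treated > 0
  out
}

#' Published replicate counts of the GSE68077 stress study
#'
#' The sample layout of GEO series GSE68077 (murine tissues under repeated
#' restraint stress vs. control): replicate counts per tissue and available
#' (stress duration, rest period) combination, as published with the
#' series.  Two design cells carry no samples at all -- rest period 1.5
#' weeks after 10 days of stress, and 6 weeks after 5 days -- which is why
#' the assembled tensor zero-fills those slices.
#'
#' @return Tibble: `tissue`, `duration`, `rest`, `n_control`, `n_treated`.
#' @export
gse68077_design_counts <- function() {
  lev <- design_levels()
  combos <- tibble::tibble(
    duration = c("5 days", "5 days", "10 days", "10 days"),
    rest = c("24 hours", "1.5 weeks", "24 hours", "6 weeks"))
  # per tissue: (control, treated) for each of the four combos above
  counts <- list(
    AY        = c(3, 2, 5, 4, 3, 4, 3, 4),
    HC        = c(3, 5, 4, 5, 5, 4, 4, 5),
    MPFC      = c(4, 5, 5, 5, 3, 4, 4, 4),
    SE        = c(3, 2, 2, 3, 3, 3, 3, 3),
    ST        = c(5, 5, 5, 5, 5, 4, 4, 4),
    VS        = c(5, 5, 5, 5, 3, 4, 5, 4),
    blood     = c(5, 5, 5, 5, 4, 5, 4, 5),
    heart     = c(5, 5, 4, 5, 5, 5, 5, 5),
    hemibrain = c(5, 5, 4, 5, 5, 5, 5, 5),
    spleen    = c(5, 5, 5, 5, 5, 4, 5, 5))
  rows <- lapply(names(counts), function(tis) {
    v <- counts[[tis]]
    tibble::tibble(tissue = tis,
                   duration = combos$duration,
                   rest = combos$rest,
                   n_control = v[c(1, 3, 5, 7)],
                   n_treated = v[c(2, 4, 6, 8)])
  })
  out <- dplyr::bind_rows(rows)
  out$tissue <- factor(out$tissue, lev$tissue)
  out$duration <- factor(out$duration, lev$duration)
  out$rest <- factor(out$rest, lev$rest)
  out
}

#' Run the multi-way stress-study feature extraction
#'
#' The full real-data analysis on an assembled five-mode tensor: HOSVD;
#' automatic identification of the treatment-difference singular value
#' vector (contrast `(+1, -1)` over control/stress) and of the tissue
#' vector coexpressed in the target tissues (membership contrast, +1 for
#' targets and -1 elsewhere); core-ranked choice of `n_omega` gene singular
#' value vectors with those two condition vectors fixed; chi-squared
#' scoring, BH adjustment and selection at `threshold`.
#'
#' @param tensor Five-mode [dense_tensor()] from [assemble_tensor()].
#' @param omega_override Optional [omega_set()] bypassing the core-ranked
#'   choice.
#' @param threshold Adjusted-P selection threshold (default 0.01).
#' @param n_omega Number of gene vectors to choose (default 3).
#' @param tissue_targets Tissues expected to coexpress (default
#'   `c("AY", "HC", "heart")`).
#' @param l1,l2 Optional manual overrides for the treatment- and
#'   tissue-mode vector indices.
#' @param keep_fit Keep the full `td_hosvd` object in the result
#'   (default TRUE).
#' @return A `td_ptsd` object: list with the `selection`
#'   (a `td_selection`), the identified `l1` and `l2`, the `omega` set,
#'   `threshold`, the ranked core at the fixed indices (`core_ranking`),
#'   and optionally `fit`.
#' @export
run_ptsd_analysis <- function(tensor, omega_override = NULL,
                              threshold = 0.01, n_omega = 3,
                              tissue_targets = c("AY", "HC", "heart"),
                              l1 = NULL, l2 = NULL, keep_fit = TRUE) {
  stopifnot(inherits(tensor, "dense_tensor"))
  if (n_modes(tensor) != 5L) {
    stop("expected a five-mode tensor (gene, treatment, tissue, duration, ",
         "rest); got ", n_modes(tensor), " modes", call. = FALSE)
  }
  fit <- hosvd(tensor)
  if (is.null(l1)) {
    l1 <- find_contrast_vector(fit, "treatment", c(1, -1))
  }
  if (is.null(l2)) {
    tissues <- fit$mode_categories[["tissue"]]
    contrast <- ifelse(tissues %in% tissue_targets, 1, -1)
    l2 <- find_contrast_vector(fit, "tissue", contrast)
  }
  fixed <- list(treatment = l1, tissue = l2)
  core_ranking <- rank_core(fit, fixed, n = 20)
  omega <- if (!is.null(omega_override)) {
    as_omega(omega_override)
  } else {
    choose_omega(fit, fixed, n_vectors = n_omega, gene_mode = "gene")
  }
  scored <- score_genes(fit$factors[[1]], omega)
  sel <- select_genes(adjust_pvalues(scored, "BH"), threshold)
  structure(
    list(selection = sel, l1 = l1, l2 = l2, omega = omega,
         threshold = threshold, core_ranking = core_ranking,
         tissue_targets = tissue_targets,
         fit = if (keep_fit) fit else NULL),
    class = "td_ptsd")
}

#' @export
print.td_ptsd <- function(x, ...) {
  cat("<td_ptsd> treatment vector l1 = ", x$l1,
      ", tissue vector l2 = ", x$l2,
      " (targets: ", paste(x$tissue_targets, collapse = ", "), ")\n",
      "  omega = {", paste(x$omega$indices, collapse = ", "), "}, ",
      sum(x$selection$selected), " probes selected at adjusted P < ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' @describeIn run_ptsd_analysis Per-gene selection table.
#' @param x A `td_ptsd` object.
#' @param ... Unused.
#' @export
tidy.td_ptsd <- function(x, ...) tidy(x$selection)

#' @describeIn run_ptsd_analysis One-row run summary.
#' @export
glance.td_ptsd <- function(x, ...) {
  dplyr::mutate(glance(x$selection), l1 = x$l1, l2 = x$l2)
}

#' Condition-wise t tests of a probe set
#'
#' Validates a selected probe set by testing, for every (tissue, duration,
#' rest) combination with both control and stress samples, whether the
#' probe-set expression differs between the two groups.  The default
#' `"summary"` form reduces each sample to its mean expression over the
#' probe set and applies a Welch two-sample t test; the `"paired"` variant
#' pairs per-probe group means and applies a paired t test across probes.
#' P-values are BH-adjusted across the tested combinations.
#'
#' Combinations with fewer than two samples in either group cannot be
#' tested (Welch needs a variance per group); they are dropped with a
#' message and listed in attribute `skipped`.
#'
#' @param expression Per-replicate expression tibble (not averaged), first
#'   column `probe_id`; use the standardized matrix.
#' @param design A `study_design` covering the samples.
#' @param probes Probe identifiers to test (non-empty).
#' @param threshold Adjusted-P significance level (default 0.01).
#' @param form `"summary"` (default) or `"paired"`; see above.
#' @return Tibble with one row per tested combination: `tissue`,
#'   `duration`, `rest`, group sizes, `statistic`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
ttest_combinations <- function(expression, design, probes,
                               threshold = 0.01,
                               form = c("summary", "paired")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(expression), "probe_id" %in% names(expression))
  if (length(probes) == 0L) stop("probe set is empty", call. = FALSE)
  missing <- setdiff(probes, expression$probe_id)
  if (length(missing) > 0L) {
    stop("probes not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(expression[match(probes, expression$probe_id), -1,
                            drop = FALSE])
  combos <- design_combination_counts(design)
  combos <- combos[combos$both_present, , drop = FALSE]
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(combos))) {
    cmb <- combos[i, ]
    in_cell <- design$tissue == cmb$tissue &
      design$duration == cmb$duration & design$rest == cmb$rest
    ctrl <- design$sample_id[in_cell & design$treatment == "control"]
    trt <- design$sample_id[in_cell & design$treatment == "stress"]
    ctrl <- intersect(ctrl, colnames(m))
    trt <- intersect(trt, colnames(m))
    label <- paste(cmb$tissue, cmb$duration, cmb$rest, sep = " / ")
    tt <- tryCatch({
      if (form == "summary") {
        a <- colMeans(m[, ctrl, drop = FALSE])
        b <- colMeans(m[, trt, drop = FALSE])
        stats::t.test(b, a)  # Welch
      } else {
        a <- rowMeans(m[, ctrl, drop = FALSE])
        b <- rowMeans(m[, trt, drop = FALSE])
        stats::t.test(b, a, paired = TRUE)
      }
    }, error = function(e) e)
    if (inherits(tt, "error")) {
      skipped <- c(skipped, label)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tissue = cmb$tissue, duration = cmb$duration, rest = cmb$rest,
      n_control = length(ctrl), n_treated = length(trt),
      statistic = unname(tt$statistic), p_raw = tt$p.value)
  }
  if (length(skipped) > 0L) {
    message("skipped combination(s) that could not be tested: ",
            paste(skipped, collapse = "; "))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    out$p_adjusted <- stats::p.adjust(out$p_raw, "BH")
    out$significant <- out$p_adjusted < threshold
  }
  attr(out, "skipped") <- skipped
  attr(out, "form") <- form
  out
}
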
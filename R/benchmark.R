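#' @importFrom mclust Mclust mclustBIC
NULL

#' Rank-based AUC of a score against binary truth
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic with
#' mid-ranks for ties: the probability that a randomly chosen positive
#' outscores a randomly chosen negative.
#'
#' @param score Numeric score, larger = more likely positive.
#' @param positive Logical vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(score, positive) {
  positive <- as.logical(positive)
  stopifnot(length(score) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("need both positive and negative examples", call. = FALSE)
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the synthetic recovery benchmark
#'
#' For each trial: generate a tensor from `spec` (with the trial index
#' folded into the seed), decompose it with [hosvd()], choose `n_omega` gene
#' singular value vectors by core ranking ([choose_omega()] with no fixed
#' modes), score genes ([score_genes()]), adjust P-values and select at each
#' threshold; record the true- and false-positive rates against the planted
#' gene sets and the AUC of the continuous chi-squared statistic.
#'
#' @param spec A [synthetic_spec()].
#' @param thresholds Adjusted-P selection thresholds (default
#'   `c(0.01, 0.05, 0.1)`).
#' @param n_trials Number of independent trials to average over
#'   (default 10).
#' @param n_omega Number of gene vectors in the selection set (default 11:
#'   one direction per planted set plus one leading background direction).
#' @param omega_mode How the selection set is chosen per trial.
#'   `"leading"` (default) takes the first `n_omega` gene singular value
#'   vectors: the gene-mode singular values order vectors by explained
#'   mass, and the planted set directions add variance on top of the noise
#'   bulk, so they occupy the leading positions.  `"core-ranked"` walks
#'   the core entries by magnitude via [choose_omega()]; note that at
#'   realistic background sizes single noise core entries can outrank the
#'   planted blocks, making this mode noticeably less powerful -- it is
#'   kept for comparison.
#' @param methods P-value adjustment methods to evaluate (default `"BH"`;
#'   `"local-fdr"` may be added).
#' @param cluster If `TRUE` (default), cluster the genes selected at the
#'   smallest threshold in the first trial with both Ward and
#'   Gaussian-mixture clustering and tabulate them against the true sets.
#' @param cluster_k Number of clusters to cut/fit (default `spec$sets + 1`).
#' @return A `td_benchmark` object with elements `rates` (tibble: trial,
#'   method, threshold, tpr, fpr, n_selected), `auc` (tibble: trial, auc),
#'   `confusion` (named list of confusion matrices, if `cluster`),
#'   `spec`, `thresholds`, `n_omega`.
#' @export
run_benchmark <- function(spec, thresholds = c(0.01, 0.05, 0.1),
                          n_trials = 10, n_omega = 11,
                          omega_mode = c("leading", "core-ranked"),
                          methods = "BH", cluster = TRUE,
                          cluster_k = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  omega_mode <- match.arg(omega_mode)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (n_trials < 1) stop("need at least one trial", call. = FALSE)
  methods <- match.arg(methods, c("BH", "local-fdr"), several.ok = TRUE)
  if (is.null(cluster_k)) cluster_k <- spec$sets + 1L
  rates <- list()
  aucs <- numeric(n_trials)
  confusion <- NULL
  for (trial in seq_len(n_trials)) {
    trial_spec <- spec
    trial_spec$seed <- spec$seed + (trial - 1L)
    sim <- generate_synthetic(trial_spec)
    fit <- hosvd(sim$tensor)
    omega <- if (omega_mode == "leading") {
      omega_set(seq_len(min(n_omega, ncol(fit$factors[[1]]))))
    } else {
      choose_omega(fit, fixed = list(), n_vectors = n_omega,
                   gene_mode = "gene")
    }
    scored <- score_genes(fit$factors[[1]], omega)
    positive <- sim$truth$gene_set > 0
    aucs[trial] <- auc_score(scored$statistic, positive)
    for (method in methods) {
      adj <- adjust_pvalues(scored, method)
      for (thr in thresholds) {
        sel <- select_genes(adj, thr)
        rates[[length(rates) + 1L]] <- tibble::tibble(
          trial = trial, method = method, threshold = thr,
          tpr = mean(sel$selected[positive]),
          fpr = mean(sel$selected[!positive]),
          n_selected = sum(sel$selected))
      }
    }
    if (cluster && trial == 1L) {
      sel1 <- select_genes(adjust_pvalues(scored, methods[1]),
                           min(thresholds))
      picked <- selected_genes(sel1)
      if (length(picked) > cluster_k) {
        confusion <- lapply(
          stats::setNames(c("ward", "gaussian-mixture"),
                          c("ward", "gaussian_mixture")),
          function(meth) {
            labels <- cluster_genes(fit$factors[[1]], picked,
                                    first_vectors = min(spec$sets,
                                                        ncol(fit$factors[[1]])),
                                    method = meth, k = cluster_k)
            confusion_table(labels, sim$truth, picked)
          })
      }
    }
  }
  structure(
    list(rates = dplyr::bind_rows(rates),
         auc = tibble::tibble(trial = seq_len(n_trials), auc = aucs),
         confusion = confusion,
         spec = spec, thresholds = thresholds, n_omega = n_omega,
         omega_mode = omega_mode, methods = methods, n_trials = n_trials),
    class = "td_benchmark")
}

#' @export
print.td_benchmark <- function(x, ...) {
  cat("<td_benchmark> ", x$n_trials, " trials, ",
      x$spec$n_genes, " genes\n", sep = "")
  print(tidy(x))
  cat("mean AUC: ", format(mean(x$auc$auc), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn run_benchmark Trial-averaged TPR/FPR per method and
#'   threshold.
#' @param x A `td_benchmark`.
#' @param ... Unused.
#' @export
tidy.td_benchmark <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$rates, .data$method, .data$threshold),
    tpr = mean(.data$tpr), fpr = mean(.data$fpr),
    n_selected = mean(.data$n_selected), .groups = "drop")
}

#' @describeIn run_benchmark One-row summary with mean AUC.
#' @export
glance.td_benchmark <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials,
    n_genes = x$spec$n_genes,
    n_omega = x$n_omega,
    mean_auc = mean(x$auc$auc),
    se_auc = stats::sd(x$auc$auc) / sqrt(x$n_trials)
  )
}

#' @describeIn run_benchmark TPR/FPR versus threshold, one panel per
#'   adjustment method.
#' @param object A `td_benchmark`.
#' @export
autoplot.td_benchmark <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("tpr", "fpr"),
                            names_to = "rate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$threshold),
                                   y = .data$value,
                                   colour = .data$rate,
                                   group = .data$rate)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_colour_manual(values = c(tpr = "red", fpr = "black")) +
    ggplot2::labs(x = "adjusted-P threshold", y = "rate") +
    ggplot2::theme_bw()
}

#' Cluster genes in singular-vector space
#'
#' Embeds the chosen genes in the space of the first `first_vectors` gene
#' singular value vectors and clusters them, either by agglomerative
#' hierarchical clustering with the Ward criterion on Euclidean distances
#' (cut into `k` clusters) or by Gaussian mixture models with 1..`k`
#' components selected by BIC (via \pkg{mclust}).
#'
#' @param gene_factor Gene-mode factor matrix (genes x vectors), rownames =
#'   gene identifiers.
#' @param genes Character identifiers (or integer row indices) of the genes
#'   to cluster.
#' @param first_vectors How many leading singular vectors span the embedding
#'   (default 10).
#' @param method `"ward"` or `"gaussian-mixture"`.
#' @param k Number of clusters to cut (Ward) or the maximum number of
#'   mixture components considered (default 11).
#' @return Integer cluster labels named by gene identifier.
#' @export
cluster_genes <- function(gene_factor, genes, first_vectors = 10,
                          method = c("ward", "gaussian-mixture"), k = 11) {
  method <- match.arg(method)
  gene_factor <- as.matrix(gene_factor)
  if (first_vectors > ncol(gene_factor)) {
    stop("first_vectors exceeds the factor rank (", ncol(gene_factor), ")",
         call. = FALSE)
  }
  if (is.character(genes) && is.null(rownames(gene_factor))) {
    stop("gene_factor has no rownames; pass integer indices", call. = FALSE)
  }
  coords <- gene_factor[genes, seq_len(first_vectors), drop = FALSE]
  if (nrow(coords) < 2L) stop("need at least two genes", call. = FALSE)
  labels <- switch(
    method,
    "ward" = {
      hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
      stats::cutree(hc, k = min(k, nrow(coords)))
    },
    "gaussian-mixture" = {
      fit <- Mclust(coords, G = seq_len(min(k, nrow(coords) - 1L)),
                    verbose = FALSE)
      fit$classification
    })
  labels <- as.integer(labels)
  names(labels) <- if (is.character(genes)) genes else
    rownames(gene_factor)[genes] %||% as.character(genes)
  labels
}

#' Confusion table of cluster labels against planted gene sets
#'
#' @param labels Integer cluster labels named by gene identifier (as from
#'   [cluster_genes()]).
#' @param truth A `synthetic_truth` (or a named integer vector of true set
#'   labels, 0 = background).
#' @param genes Identifiers of the clustered genes, in label order; defaults
#'   to `names(labels)`.
#' @return An integer matrix with one row per true set plus a final
#'   `background` row, one column per cluster; entry (s, c) counts clustered
#'   genes of set s in cluster c.
#' @export
confusion_table <- function(labels, truth, genes = names(labels)) {
  gene_set <- if (inherits(truth, "synthetic_truth")) truth$gene_set else
    truth
  if (is.null(genes)) {
    stop("labels must be named by gene, or `genes` supplied", call. = FALSE)
  }
  sets <- gene_set[genes]
  if (anyNA(sets)) {
    stop("clustered genes missing from truth: ",
         paste(utils::head(genes[is.na(sets)], 5), collapse = ", "),
         call. = FALSE)
  }
  n_sets <- max(gene_set)
  set_f <- factor(ifelse(sets == 0, n_sets + 1L, sets),
                  levels = seq_len(n_sets + 1L))
  cl_f <- factor(labels, levels = sort(unique(labels)))
  tab <- table(set_f, cl_f)
  out <- matrix(as.integer(tab), nrow = n_sets + 1L,
                dimnames = list(set = c(paste0("set", seq_len(n_sets)),
                                        "background"),
                                cluster = colnames(tab)))
  out
}
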
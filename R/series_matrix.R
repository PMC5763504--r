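#' Parse a GEO Series Matrix file
#'
#' Reads the tab-delimited expression table bracketed by the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers plus
#' the `!Sample_*` metadata lines, and maps each sample's characteristics
#' onto the multi-way stress-study design (treatment, tissue, stress
#' duration, rest period).  Label parsing is keyword-based and isolated in
#' [ptsd_label_map()], so dialect changes touch one table.
#'
#' Samples whose characteristics cannot be mapped to every design field are
#' reported in a single error listing the offending samples -- they are
#' never silently dropped.
#'
#' @param path Path to a Series Matrix TXT file (uncompressed).
#' @return A list with
#'   \describe{
#'     \item{expression}{tibble, first column `probe_id`, one numeric
#'       column per sample;}
#'     \item{design}{tibble (`study_design`): `sample_id`, `treatment`,
#'       `tissue`, `duration`, `rest` (all factors with the fixed design
#'       levels), their 1-based index codes `j1..j4`, and `replicate`.}
#'   }
#' @export
parse_series_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("not a Series Matrix file: missing table begin/end markers",
         call. = FALSE)
  }
  tab <- readr::read_tsv(I(lines[(begin + 1L):(end - 1L)]),
                         show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "probe_id"
  tab$probe_id <- as.character(tab$probe_id)
  if (anyDuplicated(tab$probe_id)) {
    stop("duplicate probe identifiers in expression table", call. = FALSE)
  }
  sample_ids <- names(tab)[-1]

  meta <- lines[seq_len(begin - 1L)]
  geo_acc <- parse_meta_row(meta, "!Sample_geo_accession")
  char_rows <- meta[startsWith(meta, "!Sample_characteristics_ch1")]
  title_row <- parse_meta_row(meta, "!Sample_title")
  chars <- lapply(char_rows, split_meta_fields)
  # per sample: all characteristic strings plus the title, joined
  per_sample <- vapply(seq_along(sample_ids), function(j) {
    pos <- if (!is.null(geo_acc)) match(sample_ids[j], geo_acc) else j
    if (is.na(pos)) pos <- j
    paste(c(if (!is.null(title_row)) title_row[pos],
            vapply(chars, function(cc) cc[pos], character(1))),
          collapse = "; ")
  }, character(1))

  design <- parse_study_design(sample_ids, per_sample)
  list(expression = tab, design = design)
}

parse_meta_row <- function(meta, key) {
  row <- meta[startsWith(meta, paste0(key, "\t"))]
  if (length(row) == 0L) return(NULL)
  split_meta_fields(row[1])
}

split_meta_fields <- function(line) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]][-1]
  gsub("^\"|\"$", "", fields)
}

#' Keyword map from sample labels to design indices
#'
#' One row per recognisable keyword: the design `field`, a case-insensitive
#' regular expression `pattern`, the 1-based `index` code and the canonical
#' `label`.  Patterns are tried in row order within each field and the first
#' match wins, so more specific labels (e.g. "ventral striatum") precede
#' their substrings ("striatum").
#'
#' Index codes follow the stress-study convention: treatment 1 = control,
#' 2 = stress; tissues 1..10 = AY, HC, MPFC, SE, ST, VS, blood, heart,
#' hemibrain, spleen; stress duration 1 = 10 days, 2 = 5 days; rest period
#' 1 = 1.5 weeks, 2 = 24 hours, 3 = 6 weeks.
#'
#' @return A tibble with columns `field`, `pattern`, `index`, `label`.
#' @export
ptsd_label_map <- function() {
  tibble::tribble(
    ~field,      ~pattern,                               ~index, ~label,
    "treatment", "non[- ]?stress|no[- ]stress|unstress|control", 1L, "control",
    "treatment", "stress|treated",                           2L, "stress",
    "tissue",    "amygdala|\\bAY\\b",                        1L, "AY",
    "tissue",    "hippocampus|\\bHC\\b",                     2L, "HC",
    "tissue",    "medial prefrontal|\\bMPFC\\b",             3L, "MPFC",
    "tissue",    "septal|\\bSE\\b",                          4L, "SE",
    "tissue",    "ventral striatum|\\bVS\\b",                6L, "VS",
    "tissue",    "striatum|\\bST\\b",                        5L, "ST",
    "tissue",    "blood",                                    7L, "blood",
    "tissue",    "heart",                                    8L, "heart",
    "tissue",    "hemibrain",                                9L, "hemibrain",
    "tissue",    "spleen",                                  10L, "spleen",
    "duration",  "\\b10[- ]?d",                              1L, "10 days",
    "duration",  "\\b5[- ]?d",                               2L, "5 days",
    "rest",      "\\b1\\.5[- ]?w",                           1L, "1.5 weeks",
    "rest",      "\\b24[- ]?h",                              2L, "24 hours",
    "rest",      "\\b6[- ]?w",                               3L, "6 weeks"
  )
}

design_levels <- function() {
  map <- ptsd_label_map()
  lapply(split(map, map$field), function(d) {
    d <- d[order(d$index), ]
    d$label[!duplicated(d$index)]
  })[c("treatment", "tissue", "duration", "rest")]
}

#' Map sample label strings onto the study design
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param label_strings One free-text label string per sample (title plus
#'   characteristics).
#' @return A `study_design` tibble; see [parse_series_matrix()].
#' @export
parse_study_design <- function(sample_ids, label_strings) {
  map <- ptsd_label_map()
  fields <- c("treatment", "tissue", "duration", "rest")
  idx <- matrix(NA_integer_, nrow = length(sample_ids), ncol = 4L,
                dimnames = list(NULL, fields))
  for (f in fields) {
    sub <- map[map$field == f, ]
    for (r in seq_len(nrow(sub))) {
      hit <- is.na(idx[, f]) &
        grepl(sub$pattern[r], label_strings, ignore.case = TRUE, perl = TRUE)
      idx[hit, f] <- sub$index[r]
    }
  }
  bad <- apply(idx, 1, anyNA)
  if (any(bad)) {
    missing_fields <- vapply(which(bad), function(i) {
      paste0(sample_ids[i], " (missing: ",
             paste(fields[is.na(idx[i, ])], collapse = ", "), ")")
    }, character(1))
    stop("could not parse design labels for ", sum(bad), " sample(s):\n  ",
         paste(missing_fields, collapse = "\n  "), call. = FALSE)
  }
  lev <- design_levels()
  out <- tibble::tibble(
    sample_id = sample_ids,
    treatment = factor(lev$treatment[idx[, "treatment"]], lev$treatment),
    tissue = factor(lev$tissue[idx[, "tissue"]], lev$tissue),
    duration = factor(lev$duration[idx[, "duration"]], lev$duration),
    rest = factor(lev$rest[idx[, "rest"]], lev$rest),
    j1 = idx[, "treatment"], j2 = idx[, "tissue"],
    j3 = idx[, "duration"], j4 = idx[, "rest"])
  out <- dplyr::group_by(out, .data$treatment, .data$tissue,
                         .data$duration, .data$rest)
  out <- dplyr::mutate(out, replicate = dplyr::row_number())
  out <- dplyr::ungroup(out)
  class(out) <- c("study_design", class(out))
  out
}

#' Remove probes by identifier prefix
#'
#' Drops every probe whose identifier starts with `prefix`
#' (case-sensitive) -- used to discard control probes (prefix `"EA"`) before
#' analysis.  An empty prefix matches every probe; removing everything must
#' be confirmed explicitly.
#'
#' @param expression Expression tibble (first column `probe_id`).
#' @param prefix Identifier prefix to remove (default `"EA"`).
#' @param confirm_remove_all Must be `TRUE` to allow `prefix = ""`.
#' @return The filtered tibble; the number removed is reported via
#'   `message()` and recorded in attribute `n_removed`.
#' @export
filter_probes <- function(expression, prefix = "EA",
                          confirm_remove_all = FALSE) {
  stopifnot(is.data.frame(expression), "probe_id" %in% names(expression))
  if (identical(prefix, "") && !confirm_remove_all) {
    stop("an empty prefix removes every probe; set ",
         "confirm_remove_all = TRUE if that is intended", call. = FALSE)
  }
  drop <- startsWith(expression$probe_id, prefix)
  out <- expression[!drop, , drop = FALSE]
  message(sum(drop), " probe(s) removed by prefix '", prefix, "', ",
          nrow(out), " kept")
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Standardize each sample to mean 0 and variance 1
#'
#' Per-sample (column) z-scoring across probes with the population variance
#' (denominator n), so the stated variance of every sample is exactly 1.
#'
#' @param expression Expression tibble (first column `probe_id`).
#' @return The standardized tibble.
#' @export
standardize_samples <- function(expression) {
  stopifnot(is.data.frame(expression), "probe_id" %in% names(expression))
  m <- as.matrix(expression[, -1, drop = FALSE])
  if (nrow(m) < 2L) stop("need at least two probes", call. = FALSE)
  n_distinct <- apply(m, 2, function(col) length(unique(col)))
  if (any(n_distinct < 2L)) {
    stop("constant sample column(s): ",
         paste(colnames(m)[n_distinct < 2L], collapse = ", "),
         call. = FALSE)
  }
  z <- scale_population(m)
  out <- expression
  out[, -1] <- as.data.frame(z)
  out
}
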
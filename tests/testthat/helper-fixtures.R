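# fixtures are built in code; nothing is read from disk except files the
# helpers themselves write into tempdirs

seeded_tensor <- function(dims, seed = 1,
                          mode_names = paste0("m", seq_along(dims))) {
  set.seed(seed)
  dense_tensor(array(rnorm(prod(dims)), dims), mode_names = mode_names)
}

# minimal stress-study design: every tissue x the four observed
# (duration, rest) combinations, n replicates per treatment arm
tiny_design <- function(tissues = c("AY", "HC", "heart"),
                        n_rep = 2) {
  combos <- data.frame(
    duration = c("5 days", "5 days", "10 days", "10 days"),
    rest = c("24 hours", "1.5 weeks", "24 hours", "6 weeks"))
  rows <- expand.grid(tissue = tissues, combo = seq_len(4),
                      treatment = c("control", "stress"),
                      replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  data.frame(
    tissue = rows$tissue,
    duration = combos$duration[rows$combo],
    rest = combos$rest[rows$combo],
    treatment = rows$treatment,
    replicate = rows$replicate,
    stringsAsFactors = FALSE)
}

# write a synthetic GEO Series Matrix file; design is a data.frame with
# columns tissue/duration/rest/treatment (label text), expr a matrix with
# probes in rows and one column per design row
write_series_matrix_fixture <- function(path, design, expr,
                                        probe_ids = rownames(expr),
                                        drop_field = NULL) {
  n <- nrow(design)
  gsm <- sprintf("GSM%04d", seq_len(n))
  char_of <- function(field, value) {
    if (!is.null(drop_field) && field == drop_field$field) {
      value[drop_field$sample] <- "unknown"
    }
    paste0("\"", field, ": ", value, "\"")
  }
  lines <- c(
    "!Series_title\t\"synthetic stress study fixture\"",
    paste(c("!Sample_geo_accession",
            paste0("\"", gsm, "\"")), collapse = "\t"),
    paste(c("!Sample_title",
            paste0("\"sample ", seq_len(n), "\"")), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            char_of("tissue", design$tissue)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            char_of("stress duration", design$duration)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            char_of("rest period", design$rest)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            char_of("treatment", design$treatment)), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", paste0("\"", gsm, "\"")), collapse = "\t"))
  for (i in seq_len(nrow(expr))) {
    lines <- c(lines, paste(c(paste0("\"", probe_ids[i], "\""),
                              format(expr[i, ], digits = 10)),
                            collapse = "\t"))
  }
  lines <- c(lines, "!series_matrix_table_end")
  writeLines(lines, path)
  invisible(path)
}

# expression matrix for a design with a planted stress effect: a shared
# per-gene baseline (as in real expression data, where gene-level
# expression dominates condition effects), i.i.d. noise, and genes
# `hit_genes` shifted by `delta` in stress samples of `hit_tissues`
planted_study_matrix <- function(design, n_genes = 200, hit_genes = 1:20,
                                 hit_tissues = c("AY", "HC", "heart"),
                                 delta = 3, baseline_sd = 2, seed = 5) {
  set.seed(seed)
  baseline <- rnorm(n_genes, sd = baseline_sd)
  m <- baseline + matrix(rnorm(n_genes * nrow(design)), n_genes,
                         nrow(design))
  hit_cols <- design$treatment == "stress" & design$tissue %in% hit_tissues
  m[hit_genes, hit_cols] <- m[hit_genes, hit_cols] + delta
  rownames(m) <- sprintf("A_51_P%04d", seq_len(n_genes))
  m
}

expr_tibble <- function(m, sample_ids) {
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- sample_ids
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)), df)
}
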
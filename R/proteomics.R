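#' Classify a ribosomal protein gene symbol by subunit
#'
#' Cytoplasmic small-subunit proteins (RpS1, RpS3, ..., RpSA) map to
#' `"SSU"`, large-subunit proteins (RpL*, including the P-stalk RpLP0-2) to
#' `"LSU"`; mitochondrial ribosomal proteins (mRpS*/mRpL*) and anything else
#' map to `"other"`. Matching is case-insensitive and vectorised.
#'
#' @param gene_symbol character vector of gene symbols.
#' @return character vector in `{"SSU", "LSU", "other"}`.
#' @export
classify_ribosomal <- function(gene_symbol) {
  if (!length(gene_symbol) || any(!nzchar(gene_symbol)))
    stop("gene symbols must be non-empty strings")
  s <- tolower(trimws(gene_symbol))
  out <- rep("other", length(s))
  mito <- grepl("^mrp[sl]", s)
  out[!mito & grepl("^rps", s)] <- "SSU"
  out[!mito & grepl("^rpl", s)] <- "LSU"
  out
}

#' Assemble a per-protein log-fold-change table
#'
#' One row per protein per comparison: `protein_id`, `gene_symbol`,
#' `subunit_class` (derived with [classify_ribosomal()] when absent),
#' `comparison`, `lfc` (log2 fold change vs wild type). When replicate
#' columns are supplied they are averaged into a single `lfc` per protein
#' (`merge_replicates`).
#'
#' @param df data frame with at least `protein_id`, `gene_symbol` and either
#'   `lfc` or replicate columns matching `lfc_rep\\d+`.
#' @param comparison comparison label applied to rows lacking one.
#' @param merge_replicates average `lfc_rep*` columns into `lfc`.
#' @return a validated `protein_table` data frame.
#' @export
protein_table <- function(df, comparison = "vs_wt", merge_replicates = TRUE) {
  stopifnot(is.data.frame(df), all(c("protein_id", "gene_symbol") %in% names(df)))
  if (!"lfc" %in% names(df)) {
    reps <- grep("^lfc_rep[0-9]+$", names(df), value = TRUE)
    if (!length(reps) || !merge_replicates)
      stop("need an 'lfc' column or lfc_rep* replicate columns")
    df$lfc <- rowMeans(df[reps])
  }
  if (!"comparison" %in% names(df)) df$comparison <- comparison
  if (!"subunit_class" %in% names(df))
    df$subunit_class <- classify_ribosomal(df$gene_symbol)
  if (anyDuplicated(df[c("protein_id", "comparison")]))
    stop("protein_id must be unique within a comparison")
  if (any(!is.finite(df$lfc))) stop("lfc values must be finite")
  class(df) <- c("protein_table", "data.frame")
  df
}

#' Ribosomal subunit stoichiometry summary
#'
#' Per-class (SSU, LSU) summary of a log-fold-change table for one
#' comparison: n, mean log2 fold change, 95% Student-t confidence interval
#' of the mean, a two-sided one-sample Wilcoxon signed-rank test against 0,
#' and a two-sided Mann-Whitney U test between the SSU and LSU values. This
#' is the stoichiometric-imbalance readout: a negative SSU mean with a
#' non-matching LSU mean indicates subunit imbalance.
#'
#' @param table a [protein_table] (or plain data frame with the same columns).
#' @param comparison which comparison to summarize (default: the only one
#'   present; required if several).
#' @param level confidence level for the CI.
#' @param ci_method `"t"` for the Student-t CI, `"bootstrap"` for a
#'   percentile bootstrap (2000 resamples).
#' @return an `imbalance_summary`: list with `classes` (data frame with one
#'   row per class: n, mean_lfc, ci_lower, ci_upper, p_vs_zero),
#'   `p_ssu_vs_lsu`, and `comparison`.
#' @export
summarize_imbalance <- function(table, comparison = NULL, level = 0.95,
                                ci_method = c("t", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  comps <- unique(table$comparison)
  if (is.null(comparison)) {
    if (length(comps) != 1L)
      stop("table holds several comparisons; pick one of: ",
           paste(comps, collapse = ", "))
    comparison <- comps
  }
  tab <- table[table$comparison == comparison, , drop = FALSE]
  rows <- lapply(c("SSU", "LSU"), function(cl) {
    v <- tab$lfc[tab$subunit_class == cl]
    if (length(v) < 2L)
      stop("class ", cl, " has fewer than 2 proteins in comparison '",
           comparison, "'")
    ci <- if (ci_method == "t") mean_ci(v, level) else boot_ci(v, level)
    p <- tryCatch(one_sample_wilcoxon(v, 0)$p_value,
                  error = function(e) NA_real_)  # degenerate all-zero class
    data.frame(subunit_class = cl, n = length(v), mean_lfc = mean(v),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               p_vs_zero = p)
  })
  classes <- do.call(rbind, rows)
  p_between <- mann_whitney_u(tab$lfc[tab$subunit_class == "SSU"],
                              tab$lfc[tab$subunit_class == "LSU"])$p_value
  structure(list(classes = classes, p_ssu_vs_lsu = p_between,
                 comparison = comparison, ci_method = ci_method),
            class = "imbalance_summary")
}

boot_ci <- function(v, level, n_boot = 2000L) {
  means <- vapply(seq_len(n_boot),
                  function(i) mean(sample(v, replace = TRUE)), numeric(1))
  q <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' @export
print.imbalance_summary <- function(x, ...) {
  cat(sprintf("Ribosomal subunit imbalance summary (%s; %s CI)\n",
              x$comparison, x$ci_method))
  print(x$classes, row.names = FALSE, digits = 4)
  cat(sprintf("SSU vs LSU (two-sided Mann-Whitney): p = %.4g\n",
              x$p_ssu_vs_lsu))
  invisible(x)
}
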
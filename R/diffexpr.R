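#' Unpaired two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] returning the two-sided t statistic
#' and p-value; the sign of t follows `mean(case) - mean(control)`. The
#' default is Welch's unequal-variance form; `variant = "student"` uses the
#' classical pooled-variance test.
#'
#' @param case_values,control_values Numeric vectors, at least 2 values each.
#' @param variant `"welch"` (default) or `"student"`.
#' @return A list with elements `t` and `p`.
#' @export
ttest_unpaired <- function(case_values, control_values,
                           variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(case_values) < 2L || length(control_values) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  fit <- stats::t.test(case_values, control_values,
                       var.equal = (variant == "student"))
  list(t = unname(fit$statistic), p = unname(fit$p.value))
}

# Vectorized row-wise unpaired t-tests (genefilter-style): one test per gene
# row of paired case/control matrices. Identical to looping stats::t.test
# over rows but orders of magnitude faster at matrix scale.
row_ttests <- function(case_mat, control_mat, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(nrow(case_mat) == nrow(control_mat))
  n1 <- ncol(case_mat); n2 <- ncol(control_mat)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples", call. = FALSE)
  m1 <- rowMeans(case_mat); m2 <- rowMeans(control_mat)
  v1 <- rowSums((case_mat - m1)^2) / (n1 - 1)
  v2 <- rowSums((control_mat - m2)^2) / (n2 - 1)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  data.frame(t = t, p = p, df = df, row.names = rownames(case_mat))
}

#' Log2 fold change between case and control
#'
#' For data already on the log2 scale the fold change is the difference of
#' group means: `logFC = mean(case) - mean(control)`.
#'
#' @inheritParams ttest_unpaired
#' @return Numeric scalar.
#' @export
log_fold_change <- function(case_values, control_values) {
  if (length(case_values) == 0L || length(control_values) == 0L) {
    stop("empty group", call. = FALSE)
  }
  mean(case_values) - mean(control_values)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()]; the one
#' implementation shared by the differential-expression and enrichment
#' modules.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene differential-expression statistics for one study
#'
#' Runs unpaired t-tests per gene on `study` (normally the Z-score
#' normalized matrix; the t statistic is invariant to the per-gene affine
#' Z transform) and computes logFC on `lfc_study` (normally the
#' pre-normalization log2 matrix, where mean differences are fold changes).
#' If `lfc_study` is `NULL` both come from `study`.
#'
#' @param study `expression_study` used for the t-tests.
#' @param lfc_study Optional `expression_study` used for logFC; must share
#'   genes and samples with `study`.
#' @param variant t-test variant, see [ttest_unpaired()].
#' @return A `gene_stat_table` data frame with columns `gene`, `t`, `p`,
#'   `p_adj`, `logFC`, `direction` (all `"none"` until thresholds are
#'   applied by [select_significant()]).
#' @export
gene_stats <- function(study, lfc_study = NULL, variant = c("welch", "student")) {
  stopifnot(inherits(study, "expression_study"))
  variant <- match.arg(variant)
  if (is.null(lfc_study)) lfc_study <- study
  stopifnot(inherits(lfc_study, "expression_study"))
  genes <- intersect(rownames(study$values), rownames(lfc_study$values))
  tt <- row_ttests(case_matrix(study)[genes, , drop = FALSE],
                   control_matrix(study)[genes, , drop = FALSE],
                   variant = variant)
  lfc <- rowMeans(case_matrix(lfc_study)[genes, , drop = FALSE]) -
    rowMeans(control_matrix(lfc_study)[genes, , drop = FALSE])
  out <- data.frame(gene = genes, t = tt$t, p = tt$p,
                    p_adj = bh_adjust(tt$p), logFC = unname(lfc),
                    direction = "none",
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_stat_table", class(out))
  out
}

#' Select significantly up- and down-regulated genes
#'
#' Applies the joint significance rule: a gene is up-regulated when
#' `p* <= p_cutoff` and `logFC >= lfc_cutoff`, down-regulated when
#' `p* <= p_cutoff` and `logFC <= -lfc_cutoff`, where `p*` is the
#' BH-adjusted p-value by default (`use_adjusted = FALSE` switches to the
#' raw p-value).
#'
#' @param table A `gene_stat_table` from [gene_stats()].
#' @param disease_id Identifier stored on the resulting set.
#' @param p_cutoff Significance cutoff (default 0.01).
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 1).
#' @param use_adjusted Use the BH-adjusted p-value (default `TRUE`).
#' @return A `disease_gene_set`: fields `disease_id`, `up`, `down`,
#'   `thresholds`, and `table` (the input with the `direction` column
#'   filled in).
#' @export
select_significant <- function(table, disease_id = "study", p_cutoff = 0.01,
                               lfc_cutoff = 1, use_adjusted = TRUE) {
  stopifnot(inherits(table, "gene_stat_table") ||
              all(c("gene", "p", "p_adj", "logFC") %in% names(table)))
  assert_scalar_num(p_cutoff, "p_cutoff", lower = 0, upper = 1)
  assert_scalar_num(lfc_cutoff, "lfc_cutoff", lower = 0)
  assert_flag(use_adjusted, "use_adjusted")
  pstar <- if (use_adjusted) table$p_adj else table$p
  up <- !is.na(pstar) & pstar <= p_cutoff & table$logFC >= lfc_cutoff
  down <- !is.na(pstar) & pstar <= p_cutoff & table$logFC <= -lfc_cutoff
  table$direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  structure(
    list(disease_id = disease_id,
         up = sort(table$gene[up]), down = sort(table$gene[down]),
         thresholds = list(p_cutoff = p_cutoff, lfc_cutoff = lfc_cutoff,
                           use_adjusted = use_adjusted),
         table = table),
    class = "disease_gene_set")
}

#' @export
print.disease_gene_set <- function(x, ...) {
  cat(sprintf("disease_gene_set '%s': %d up, %d down (p<=%g, |logFC|>=%g, %s p)\n",
              x$disease_id, length(x$up), length(x$down),
              x$thresholds$p_cutoff, x$thresholds$lfc_cutoff,
              if (x$thresholds$use_adjusted) "adjusted" else "raw"))
  invisible(x)
}

#' Write a gene-stat table / disease gene set to disk
#'
#' `write_gene_stats()` writes the fixed column order
#' `gene, t, p, p_adj, logFC, direction`; `write_gene_set()` writes the
#' two-column `(gene, direction)` text consumed by downstream tools.
#' @param table A `gene_stat_table`.
#' @param path Output path.
#' @export
write_gene_stats <- function(table, path) {
  write_tsv_det(table[, c("gene", "t", "p", "p_adj", "logFC", "direction")], path)
}

#' @rdname write_gene_stats
#' @param set A `disease_gene_set`.
#' @export
write_gene_set <- function(set, path) {
  df <- data.frame(
    gene = c(set$up, set$down),
    direction = rep(c("up", "down"), c(length(set$up), length(set$down))),
    stringsAsFactors = FALSE)
  write_tsv_det(df[order(df$gene), , drop = FALSE], path)
}
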
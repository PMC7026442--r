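#' Construct an expression study
#'
#' The basic container of the package: a log-scale gene x sample matrix with
#' a case/control label per sample. Gene symbols are upper-cased so that
#' studies from different platforms can be intersected by symbol.
#'
#' @param study_id Character scalar.
#' @param values Numeric matrix, rows = genes (rownames = symbols),
#'   columns = samples (colnames = sample ids).
#' @param group Character vector of `"case"`/`"control"`, either named by
#'   sample id or in column order.
#' @return An object of class `expression_study` with fields `study_id`,
#'   `values`, `group`.
#' @export
expression_study <- function(study_id, values, group) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) == 0L ||
      ncol(values) == 0L) {
    stop("`values` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene rownames and sample colnames", call. = FALSE)
  }
  rownames(values) <- norm_symbols(rownames(values))
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (!is.null(names(group))) {
    if (!all(colnames(values) %in% names(group))) {
      stop("every sample needs a group label", call. = FALSE)
    }
    group <- group[colnames(values)]
  } else {
    if (length(group) != ncol(values)) {
      stop("every sample needs a group label", call. = FALSE)
    }
    names(group) <- colnames(values)
  }
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  }
  group <- stats::setNames(as.character(group), names(group))
  structure(list(study_id = study_id, values = values, group = group),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study '%s': %d genes x %d samples (%d case / %d control)\n",
              x$study_id, nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

case_matrix <- function(study) study$values[, study$group == "case", drop = FALSE]
control_matrix <- function(study) study$values[, study$group == "control", drop = FALSE]

#' Read / write a tab-separated expression matrix
#'
#' The layout is the plain series-matrix-like table used throughout the
#' package: first column the gene (or probe) id, header row the sample ids,
#' tab-separated numeric values.
#'
#' @param path File path.
#' @param label_map Named character vector `sample id -> "case"/"control"`.
#' @param study_id Study identifier; defaults to the file name.
#' @param strict If `TRUE` (default) samples missing from `label_map` are an
#'   error; if `FALSE` they are dropped with a message.
#' @return An `expression_study`.
#' @export
read_expression <- function(path, label_map, study_id = NULL, strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error: empty expression matrix", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (length(samples) == 0L) stop("parse error: no sample columns", call. = FALSE)
  if (anyDuplicated(samples)) {
    stop(sprintf("parse error: duplicated sample id '%s'",
                 samples[duplicated(samples)][1L]), call. = FALSE)
  }
  width <- length(header)
  n_fields <- lengths(fields)
  bad <- which(n_fields != width)
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d: %d fields, expected %d",
                 bad[1L], n_fields[bad[1L]], width), call. = FALSE)
  }
  body <- fields[-1L]
  ids <- vapply(body, `[[`, character(1), 1L)
  mat <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE))),
    nrow = length(body), byrow = TRUE,
    dimnames = list(norm_symbols(ids), samples))

  missing <- setdiff(samples, names(label_map))
  if (length(missing) > 0L) {
    if (strict) {
      stop(sprintf("samples missing from label map: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    message(sprintf("dropping %d unlabelled sample(s)", length(missing)))
    mat <- mat[, setdiff(samples, missing), drop = FALSE]
  }
  if (is.null(study_id)) study_id <- tools::file_path_sans_ext(basename(path))
  expression_study(study_id, mat, label_map[colnames(mat)])
}

#' @rdname read_expression
#' @param study An `expression_study` to write.
#' @export
write_expression <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$values), study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_det(df, path)
}

#' Write / read the sample label table of a study
#'
#' Two columns, `sample` and `group`, tab-separated. `read_labels()` returns
#' the named character vector accepted by [read_expression()].
#' @param study An `expression_study`.
#' @param path File path.
#' @export
write_labels <- function(study, path) {
  write_tsv_det(data.frame(sample = names(study$group), group = study$group,
                           stringsAsFactors = FALSE), path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$group, df$sample)
}

#' Collapse probe-level rows to one row per gene symbol
#'
#' Microarray platforms carry several probes per gene; downstream modules
#' need one row per symbol. The retained probe is chosen by `policy`:
#' `"max_mean"` keeps the probe with the highest mean expression (the usual
#' brightest-probe rule), `"max_abs_t"` the probe with the largest absolute
#' case-vs-control t statistic, `"first"` the first probe in file order.
#'
#' @param study An `expression_study` whose rownames are probe ids.
#' @param probe_to_gene Two-column data frame (`probe`, `gene`) or a named
#'   character vector `probe -> gene`.
#' @param policy One of `"max_mean"`, `"max_abs_t"`, `"first"`.
#' @param variant t-test variant used by `"max_abs_t"` (see
#'   [ttest_unpaired()]).
#' @return An `expression_study` with unique gene-symbol rownames; the
#'   number of unmapped probes dropped is attached as attribute
#'   `"n_unmapped"` and reported with a message.
#' @export
collapse_probes <- function(study, probe_to_gene,
                            policy = c("max_mean", "max_abs_t", "first"),
                            variant = c("welch", "student")) {
  stopifnot(inherits(study, "expression_study"))
  policy <- match.arg(policy)
  variant <- match.arg(variant)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(norm_symbols(probe_to_gene[[2L]]),
                           norm_symbols(probe_to_gene[[1L]]))
  } else {
    map <- stats::setNames(norm_symbols(probe_to_gene),
                           norm_symbols(names(probe_to_gene)))
  }
  if (length(map) == 0L) stop("empty probe-to-gene mapping", call. = FALSE)

  probes <- rownames(study$values)
  mapped <- probes %in% names(map)
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0L) {
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)", n_unmapped))
  }
  keep <- which(mapped)
  genes <- map[probes[keep]]

  score <- switch(policy,
    max_mean = rowMeans(study$values[keep, , drop = FALSE]),
    max_abs_t = {
      tt <- row_ttests(case_matrix(study)[keep, , drop = FALSE],
                       control_matrix(study)[keep, , drop = FALSE],
                       variant = variant)
      abs(tt$t)
    },
    first = -seq_along(keep)  # earlier probe = higher score
  )
  ord <- order(genes, -score)
  chosen <- keep[ord][!duplicated(genes[ord])]
  chosen <- chosen[order(match(probes[chosen], probes))]

  mat <- study$values[chosen, , drop = FALSE]
  rownames(mat) <- unname(map[probes[chosen]])
  out <- expression_study(study$study_id, mat, study$group)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Z-score normalize a study gene-wise
#'
#' Standardizes each gene row across all samples of the study:
#' `Z_ij = (g_ij - mean(g_i)) / SD(g_i)` with the sample (n-1) standard
#' deviation, so that expression from different platforms becomes directly
#' comparable. Rows with zero variance or any missing value cannot be
#' standardized and are dropped (and flagged), never silently zeroed.
#'
#' @param study An `expression_study`.
#' @return The standardized `expression_study`; dropped gene symbols are in
#'   attribute `"dropped_genes"`.
#' @export
zscore_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  v <- study$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  bad <- !is.finite(mu) | !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    message(sprintf("zscore_normalize: dropping %d constant/missing gene row(s)",
                    sum(bad)))
  }
  z <- (v[!bad, , drop = FALSE] - mu[!bad]) / sdv[!bad]
  if (nrow(z) == 0L) stop("no genes left after dropping constant rows", call. = FALSE)
  out <- expression_study(study$study_id, z, study$group)
  attr(out, "dropped_genes") <- rownames(v)[bad]
  out
}
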
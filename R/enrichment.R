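#' Load a GMT gene-set library
#'
#' Standard GMT: one term per line, fields `term`, `description`, then the
#' member gene symbols, tab-separated. Gene symbols are upper-cased; the
#' background universe defaults to the union of all member genes.
#'
#' @param path GMT file.
#' @param name Library name; defaults to the file name.
#' @return A `gene_set_library`: `name`, `terms` (named list of gene-symbol
#'   vectors), `descriptions`, `background` (universe size).
#' @export
load_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT parse error at line %d: fewer than 3 fields", short[1L]),
         call. = FALSE)
  }
  term_names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(term_names)) {
    stop(sprintf("duplicated term '%s'", term_names[duplicated(term_names)][1L]),
         call. = FALSE)
  }
  terms <- lapply(fields, function(f) sort(unique(norm_symbols(f[-c(1L, 2L)]))))
  names(terms) <- term_names
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), term_names)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  structure(
    list(name = name, terms = terms, descriptions = desc,
         background = length(unique(unlist(terms, use.names = FALSE)))),
    class = "gene_set_library")
}

#' @rdname load_gmt
#' @param library A `gene_set_library` to write.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$terms), function(tm) {
    paste(c(tm, library$descriptions[[tm]], library$terms[[tm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher-exact over-representation of a query gene set
#'
#' For each term of the library, tests over-representation of the query in
#' the term with the one-sided (greater) Fisher exact test on the 2x2 table
#' (overlap, query-only, term-only, neither) — the hypergeometric upper
#' tail — then adjusts p-values across the library's terms with
#' Benjamini-Hochberg. This is the statistical core of Enrichr-style
#' enrichment; the background universe defaults to the library's own gene
#' union.
#'
#' @param query Character vector of gene symbols (non-empty).
#' @param library A `gene_set_library`.
#' @param background_n Background universe size; defaults to
#'   `library$background`. Must be at least `|query union term|` for every
#'   term.
#' @return Data frame of class `enrichment_table`, one row per term:
#'   `term`, `overlap_genes` (comma-joined), `overlap`, `term_size`,
#'   `odds_ratio`, `p`, `p_adj`; sorted by `p_adj` then term.
#' @export
fisher_enrichment <- function(query, library, background_n = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  query <- unique(norm_symbols(query))
  if (length(query) == 0L) stop("empty query gene set", call. = FALSE)
  N <- if (is.null(background_n)) library$background else
    assert_count(background_n, "background_n")

  rows <- lapply(names(library$terms), function(tm) {
    ts <- library$terms[[tm]]
    ov <- intersect(query, ts)
    if (length(union(query, ts)) > N) {
      stop(sprintf("background (%d) smaller than |query union '%s'|", N, tm),
           call. = FALSE)
    }
    k <- length(ov); K <- length(ts); nq <- length(query)
    # one-sided Fisher p = P(X >= k), X ~ Hypergeom(N, K, nq)
    p <- stats::phyper(k - 1L, K, N - K, nq, lower.tail = FALSE)
    a <- k; b <- nq - k; cc <- K - k; d <- N - nq - K + k
    or <- (a * d) / (b * cc)
    data.frame(term = tm, overlap_genes = paste(sort(ov), collapse = ","),
               overlap = k, term_size = K, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p_adj, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Write an enrichment table
#'
#' Tab-separated with the reporting layout term / member genes / adjusted p
#' (plus the supporting counts and raw p).
#' @param table An `enrichment_table`.
#' @param path Output file.
#' @export
write_enrichment <- function(table, path) {
  write_tsv_det(table[, c("term", "overlap_genes", "overlap", "term_size",
                          "odds_ratio", "p", "p_adj")], path)
}
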
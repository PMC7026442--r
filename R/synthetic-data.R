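#' Specify a synthetic expression study
#'
#' A study spec fixes the gene universe, arm sizes, the planted up- and
#' down-regulated gene sets, the mean log2 shift of planted genes and the
#' per-gene noise level. [generate_expression_study()] turns a spec into a
#' gene x sample matrix with known ground truth.
#'
#' @param study_id Character scalar identifying the study.
#' @param n_genes Number of genes in the universe; gene ids are
#'   `G000001 ... G<n_genes>` unless `gene_ids` is supplied.
#' @param n_case,n_control Number of case / control samples.
#' @param de_up,de_down Character vectors of gene ids planted up- and
#'   down-regulated in cases. Must be disjoint subsets of the universe.
#' @param effect_size Mean log2 shift (> 0) applied to planted genes
#'   (positive for `de_up`, negative for `de_down`).
#' @param noise_sd Per-gene Gaussian noise standard deviation (> 0).
#' @param seed Integer seed making generation deterministic.
#' @param gene_ids Optional explicit gene universe (length `n_genes`).
#'
#' @return An object of class `study_spec`.
#' @seealso [generate_expression_study()], [generate_linked_studies()]
#' @export
study_spec <- function(study_id, n_genes, n_case, n_control,
                       de_up = character(), de_down = character(),
                       effect_size = 2, noise_sd = 0.5, seed = 1L,
                       gene_ids = NULL) {
  stopifnot(is.character(study_id), length(study_id) == 1L, nzchar(study_id))
  n_genes <- assert_count(n_genes, "n_genes")
  n_case <- assert_count(n_case, "n_case")
  n_control <- assert_count(n_control, "n_control")
  assert_scalar_num(effect_size, "effect_size", lower = 0, open_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%06d", seq_len(n_genes))
  }
  gene_ids <- norm_symbols(gene_ids)
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    stop("`gene_ids` must be `n_genes` unique symbols", call. = FALSE)
  }
  de_up <- norm_symbols(de_up)
  de_down <- norm_symbols(de_down)
  if (length(intersect(de_up, de_down)) > 0L) {
    stop("invalid spec: `de_up` and `de_down` overlap", call. = FALSE)
  }
  if (!all(de_up %in% gene_ids) || !all(de_down %in% gene_ids)) {
    stop("invalid spec: planted genes outside the gene universe", call. = FALSE)
  }
  structure(
    list(study_id = study_id, n_genes = n_genes, n_case = n_case,
         n_control = n_control, de_up = de_up, de_down = de_down,
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed), gene_ids = gene_ids),
    class = "study_spec"
  )
}

#' Generate an expression study with planted differential expression
#'
#' Draws a log2-scale expression matrix: every gene gets a baseline level
#' (Gaussian around 7, the typical mid-range of log2 microarray intensities),
#' i.i.d. Gaussian noise with `noise_sd`, and planted genes additionally get
#' `+effect_size` (`de_up`) or `-effect_size` (`de_down`) in case samples.
#' The expected case-minus-control mean difference therefore equals the
#' planted log2 fold change.
#'
#' @param spec A [study_spec()].
#' @return An [expression_study()] with samples `"<id>_case_i"` /
#'   `"<id>_ctrl_i"` and the spec attached as attribute `"spec"`.
#' @export
generate_expression_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  n_s <- spec$n_case + spec$n_control
  with_seed(spec$seed, {
    baseline <- stats::rnorm(spec$n_genes, mean = 7, sd = 1.5)
    mat <- baseline + matrix(stats::rnorm(spec$n_genes * n_s, sd = spec$noise_sd),
                             nrow = spec$n_genes, ncol = n_s)
    case_cols <- seq_len(spec$n_case)
    up_rows <- match(spec$de_up, spec$gene_ids)
    down_rows <- match(spec$de_down, spec$gene_ids)
    mat[up_rows, case_cols] <- mat[up_rows, case_cols] + spec$effect_size
    mat[down_rows, case_cols] <- mat[down_rows, case_cols] - spec$effect_size
    samples <- c(sprintf("%s_case_%02d", spec$study_id, seq_len(spec$n_case)),
                 sprintf("%s_ctrl_%02d", spec$study_id, seq_len(spec$n_control)))
    dimnames(mat) <- list(spec$gene_ids, samples)
    group <- stats::setNames(
      rep(c("case", "control"), c(spec$n_case, spec$n_control)), samples)
    out <- expression_study(spec$study_id, mat, group)
    attr(out, "spec") <- spec
    out
  })
}

#' Generate an exposure study plus disease studies with planted overlaps
#'
#' Emulates the cross-study design in which an exposure signature shares a
#' known number of dysregulated genes with each disease: each disease study's
#' planted sets are exactly the requested shared genes (taken from the
#' exposure's planted sets) plus the disease spec's own private genes.
#'
#' @param exposure A [study_spec()] for the exposure study.
#' @param diseases List of [study_spec()]s; their `de_up`/`de_down` are the
#'   disease-private planted genes and must not overlap the exposure's
#'   planted sets (otherwise ground-truth overlap counts would be wrong).
#' @param shared_up,shared_down Named lists / maps `disease_id -> gene set`;
#'   every shared gene must be planted in the exposure in that direction.
#' @return A `linked_studies` object: `$studies` (exposure first, then the
#'   diseases) and `$ground_truth` with planted sets and true per-disease
#'   overlap counts.
#' @export
generate_linked_studies <- function(exposure, diseases,
                                    shared_up = list(), shared_down = list()) {
  stopifnot(inherits(exposure, "study_spec"))
  ids <- vapply(diseases, function(d) d$study_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate disease study ids", call. = FALSE)
  exposure_planted <- c(exposure$de_up, exposure$de_down)

  specs <- lapply(diseases, function(d) {
    su <- norm_symbols(shared_up[[d$study_id]] %||% character())
    sd_ <- norm_symbols(shared_down[[d$study_id]] %||% character())
    if (!all(su %in% exposure$de_up)) {
      stop(sprintf("invalid spec: shared up genes for '%s' not planted up in exposure",
                   d$study_id), call. = FALSE)
    }
    if (!all(sd_ %in% exposure$de_down)) {
      stop(sprintf("invalid spec: shared down genes for '%s' not planted down in exposure",
                   d$study_id), call. = FALSE)
    }
    if (length(intersect(c(d$de_up, d$de_down), exposure_planted)) > 0L) {
      stop(sprintf("invalid spec: private genes of '%s' overlap the exposure's planted sets",
                   d$study_id), call. = FALSE)
    }
    study_spec(d$study_id, d$n_genes, d$n_case, d$n_control,
               de_up = union(su, d$de_up), de_down = union(sd_, d$de_down),
               effect_size = d$effect_size, noise_sd = d$noise_sd,
               seed = d$seed, gene_ids = d$gene_ids)
  })

  studies <- c(list(generate_expression_study(exposure)),
               lapply(specs, generate_expression_study))
  names(studies) <- c(exposure$study_id, ids)

  truth <- list(
    exposure_id = exposure$study_id,
    planted = lapply(studies, function(s) {
      sp <- attr(s, "spec")
      list(up = sp$de_up, down = sp$de_down)
    }),
    shared_up = lapply(stats::setNames(ids, ids), function(i)
      norm_symbols(shared_up[[i]] %||% character())),
    shared_down = lapply(stats::setNames(ids, ids), function(i)
      norm_symbols(shared_down[[i]] %||% character()))
  )
  truth$overlap_counts <- vapply(ids, function(i) {
    length(truth$shared_up[[i]]) + length(truth$shared_down[[i]])
  }, integer(1))

  structure(list(studies = studies, ground_truth = truth),
            class = "linked_studies")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a synthetic survival cohort
#'
#' Event times follow a proportional-hazards model: patient i's hazard is
#' `exp(beta' x_i) / baseline_scale` with exponential baseline, where `x_i`
#' is the vector of binary per-gene alteration indicators. Censoring is an
#' independent exponential whose rate is solved numerically so that the
#' expected censored fraction equals `censor_rate`.
#'
#' @param n_patients Number of patients.
#' @param gene_ids Character vector of gene symbols carried by the cohort.
#' @param beta_true Numeric vector of planted Cox log-hazard coefficients,
#'   one per gene (recycled scalar allowed).
#' @param clinical_factors Named list `factor name -> character vector of
#'   levels`; sampled independently of gene status unless `confound > 0`.
#' @param baseline_scale Mean of the exponential baseline event time
#'   (months, > 0).
#' @param censor_rate Target fraction of censored patients in `[0, 1)`.
#' @param alteration_rate Per-gene probability that a patient is altered,
#'   in `(0, 1)`.
#' @param seed Integer seed.
#' @param confound Mixing weight in `[0, 1]`: probability that the first
#'   clinical factor's level is copied from the first gene's alteration
#'   status rather than drawn independently (0 = clean null).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, gene_ids, beta_true = 0,
                        clinical_factors = list(), baseline_scale = 60,
                        censor_rate = 0.3, alteration_rate = 0.25,
                        seed = 1L, confound = 0) {
  n_patients <- assert_count(n_patients, "n_patients")
  gene_ids <- norm_symbols(gene_ids)
  stopifnot(length(gene_ids) >= 1L, !anyDuplicated(gene_ids))
  beta_true <- rep_len(as.numeric(beta_true), length(gene_ids))
  names(beta_true) <- gene_ids
  assert_scalar_num(baseline_scale, "baseline_scale", lower = 0, open_lower = TRUE)
  assert_scalar_num(censor_rate, "censor_rate", lower = 0, upper = 1, open_upper = TRUE)
  assert_scalar_num(alteration_rate, "alteration_rate", lower = 0, upper = 1,
                    open_lower = TRUE, open_upper = TRUE)
  assert_scalar_num(confound, "confound", lower = 0, upper = 1)
  if (length(clinical_factors) > 0L) {
    stopifnot(!is.null(names(clinical_factors)), all(nzchar(names(clinical_factors))))
  }
  structure(
    list(n_patients = n_patients, gene_ids = gene_ids, beta_true = beta_true,
         clinical_factors = clinical_factors, baseline_scale = baseline_scale,
         censor_rate = censor_rate, alteration_rate = alteration_rate,
         seed = as.integer(seed), confound = confound),
    class = "cohort_spec"
  )
}

#' Generate a survival cohort from a proportional-hazards model
#'
#' @param spec A [cohort_spec()].
#' @return A `survival_cohort`: `$time` (months), `$event` (1 = event,
#'   0 = censored), `$status` (patients x genes logical alteration matrix),
#'   `$clinical` (data frame of categorical factors), `$patient_id`. The
#'   planted coefficients are attached as attribute `"beta_true"`.
#' @export
generate_survival_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    g <- length(spec$gene_ids)
    status <- matrix(stats::runif(n * g) < spec$alteration_rate, nrow = n,
                     dimnames = list(NULL, spec$gene_ids))
    lp <- drop(status %*% spec$beta_true)
    rate <- exp(lp) / spec$baseline_scale
    t_event <- stats::rexp(n, rate = rate)

    if (spec$censor_rate > 0) {
      # Solve for the censoring rate c with mean_i c/(c + rate_i) = censor_rate.
      target <- spec$censor_rate
      f <- function(cc) mean(cc / (cc + rate)) - target
      c_rate <- stats::uniroot(f, lower = 1e-10, upper = 1e10,
                               tol = 1e-12)$root
      t_cens <- stats::rexp(n, rate = c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }

    clinical <- as.data.frame(
      lapply(spec$clinical_factors, function(lv) sample(lv, n, replace = TRUE)),
      stringsAsFactors = FALSE)
    if (spec$confound > 0 && length(spec$clinical_factors) > 0L) {
      lv1 <- spec$clinical_factors[[1L]]
      mix <- stats::runif(n) < spec$confound
      forced <- ifelse(status[, 1L], lv1[length(lv1)], lv1[1L])
      clinical[[1L]][mix] <- forced[mix]
    }

    out <- structure(
      list(patient_id = sprintf("P%05d", seq_len(n)),
           time = time, event = event, status = status, clinical = clinical),
      class = "survival_cohort")
    attr(out, "beta_true") <- spec$beta_true
    out
  })
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d patients, %d genes, %d events (%.1f%% censored)\n",
              length(x$time), ncol(x$status), sum(x$event),
              100 * mean(x$event == 0)))
  if (ncol(x$clinical) > 0L) {
    cat("clinical factors:", paste(names(x$clinical), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a survival cohort as a tab-separated clinical table
#'
#' Layout: `patient_id`, `time`, `event`, one column per clinical factor,
#' then one `status_<GENE>` column per gene with values `altered`/`normal`.
#'
#' @param cohort A `survival_cohort`.
#' @param path Output file.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `survival_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "survival_cohort"))
  df <- data.frame(patient_id = cohort$patient_id,
                   time = cohort$time, event = cohort$event,
                   cohort$clinical, check.names = FALSE,
                   stringsAsFactors = FALSE)
  st <- as.data.frame(ifelse(cohort$status, "altered", "normal"),
                      stringsAsFactors = FALSE)
  names(st) <- paste0("status_", colnames(cohort$status))
  write_tsv_det(cbind(df, st), path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("patient_id", "time", "event")
  if (!all(req %in% names(df))) {
    stop("clinical table must have patient_id, time, event columns", call. = FALSE)
  }
  if (any(df$time < 0) || !all(df$event %in% c(0L, 1L))) {
    stop("times must be >= 0 and event indicators in {0, 1}", call. = FALSE)
  }
  status_cols <- grep("^status_", names(df), value = TRUE)
  status <- as.matrix(df[status_cols] == "altered")
  dimnames(status) <- list(NULL, norm_symbols(sub("^status_", "", status_cols)))
  clin_cols <- setdiff(names(df), c(req, status_cols))
  structure(
    list(patient_id = as.character(df$patient_id),
         time = as.numeric(df$time), event = as.integer(df$event),
         status = status,
         clinical = df[clin_cols]),
    class = "survival_cohort")
}
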
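#' Read and validate a pipeline run configuration
#'
#' The whole analysis is driven by one YAML file: the exposure study entry,
#' the disease study entries (expression matrix + sample label paths, an
#' `already_log2` flag per study), the significance thresholds, optional
#' enrichment libraries, and the survival cohort entries. Relative paths are
#' resolved against the config file's directory.
#'
#' @param path YAML config file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }

  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- resolve(cfg$output_dir %||% "diseasomix_out")
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    p_cutoff = as.numeric(th$p_cutoff %||% 0.01),
    lfc_cutoff = as.numeric(th$lfc_cutoff %||% 1),
    use_adjusted = isTRUE(th$use_adjusted %||% TRUE),
    variant = match.arg(th$variant %||% "welch", c("welch", "student")))
  assert_scalar_num(cfg$thresholds$p_cutoff, "p_cutoff", 0, 1)
  assert_scalar_num(cfg$thresholds$lfc_cutoff, "lfc_cutoff", 0)

  check_study <- function(e, what) {
    for (f in c("id", "expression", "labels")) {
      if (is.null(e[[f]])) stop(sprintf("%s entry missing '%s'", what, f), call. = FALSE)
    }
    e$expression <- resolve(e$expression)
    e$labels <- resolve(e$labels)
    for (p in c(e$expression, e$labels)) {
      if (!file.exists(p)) stop(sprintf("missing file: %s", p), call. = FALSE)
    }
    e$already_log2 <- isTRUE(e$already_log2 %||% TRUE)
    e
  }
  if (is.null(cfg$exposure)) stop("config missing 'exposure'", call. = FALSE)
  cfg$exposure <- check_study(cfg$exposure, "exposure")
  if (length(cfg$diseases %||% list()) == 0L) {
    stop("config needs at least one disease study", call. = FALSE)
  }
  cfg$diseases <- lapply(cfg$diseases, check_study, what = "disease")
  ids <- vapply(cfg$diseases, `[[`, character(1), "id")
  if (anyDuplicated(c(cfg$exposure$id, ids))) {
    stop("duplicate study ids in config", call. = FALSE)
  }

  if (!is.null(cfg$enrichment)) {
    cfg$enrichment$libraries <- lapply(cfg$enrichment$libraries %||% list(), resolve)
    for (p in cfg$enrichment$libraries) {
      if (!file.exists(p)) stop(sprintf("missing GMT: %s", p), call. = FALSE)
    }
  }
  if (!is.null(cfg$survival)) {
    cfg$survival$alpha <- as.numeric(cfg$survival$alpha %||% 0.05)
    cfg$survival$ties <- match.arg(cfg$survival$ties %||% "efron",
                                   c("efron", "breslow"))
    cfg$survival$cohorts <- lapply(cfg$survival$cohorts %||% list(), function(e) {
      if (is.null(e$id) || is.null(e$clinical)) {
        stop("survival cohort entry needs 'id' and 'clinical'", call. = FALSE)
      }
      e$clinical <- resolve(e$clinical)
      if (!file.exists(e$clinical)) {
        stop(sprintf("missing file: %s", e$clinical), call. = FALSE)
      }
      e
    })
  }
  class(cfg) <- "run_config"
  cfg
}

load_study <- function(entry) {
  labels <- read_labels(entry$labels)
  study <- read_expression(entry$expression, labels, study_id = entry$id)
  if (!entry$already_log2) {
    study$values <- log2(study$values + 1)
  }
  study
}

#' Run the full analysis pipeline
#'
#' Executes, in order: per-study Z-score normalization and differential
#' expression; construction of the up- and down-regulated exposure-centred
#' diseasome networks; Fisher-exact enrichment of each exposure-disease
#' overlap gene set against every configured GMT library; and the Cox /
#' log-rank survival screen of each disease's overlap genes on its cohort.
#' All artifacts are written under the config's output directory and listed
#' with MD5 checksums in a run manifest, so identical config + seed gives
#' identical checksums.
#'
#' @param config A `run_config` or the path to a YAML config.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  warnings_log <- character()
  files <- character()
  timings <- list()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  emit <- function(path) { files <<- c(files, path); path }

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        note(sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        note(sprintf("[%s] %s", name, trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  th <- config$thresholds

  sets <- run_stage("diffexpr", {
    entries <- c(list(config$exposure), config$diseases)
    lapply(entries, function(entry) {
      raw <- load_study(entry)
      norm <- zscore_normalize(raw)
      stats_tab <- gene_stats(norm, lfc_study = raw, variant = th$variant)
      set <- select_significant(stats_tab, disease_id = entry$id,
                                p_cutoff = th$p_cutoff,
                                lfc_cutoff = th$lfc_cutoff,
                                use_adjusted = th$use_adjusted)
      emit(write_gene_stats(set$table,
                            file.path(outdir, sprintf("de_%s.tsv", entry$id))))
      emit(write_gene_set(set,
                          file.path(outdir, sprintf("geneset_%s.tsv", entry$id))))
      set
    })
  })
  exposure_set <- sets[[1L]]
  disease_sets <- sets[-1L]

  networks <- run_stage("diseasome", {
    nets <- lapply(c("up", "down"), function(dir) {
      net <- build_diseasome(exposure_set, disease_sets, direction = dir)
      for (fmt in c("tsv", "sif", "graphml")) {
        ext <- if (fmt == "tsv") "edges.tsv" else fmt
        emit(export_network(net, file.path(outdir, sprintf("diseasome_%s.%s", dir, ext)),
                            format = fmt))
      }
      net
    })
    names(nets) <- c("up", "down")
    expo_assoc <- do.call(rbind, lapply(nets, function(n) {
      a <- n$associations
      a <- a[a$i == n$exposure_id | a$j == n$exposure_id, , drop = FALSE]
      if (nrow(a) == 0L) return(NULL)
      data.frame(direction = n$direction,
                 disease = ifelse(a$i == n$exposure_id, a$j, a$i),
                 n_shared = a$n_shared, jaccard = a$jaccard,
                 stringsAsFactors = FALSE)
    }))
    rownames(expo_assoc) <- NULL
    emit(write_tsv_det(expo_assoc, file.path(outdir, "shared_counts.tsv")))
    nets
  })

  overlap_genes <- lapply(stats::setNames(nm = vapply(disease_sets, `[[`,
                                                      character(1), "disease_id")),
                          function(d) {
    sort(union(
      networks$up$gene_edges$gene[networks$up$gene_edges$disease == d],
      networks$down$gene_edges$gene[networks$down$gene_edges$disease == d]))
  })

  if (!is.null(config$enrichment) &&
      length(config$enrichment$libraries) > 0L) {
    run_stage("enrichment", {
      for (libpath in config$enrichment$libraries) {
        lib <- load_gmt(libpath)
        for (d in names(overlap_genes)) {
          q <- overlap_genes[[d]]
          if (length(q) == 0L) next
          tab <- fisher_enrichment(q, lib,
                                   background_n = config$enrichment$background)
          emit(write_enrichment(tab, file.path(
            outdir, sprintf("enrichment_%s_%s.tsv", d, lib$name))))
        }
      }
      invisible(NULL)
    })
  }

  if (!is.null(config$survival) && length(config$survival$cohorts) > 0L) {
    run_stage("survival", {
      for (entry in config$survival$cohorts) {
        cohort <- read_cohort(entry$clinical)
        genes <- intersect(overlap_genes[[entry$id]] %||% character(),
                           colnames(cohort$status))
        screen <- gene_survival_screen(cohort, genes = genes,
                                       alpha = config$survival$alpha,
                                       ties = config$survival$ties)
        emit(write_screen_report(screen, file.path(
          outdir, sprintf("survival_%s.tsv", entry$id))))
        for (g in names(screen$km_curves)) {
          for (grp in c("altered", "normal")) {
            emit(write_km_curve(screen$km_curves[[g]][[grp]], file.path(
              outdir, sprintf("km_%s_%s_%s.tsv", entry$id, g, grp))))
          }
        }
      }
      invisible(NULL)
    })
  }

  files <- sort(unique(files))
  manifest <- list(
    package = "diseasomix",
    version = as.character(utils::packageVersion("diseasomix")),
    seed = config$seed,
    thresholds = config$thresholds,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))),
    timings = timings,
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Planted demo scenario: exposure signature of 392 up / 511 down genes, four
# disease studies with the per-study DE totals 939/553/890/691 (503+436,
# 323+230, 673+217, 463+228 up+down) and exposure overlaps of 36, 13, 25 and
# 17 genes split 20/16, 8/5, 15/10 and 10/7 across directions. A few shared
# genes are planted into two diseases at once so the multi-disease degree
# filter has something to find.
demo_plan <- function(n_genes = 6000L) {
  universe <- sprintf("G%06d", seq_len(n_genes))
  wf_up <- universe[1:392]
  wf_down <- universe[393:903]
  shared_up <- list(
    CC = wf_up[1:20],
    PC = wf_up[c(1, 2, 21:26)],          # genes 1-2 also shared with CC
    LC = wf_up[c(3, 27:40)],             # gene 3 also shared with CC
    GC = wf_up[c(4, 5, 6, 41:47)])       # genes 4-6 also shared with CC
  shared_down <- list(
    CC = wf_down[1:16], PC = wf_down[17:21],
    LC = wf_down[22:31], GC = wf_down[32:38])
  private_sizes <- list(  # per-disease private up/down set sizes
    CC = c(483L, 420L), PC = c(315L, 225L),
    LC = c(658L, 207L), GC = c(453L, 221L))
  pool <- universe[904:n_genes]
  offset <- 0L
  private <- lapply(private_sizes, function(sz) {
    up <- pool[offset + seq_len(sz[1L])]
    offset <<- offset + sz[1L]
    down <- pool[offset + seq_len(sz[2L])]
    offset <<- offset + sz[2L]
    list(up = up, down = down)
  })
  list(universe = universe, wf_up = wf_up, wf_down = wf_down,
       shared_up = shared_up, shared_down = shared_down, private = private)
}

#' Generate the demo scenario's linked expression studies in memory
#'
#' The reference planted scenario used by [make_demo()]: a 6000-gene
#' universe, an exposure study with 392 up / 511 down planted genes, and
#' four disease studies (CC, PC, LC, GC) overlapping the exposure by
#' 36, 13, 25 and 17 genes, all with 20 case / 20 control samples, effect
#' size 2 and noise SD 0.5.
#'
#' @param seed Integer seed; sub-seeds per study are derived from it.
#' @return A `linked_studies` object (see [generate_linked_studies()]).
#' @export
demo_studies <- function(seed = 1L) {
  seed <- as.integer(seed)
  plan <- demo_plan()
  ids <- c("CC", "PC", "LC", "GC")
  exposure <- study_spec("WF", n_genes = length(plan$universe),
                         n_case = 20, n_control = 20,
                         de_up = plan$wf_up, de_down = plan$wf_down,
                         effect_size = 2, noise_sd = 0.5,
                         seed = derive_seed(seed, 1L),
                         gene_ids = plan$universe)
  diseases <- lapply(seq_along(ids), function(i) {
    d <- ids[i]
    study_spec(d, n_genes = length(plan$universe),
               n_case = 20, n_control = 20,
               de_up = plan$private[[d]]$up, de_down = plan$private[[d]]$down,
               effect_size = 2, noise_sd = 0.5,
               seed = derive_seed(seed, 1L + i),
               gene_ids = plan$universe)
  })
  generate_linked_studies(exposure, diseases,
                          shared_up = plan$shared_up,
                          shared_down = plan$shared_down)
}

#' Write a ready-to-run synthetic demo data set
#'
#' Generates the package's reference scenario — an exposure study whose
#' signature (392 up / 511 down planted genes) overlaps four disease
#' studies by 36, 13, 25 and 17 genes, matching survival cohorts with three
#' prognostic genes planted at hazard ratio 2 per disease, and a small GMT
#' library — then writes everything (expression matrices, label tables,
#' clinical tables, GMT, ground-truth JSON) plus a `config.yaml` under
#' `outdir`. Studies use 20 case / 20 control samples, planted effect size
#' 2 and noise SD 0.5; cohorts have 300 patients, 25% alteration rate and
#' 30% censoring.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; per-study and per-cohort sub-seeds are derived
#'   deterministically from it.
#' @return Path of the written config file.
#' @export
make_demo <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  plan <- demo_plan()
  ids <- c("CC", "PC", "LC", "GC")
  linked <- demo_studies(seed)

  for (s in linked$studies) {
    write_expression(s, file.path(outdir, sprintf("expr_%s.tsv", s$study_id)))
    write_labels(s, file.path(outdir, sprintf("labels_%s.tsv", s$study_id)))
  }

  clinical_factors <- list(
    ethnicity = c("groupA", "groupB", "groupC"),
    histological_grade = c("G1", "G2", "G3"),
    primary_site = c("site1", "site2"))
  beta_by_disease <- list()
  for (i in seq_along(ids)) {
    d <- ids[i]
    genes <- sort(union(plan$shared_up[[d]], plan$shared_down[[d]]))
    beta <- stats::setNames(rep(0, length(genes)), genes)
    beta[seq_len(min(3L, length(genes)))] <- log(2)
    beta_by_disease[[d]] <- beta
    cohort <- generate_survival_cohort(cohort_spec(
      n_patients = 300, gene_ids = genes, beta_true = beta,
      clinical_factors = clinical_factors, baseline_scale = 60,
      censor_rate = 0.3, alteration_rate = 0.25,
      seed = derive_seed(seed, 10L + i)))
    write_cohort(cohort, file.path(outdir, sprintf("cohort_%s.tsv", d)))
  }

  # Small synthetic gene-set library: one term per planted overlap set plus
  # background terms drawn from the universe.
  lib_terms <- with_seed(derive_seed(seed, 99L), {
    terms <- list()
    for (d in ids) {
      terms[[sprintf("PLANTED_%s_UP", d)]] <- plan$shared_up[[d]]
      terms[[sprintf("PLANTED_%s_DOWN", d)]] <- plan$shared_down[[d]]
    }
    for (k in 1:20) {
      terms[[sprintf("RANDOM_TERM_%02d", k)]] <-
        sort(sample(plan$universe, 25L))
    }
    terms
  })
  lib <- structure(
    list(name = "demo_library",
         terms = lapply(lib_terms, function(g) sort(unique(norm_symbols(g)))),
         descriptions = stats::setNames(rep("synthetic", length(lib_terms)),
                                        names(lib_terms)),
         background = length(unique(unlist(lib_terms, use.names = FALSE)))),
    class = "gene_set_library")
  write_gmt(lib, file.path(outdir, "demo_library.gmt"))

  truth <- linked$ground_truth
  truth$beta_true <- lapply(beta_by_disease, as.list)
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg <- list(
    seed = seed,
    output_dir = "results",
    thresholds = list(p_cutoff = 0.01, lfc_cutoff = 1, use_adjusted = TRUE,
                      variant = "welch"),
    exposure = list(id = "WF", expression = "expr_WF.tsv",
                    labels = "labels_WF.tsv", already_log2 = TRUE),
    diseases = lapply(ids, function(d) list(
      id = d, expression = sprintf("expr_%s.tsv", d),
      labels = sprintf("labels_%s.tsv", d), already_log2 = TRUE)),
    enrichment = list(libraries = list("demo_library.gmt")),
    survival = list(alpha = 0.05, ties = "efron",
                    cohorts = lapply(ids, function(d) list(
                      id = d, clinical = sprintf("cohort_%s.tsv", d)))))
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
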
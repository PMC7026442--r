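#' Stratify patients into altered vs normal by expression z-score
#'
#' A patient is "altered" for a gene when the tumour expression z-score
#' (against the cohort's reference distribution) deviates by at least
#' `z_star` in either direction — the usual threshold convention for
#' mRNA-based alteration calls, with `z_star = 2` as default.
#'
#' @param z Numeric vector of per-patient z-scores for one gene.
#' @param z_star Positive threshold (default 2).
#' @return Character vector of `"altered"`/`"normal"`.
#' @export
stratify_by_alteration <- function(z, z_star = 2) {
  assert_scalar_num(z_star, "z_star", lower = 0, open_lower = TRUE)
  ifelse(abs(z) >= z_star, "altered", "normal")
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function `S(t_j) = prod_{i<=j} (1 - d_i/n_i)` over
#' the distinct event times, via [survival::survfit()]. Censored-only times
#' do not create steps but reduce later at-risk counts; at tied times,
#' deaths are processed before censorings.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `km_curve` data frame: `time` (distinct event times), `n_risk`,
#'   `n_event`, `surv`. With no events the frame has zero rows (the
#'   estimate is identically 1).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], surv = fit$surv[keep])
  rownames(out) <- NULL
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Compares the survival functions of two groups (e.g. altered vs normal):
#' at each distinct event time the observed events in group A are compared
#' with their hypergeometric expectation, and the variance-normalized sum is
#' referred to a chi-square with 1 df. Computed by [survival::survdiff()].
#'
#' @param times_a,events_a Follow-up times and event indicators, group A.
#' @param times_b,events_b Same for group B.
#' @return List with `statistic` (chi-square), `p`, and the per-group
#'   observed/expected counts.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE),
       observed = unname(sd_$obs), expected = unname(sd_$exp))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood for `h(t|X) = h0(t) exp(beta' X)`
#' via [survival::coxph()], with Efron (default) or Breslow handling of tied
#' event times. Hazard ratios are `exp(beta)`; standard errors come from the
#' inverse observed information and p-values are two-sided Wald tests.
#'
#' @param x Covariate data frame or numeric matrix (one column per
#'   covariate; factors are dummy-encoded by the model).
#' @param times,events Follow-up times and event indicators.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit`: `beta`, `hr`, `se`, `z`, `p`, `loglik` (log partial
#'   likelihood at the estimate), `score` (score test statistic at beta=0),
#'   `converged`, `ties`, `n`, `n_event`.
#' @export
cox_fit <- function(x, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(nrow(x) == length(times), length(times) == length(events))
  d <- cbind(data.frame(.time = times, .event = events), x)
  infinite_warn <- FALSE
  iter_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = d,
                    ties = ties),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite", msg, fixed = TRUE)) infinite_warn <<- TRUE
      if (grepl("Ran out of iterations", msg, fixed = TRUE)) iter_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (infinite_warn) {
    stop(structure(
      class = c("monotone_likelihood_error", "error", "condition"),
      list(message = "monotone partial likelihood (perfect separation): coefficient diverges",
           call = sys.call())))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  structure(
    list(beta = beta, hr = exp(beta), se = se, z = z,
         p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         loglik = fit$loglik[2L], score = unname(fit$score),
         converged = !iter_warn, ties = ties,
         n = fit$n, n_event = fit$nevent),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties, %s): n=%d, events=%d\n", x$ties,
              if (x$converged) "converged" else "NOT converged", x$n, x$n_event))
  print(data.frame(beta = x$beta, HR = x$hr, se = x$se, p = x$p))
  invisible(x)
}

#' Hazard ratio of a Cox coefficient
#'
#' `HR = exp(beta)`: the multiplicative effect of a one-unit covariate
#' change on the hazard.
#'
#' @param beta Finite numeric vector of log-hazard coefficients.
#' @return `exp(beta)`.
#' @export
hazard_ratio <- function(beta) {
  stopifnot(is.numeric(beta), all(is.finite(beta)))
  exp(beta)
}

# Relevel clinical factors against their most frequent level; drop factors
# with a single observed level (uninformative) with a warning.
prepare_clinical <- function(clinical) {
  if (is.null(clinical) || ncol(clinical) == 0L) return(NULL)
  keep <- list()
  for (nm in names(clinical)) {
    tab <- sort(table(clinical[[nm]]), decreasing = TRUE)
    if (length(tab) < 2L) {
      warning(sprintf("clinical factor '%s' has a single level; dropped", nm),
              call. = FALSE)
      next
    }
    keep[[nm]] <- factor(clinical[[nm]], levels = names(tab))
  }
  if (length(keep) == 0L) return(NULL)
  as.data.frame(keep, stringsAsFactors = TRUE)
}

#' Survival screen of candidate genes
#'
#' For each gene of a cohort, fits three Cox models mirroring the standard
#' reporting layout: univariate (the gene's altered/normal status alone),
#' multivariate (all screened genes jointly), and combined (the gene's
#' status plus the clinical covariates), each reported as beta / HR /
#' Wald p. A per-gene log-rank test of altered vs normal survival is run
#' alongside; genes are flagged significant when the designated model's p
#' is at most `alpha`, and Kaplan-Meier curves (altered and normal) are
#' returned for the flagged genes.
#'
#' @param cohort A `survival_cohort`.
#' @param genes Genes to screen; default all genes of the cohort.
#' @param alpha Significance threshold (default 0.05).
#' @param ties Ties method passed to [cox_fit()].
#' @param flag_model Which model's p-value flags a gene: `"univariate"`
#'   (default), `"multivariate"`, `"combined"` or `"logrank"`.
#' @param use_clinical Include the cohort's clinical factors in the
#'   combined model (default `TRUE`).
#' @return A `survival_screen`: `$report` data frame (gene, beta/HR/p for
#'   the three models, log-rank statistic and p, `significant`),
#'   `$km_curves` (per flagged gene, `altered` and `normal` `km_curve`s),
#'   `$alpha`, `$flag_model`.
#' @export
gene_survival_screen <- function(cohort, genes = colnames(cohort$status),
                                 alpha = 0.05, ties = c("efron", "breslow"),
                                 flag_model = c("univariate", "multivariate",
                                                "combined", "logrank"),
                                 use_clinical = TRUE) {
  stopifnot(inherits(cohort, "survival_cohort"))
  ties <- match.arg(ties)
  flag_model <- match.arg(flag_model)
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  genes <- norm_symbols(genes)

  empty <- data.frame(
    gene = character(), beta_uni = numeric(), hr_uni = numeric(),
    p_uni = numeric(), beta_multi = numeric(), hr_multi = numeric(),
    p_multi = numeric(), beta_comb = numeric(), hr_comb = numeric(),
    p_comb = numeric(), logrank_chisq = numeric(), logrank_p = numeric(),
    significant = logical(), stringsAsFactors = FALSE)
  if (length(genes) == 0L) {
    return(structure(list(report = empty, km_curves = list(), alpha = alpha,
                          flag_model = flag_model),
                     class = "survival_screen"))
  }
  missing <- setdiff(genes, colnames(cohort$status))
  if (length(missing) > 0L) {
    stop(sprintf("genes not in cohort: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }

  ok <- stats::complete.cases(cohort$time, cohort$event)
  time <- cohort$time[ok]; event <- cohort$event[ok]
  status <- cohort$status[ok, genes, drop = FALSE]
  clinical <- if (use_clinical) prepare_clinical(cohort$clinical[ok, , drop = FALSE])
  if (sum(!ok) > 0L) message(sprintf("excluding %d patient(s) with missing time/event", sum(!ok)))

  usable <- vapply(genes, function(g) {
    s <- status[, g]
    any(s) && !all(s)
  }, logical(1))
  if (any(!usable)) {
    warning(sprintf("gene(s) with constant alteration status skipped: %s",
                    paste(genes[!usable], collapse = ", ")), call. = FALSE)
  }

  safe_fit <- function(x) {
    tryCatch(cox_fit(x, time, event, ties = ties),
             monotone_likelihood_error = function(e) NULL,
             error = function(e) NULL)
  }

  # multivariate: all usable genes jointly
  multi <- NULL
  if (sum(usable) > 0L) {
    xm <- as.data.frame(status[, genes[usable], drop = FALSE] * 1L)
    multi <- safe_fit(xm)
  }

  rows <- lapply(genes, function(g) {
    row <- data.frame(gene = g, beta_uni = NA_real_, hr_uni = NA_real_,
                      p_uni = NA_real_, beta_multi = NA_real_,
                      hr_multi = NA_real_, p_multi = NA_real_,
                      beta_comb = NA_real_, hr_comb = NA_real_,
                      p_comb = NA_real_, logrank_chisq = NA_real_,
                      logrank_p = NA_real_, significant = FALSE,
                      stringsAsFactors = FALSE)
    if (!usable[[g]]) return(row)
    s <- status[, g]

    lr <- logrank_test(time[s], event[s], time[!s], event[!s])
    row$logrank_chisq <- lr$statistic
    row$logrank_p <- lr$p

    uni <- safe_fit(data.frame(gene = s * 1L))
    if (!is.null(uni) && uni$converged) {
      row$beta_uni <- unname(uni$beta[1L])
      row$hr_uni <- unname(uni$hr[1L])
      row$p_uni <- unname(uni$p[1L])
    }
    if (!is.null(multi) && multi$converged && g %in% names(multi$beta)) {
      row$beta_multi <- unname(multi$beta[g])
      row$hr_multi <- unname(multi$hr[g])
      row$p_multi <- unname(multi$p[g])
    }
    xc <- data.frame(gene = s * 1L)
    if (!is.null(clinical)) xc <- cbind(xc, clinical)
    comb <- safe_fit(xc)
    if (!is.null(comb) && comb$converged) {
      row$beta_comb <- unname(comb$beta["gene"])
      row$hr_comb <- unname(comb$hr["gene"])
      row$p_comb <- unname(comb$p["gene"])
    }
    row
  })
  report <- do.call(rbind, rows)

  pcol <- switch(flag_model, univariate = report$p_uni,
                 multivariate = report$p_multi, combined = report$p_comb,
                 logrank = report$logrank_p)
  report$significant <- !is.na(pcol) & pcol <= alpha

  km_curves <- lapply(stats::setNames(report$gene[report$significant],
                                      report$gene[report$significant]),
                      function(g) {
    s <- status[, g]
    list(altered = km_estimate(time[s], event[s]),
         normal = km_estimate(time[!s], event[!s]))
  })

  structure(list(report = report, km_curves = km_curves, alpha = alpha,
                 flag_model = flag_model),
            class = "survival_screen")
}

#' @export
print.survival_screen <- function(x, ...) {
  cat(sprintf("survival_screen: %d genes, %d significant at alpha=%g (%s model)\n",
              nrow(x$report), sum(x$report$significant), x$alpha, x$flag_model))
  invisible(x)
}

#' Write a survival screen report / a KM curve
#'
#' The report replicates the three-block layout gene, beta/HR/p x
#' {univariate, multivariate, combined}, plus the log-rank columns; KM
#' curves are written as per-curve TSV (time, n_risk, n_event, surv).
#' @param screen A `survival_screen`.
#' @param path Output file.
#' @export
write_screen_report <- function(screen, path) {
  write_tsv_det(screen$report, path)
}

#' @rdname write_screen_report
#' @param curve A `km_curve`.
#' @export
write_km_curve <- function(curve, path) {
  write_tsv_det(as.data.frame(curve), path)
}
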
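test_that("alteration stratification thresholds absolute z-scores", {
  expect_identical(stratify_by_alteration(c(0, 0, 0)), rep("normal", 3))
  expect_identical(stratify_by_alteration(c(2.5, -2.1, 0.3, 1.9), z_star = 2),
                   c("altered", "altered", "normal", "normal"))
  expect_identical(stratify_by_alteration(c(0.1, -0.2), z_star = 1e-9),
                   c("altered", "altered"))
  expect_error(stratify_by_alteration(1, z_star = 0), "z_star")
})

test_that("the product-limit estimator matches the hand computation", {
  km <- km_estimate(c(1, 2, 2, 3), c(1, 1, 1, 0))
  expect_equal(km$time, c(1, 2))
  expect_equal(km$n_risk, c(4, 3))
  expect_equal(km$n_event, c(1, 2))
  expect_equal(km$surv, c(0.75, 0.25), tolerance = 1e-12)

  none <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_identical(nrow(none), 0L)
  expect_error(km_estimate(numeric(), numeric()), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("KM curves agree with the brute-force product oracle and with the
           empirical survivor fraction when nothing is censored", {
  set.seed(55)
  for (i in 1:40) {
    n <- sample(4:25, 1)
    times <- sample(1:12, n, replace = TRUE)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) next
    got <- km_estimate(times, events)
    ref <- oracle_km(times, events)
    expect_equal(got$time, ref$time)
    expect_equal(got$n_risk, ref$n_risk)
    expect_equal(got$n_event, ref$n_event)
    expect_equal(got$surv, ref$surv, tolerance = 1e-12)
    expect_true(all(diff(got$surv) <= 1e-12))  # non-increasing
  }
  # no censoring: the estimate is the empirical survivor fraction exactly
  times <- c(3, 1, 4, 1, 5, 9, 2, 6)
  got <- km_estimate(times, rep(1, 8))
  expect_equal(got$surv, vapply(got$time, function(t) mean(times > t),
                                numeric(1)), tolerance = 1e-12)
})

test_that("KM converges to the true exponential survivor function", {
  spec <- cohort_spec(4000, gene_ids = "G1", beta_true = 0,
                      baseline_scale = 50, censor_rate = 0, seed = 77)
  co <- generate_survival_cohort(spec)
  km <- km_estimate(co$time, co$event)
  sup_dist <- max(abs(km$surv - exp(-km$time / 50)))
  expect_lt(sup_dist, 0.03)
})

test_that("log-rank is null on duplicated data and matches the hand oracle", {
  t0 <- c(1, 2, 3, 4, 6); e0 <- c(1, 0, 1, 1, 0)
  same <- logrank_test(t0, e0, t0, e0)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  got <- logrank_test(c(1, 3), c(1, 1), c(2, 4), c(1, 1))
  ref <- oracle_logrank(c(1, 3), c(1, 1), c(2, 4), c(1, 1))
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-10)
  expect_equal(got$p, ref$p, tolerance = 1e-10)

  set.seed(4)
  for (i in 1:30) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    t1 <- sample(1:15, n1, TRUE); e1 <- rbinom(n1, 1, 0.8)
    t2 <- sample(1:15, n2, TRUE); e2 <- rbinom(n2, 1, 0.8)
    if (sum(e1) + sum(e2) < 2) next
    got <- logrank_test(t1, e1, t2, e2)
    ref <- oracle_logrank(t1, e1, t2, e2)
    expect_equal(got$statistic, ref$statistic, tolerance = 1e-8)
    swapped <- logrank_test(t2, e2, t1, e1)
    expect_equal(swapped$statistic, got$statistic, tolerance = 1e-10)
  }
  expect_error(logrank_test(numeric(), numeric(), 1, 1), "non-empty")
})

test_that("Cox fits are null when the covariate carries no information", {
  set.seed(12)
  times <- rexp(30, 0.1); events <- rbinom(30, 1, 0.8)
  # the same survival data duplicated into both covariate groups
  fit <- cox_fit(data.frame(x = rep(c(0, 1), each = 30)),
                 c(times, times), c(events, events))
  expect_lt(abs(fit$beta), 1e-6)
  expect_equal(unname(fit$hr), 1, tolerance = 1e-5)
})

test_that("Cox estimates maximize the written partial likelihood", {
  # 6-patient worked data, one binary covariate, no tied event times
  times <- c(2, 5, 7, 9, 12, 16)
  events <- c(1, 1, 1, 1, 0, 1)
  x <- c(1, 1, 0, 1, 0, 0)
  fit <- cox_fit(data.frame(x = x), times, events, ties = "breslow")
  b_ref <- oracle_cox_fit(x, times, events)
  expect_equal(unname(fit$beta), b_ref, tolerance = 1e-3)
  expect_equal(fit$loglik, oracle_cox_loglik(unname(fit$beta), x, times, events),
               tolerance = 1e-8)
  expect_identical(unname(fit$hr), exp(unname(fit$beta)))
  expect_true(fit$converged)
})

test_that("Efron and Breslow agree exactly without tied event times", {
  set.seed(8)
  n <- 40
  times <- rexp(n); events <- rbinom(n, 1, 0.7)
  x <- rbinom(n, 1, 0.5)
  fe <- cox_fit(data.frame(x = x), times, events, ties = "efron")
  fb <- cox_fit(data.frame(x = x), times, events, ties = "breslow")
  expect_equal(unname(fe$beta), unname(fb$beta), tolerance = 1e-9)
})

test_that("perfect separation raises a monotone-likelihood error", {
  # all group-1 deaths precede every group-0 death: beta diverges
  times <- c(1, 2, 3, 10, 11, 12)
  events <- rep(1, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_error(cox_fit(data.frame(x = x), times, events),
               class = "monotone_likelihood_error")
})

test_that("the log-rank statistic equals the Cox score test for one binary covariate", {
  set.seed(23)
  for (i in 1:20) {
    co <- generate_survival_cohort(cohort_spec(
      80, gene_ids = "G1", beta_true = runif(1, -1, 1),
      censor_rate = 0.2, alteration_rate = 0.4, seed = 1000 + i))
    s <- co$status[, 1]
    lr <- logrank_test(co$time[s], co$event[s], co$time[!s], co$event[!s])
    fit <- cox_fit(data.frame(x = s * 1), co$time, co$event, ties = "breslow")
    expect_equal(lr$statistic, fit$score, tolerance = 1e-6)
  }
})

test_that("hazard ratios are the exponential of the coefficients", {
  expect_identical(hazard_ratio(0), 1)
  expect_equal(signif(hazard_ratio(0.316), 3), 1.37)
  expect_equal(signif(hazard_ratio(-0.414), 3), 0.661)
  expect_error(hazard_ratio(Inf))
  b <- rnorm(10)
  expect_identical(hazard_ratio(b), exp(b))
})

test_that("the survival screen reports the three model blocks and flags planted genes", {
  spec <- cohort_spec(
    500, gene_ids = c("HIT1", "NULL1", "NULL2"),
    beta_true = c(1, 0, 0),
    clinical_factors = list(grade = c("G1", "G2", "G3"),
                            site = c("s1", "s2")),
    censor_rate = 0.25, alteration_rate = 0.3, seed = 61)
  co <- generate_survival_cohort(spec)
  screen <- gene_survival_screen(co)
  rep_ <- screen$report
  expect_identical(rep_$gene, c("HIT1", "NULL1", "NULL2"))
  expect_identical(names(rep_),
                   c("gene", "beta_uni", "hr_uni", "p_uni", "beta_multi",
                     "hr_multi", "p_multi", "beta_comb", "hr_comb", "p_comb",
                     "logrank_chisq", "logrank_p", "significant"))
  expect_true(rep_$significant[rep_$gene == "HIT1"])
  expect_equal(rep_$beta_uni[1], 1, tolerance = 0.35)
  expect_equal(rep_$hr_uni, exp(rep_$beta_uni), tolerance = 1e-12)
  expect_equal(rep_$hr_comb, exp(rep_$beta_comb), tolerance = 1e-12)
  # KM curves are emitted for each flagged gene, altered and normal arms
  expect_setequal(names(screen$km_curves), rep_$gene[rep_$significant])
  expect_named(screen$km_curves[["HIT1"]], c("altered", "normal"))
})

test_that("screen edge cases: empty gene list, constant status, single-level factor", {
  spec <- cohort_spec(60, gene_ids = c("A1", "B1"), beta_true = 0,
                      clinical_factors = list(only = "one_level"),
                      censor_rate = 0.2, seed = 3)
  co <- generate_survival_cohort(spec)

  empty <- gene_survival_screen(co, genes = character())
  expect_identical(nrow(empty$report), 0L)

  co2 <- co
  co2$status[, "A1"] <- TRUE  # constant: no normal group exists
  expect_warning(
    expect_warning(s2 <- gene_survival_screen(co2), "single level"),
    "constant alteration")
  expect_true(is.na(s2$report$beta_uni[s2$report$gene == "A1"]))
  expect_false(s2$report$significant[s2$report$gene == "A1"])

  expect_error(gene_survival_screen(co, genes = "NOPE"), "not in cohort")
})
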
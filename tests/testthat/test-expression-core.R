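toy_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a small expression matrix parses with its labels", {
  path <- toy_file(c("gene\ts1\ts2\ts3\ts4",
                     "TP53\t1\t2\t3\t4",
                     "KRAS\t5\t6\t7\t8",
                     "EGFR\t0.5\t0.25\t1\t2"))
  labels <- c(s1 = "case", s2 = "case", s3 = "control", s4 = "control")
  st <- read_expression(path, labels, study_id = "toy")
  expect_identical(dim(st$values), c(3L, 4L))
  expect_identical(rownames(st$values), c("TP53", "KRAS", "EGFR"))
  expect_identical(unname(st$group), c("case", "case", "control", "control"))
})

test_that("malformed matrices are rejected with the offending detail", {
  dup <- toy_file(c("gene\ts1\ts1", "TP53\t1\t2"))
  expect_error(read_expression(dup, c(s1 = "case")), "duplicated sample")
  ragged <- toy_file(c("gene\ts1\ts2", "TP53\t1\t2", "KRAS\t1"))
  expect_error(read_expression(ragged, c(s1 = "case", s2 = "control")),
               "line 3")
  empty <- toy_file("gene\ts1")
  expect_error(read_expression(empty, c(s1 = "case")), "empty")
})

test_that("unlabelled samples are an error in strict mode, dropped otherwise", {
  path <- toy_file(c("gene\ts1\ts2\ts3\ts4",
                     "TP53\t1\t2\t3\t4", "KRAS\t5\t6\t7\t8"))
  labels <- c(s1 = "case", s2 = "case", s3 = "control")
  expect_error(read_expression(path, labels), "missing from label map")
  st <- suppressMessages(read_expression(path, labels, strict = FALSE))
  expect_identical(colnames(st$values), c("s1", "s2", "s3"))
})

test_that("write/read round-trips a generated study", {
  st <- generate_expression_study(
    study_spec("RT", 40, 4, 5, de_up = sprintf("G%06d", 1:4), seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(st, path)
  lab_path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(st, lab_path)
  back <- read_expression(path, read_labels(lab_path), study_id = "RT")
  expect_identical(rownames(back$values), rownames(st$values))
  expect_identical(back$group, st$group)
  expect_equal(back$values, st$values, tolerance = 1e-9)
})

test_that("probe collapsing keeps one probe per gene as the policy dictates", {
  vals <- rbind(p1 = c(1, 1, 1, 1), p2 = c(5, 5, 5, 5), p3 = c(2, 2, 3, 3))
  colnames(vals) <- paste0("s", 1:4)
  st <- expression_study("P", vals,
                         c(s1 = "case", s2 = "case", s3 = "control", s4 = "control"))
  map <- c(P1 = "GENEA", P2 = "GENEA", P3 = "GENEB")
  out <- collapse_probes(st, map, policy = "max_mean")
  expect_identical(sort(rownames(out$values)), c("GENEA", "GENEB"))
  expect_equal(unname(out$values["GENEA", ]), rep(5, 4))  # brighter probe wins
  expect_error(collapse_probes(st, character()), "empty")
})

test_that("identity mapping leaves the study unchanged and unmapped probes drop", {
  st <- generate_expression_study(study_spec("ID", 15, 3, 3, seed = 4))
  ident <- setNames(rownames(st$values), rownames(st$values))
  out <- collapse_probes(st, ident, policy = "first")
  expect_equal(out$values, st$values)
  partial <- ident[1:10]
  expect_message(out2 <- collapse_probes(st, partial, policy = "first"),
                 "5 unmapped")
  expect_identical(nrow(out2$values), 10L)
})

test_that("max_abs_t collapsing matches a per-gene argmax over t.test calls", {
  set.seed(42)
  n_probe <- 50
  vals <- matrix(rnorm(n_probe * 12), nrow = n_probe,
                 dimnames = list(sprintf("PR%02d", 1:n_probe), paste0("s", 1:12)))
  group <- setNames(rep(c("case", "control"), each = 6), paste0("s", 1:12))
  st <- expression_study("T", vals, group)
  map <- setNames(sprintf("GENE%02d", rep(1:10, each = 5)), rownames(vals))
  out <- collapse_probes(st, map, policy = "max_abs_t", variant = "welch")
  for (g in unique(map)) {
    probes <- names(map)[map == g]
    tstats <- vapply(probes, function(p) {
      abs(t.test(vals[p, 1:6], vals[p, 7:12])$statistic)
    }, numeric(1))
    best <- probes[which.max(tstats)]
    expect_equal(unname(out$values[g, ]), unname(vals[best, ]))
  }
})

test_that("z-scoring standardizes every row and ignores affine input changes", {
  st <- generate_expression_study(study_spec("Z", 20, 5, 5, seed = 6))
  z <- zscore_normalize(st)
  expect_lt(max(abs(rowMeans(z$values))), 1e-12)
  expect_lt(max(abs(apply(z$values, 1, sd) - 1)), 1e-12)

  st2 <- st
  st2$values <- 3.7 * st$values + 11
  z2 <- zscore_normalize(st2)
  expect_equal(z2$values, z$values, tolerance = 1e-12)

  # row (1,2,3) under the sample-SD convention
  v <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("A", paste0("s", 1:3)))
  zz <- zscore_normalize(expression_study(
    "ONE", v, c(s1 = "case", s2 = "case", s3 = "control")))
  expect_equal(unname(zz$values[1, ]), c(-1, 0, 1), tolerance = 1e-12)
})

test_that("z-scoring is idempotent and drops constant or incomplete rows", {
  st <- generate_expression_study(study_spec("I", 30, 4, 4, seed = 8))
  st$values["G000001", ] <- 5            # constant row: SD undefined
  st$values["G000002", 2] <- NA          # incomplete row: dropped, not imputed
  z1 <- suppressMessages(zscore_normalize(st))
  expect_setequal(attr(z1, "dropped_genes"), c("G000001", "G000002"))
  expect_false(any(c("G000001", "G000002") %in% rownames(z1$values)))
  z2 <- zscore_normalize(z1)
  expect_equal(z2$values, z1$values, tolerance = 1e-12)
})

test_that("collapsing then normalizing equals normalizing the collapsed rows", {
  st <- generate_expression_study(study_spec("C", 20, 4, 4, seed = 10))
  map <- setNames(sprintf("GENE%02d", 1:20), rownames(st$values))
  a <- zscore_normalize(collapse_probes(st, map, policy = "max_mean"))
  b <- collapse_probes(zscore_normalize(st),
                       setNames(sprintf("GENE%02d", 1:20), rownames(st$values)),
                       policy = "first")
  expect_equal(a$values[sort(rownames(a$values)), ],
               b$values[sort(rownames(b$values)), ], tolerance = 1e-12)
})
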
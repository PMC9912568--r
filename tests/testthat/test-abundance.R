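test_that("abundance tables round-trip through write and read", {
  vals <- matrix(c(0.3, 0.25, 0.5, 0.125, 0, 0.375), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  tab <- abundance_table(vals, c("control", "case", "case"),
                         c("s1", "s1", "s2"))
  d <- withr::local_tempdir()
  write_abundance(tab, file.path(d, "ab.tsv"), file.path(d, "meta.tsv"))
  back <- read_abundance(file.path(d, "ab.tsv"), file.path(d, "meta.tsv"))
  expect_identical(back$values, tab$values)
  expect_identical(back$labels, tab$labels)
  expect_identical(back$study, tab$study)
})

test_that("read_abundance parses numeric cells and detects CSV by extension", {
  d <- withr::local_tempdir()
  writeLines(c("sample_id,t1,t2", "a,0.3,0.1", "b,0.2,0.4"),
             file.path(d, "ab.csv"))
  writeLines(c("sample_id,label,study", "a,control,s1", "b,case,s1"),
             file.path(d, "meta.csv"))
  tab <- read_abundance(file.path(d, "ab.csv"), file.path(d, "meta.csv"))
  expect_equal(tab$values["a", "t1"], 0.3)
  expect_equal(dim(tab$values), c(2L, 2L))
})

test_that("samples present in only one file are an error naming the sample", {
  d <- withr::local_tempdir()
  writeLines(c("sample_id\tt1", "a\t0.3", "b\t0.2"), file.path(d, "ab.tsv"))
  writeLines(c("sample_id\tlabel\tstudy", "a\tcontrol\ts1"),
             file.path(d, "meta.tsv"))
  expect_error(read_abundance(file.path(d, "ab.tsv"), file.path(d, "meta.tsv")),
               "b")
  writeLines(c("sample_id\tlabel\tstudy", "a\tcontrol\ts1", "b\tcase\ts1",
               "zz\tcase\ts1"), file.path(d, "meta.tsv"))
  expect_error(read_abundance(file.path(d, "ab.tsv"), file.path(d, "meta.tsv")),
               "zz")
})

test_that("constructor enforces the table invariants", {
  v <- matrix(0.1, 2, 2, dimnames = list(c("a", "a"), c("t1", "t2")))
  expect_error(abundance_table(v, c("case", "case"), c("s", "s")),
               "duplicate sample")
  v2 <- matrix(0.1, 2, 2, dimnames = list(c("a", "b"), c("t1", "t1")))
  expect_error(abundance_table(v2, c("case", "case"), c("s", "s")),
               "duplicate taxon")
  v3 <- matrix(0.9, 2, 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_error(abundance_table(v3, c("case", "case"), c("s", "s")),
               "exceed")
  v4 <- matrix(0.1, 2, 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_error(abundance_table(v4, c("case", "sick"), c("s", "s")),
               "sick")
  expect_error(abundance_table(v4 * -1, c("case", "control"), c("s", "s")),
               "non-negative")
})

test_that("abundance filter zeroes values strictly below the threshold", {
  vals <- matrix(c(1e-20, 0.5, 1e-15, 0.2), 2, 2,
                 dimnames = list(c("a", "b"), c("t1", "t2")))
  tab <- toy_table(vals)
  out <- filter_abundance(tab, 1e-15)
  expect_equal(out$values["a", "t1"], 0)        # below threshold
  expect_equal(out$values["b", "t1"], 0.5)      # untouched
  expect_equal(out$values["a", "t2"], 1e-15)    # equal: strict comparison keeps it
  expect_equal(dim(out$values), dim(vals))
  # threshold 0 leaves non-negative data unchanged
  expect_identical(filter_abundance(tab, 0)$values, vals)
  expect_error(filter_abundance(tab, -1), "non-negative")
})

test_that("prevalence filter drops taxa with zero-fraction strictly above threshold", {
  # 20 samples; taxon A has 19 zeros (0.95 > 0.9, dropped), taxon B none
  vals <- cbind(A = c(rep(0, 19), 0.5), B = rep(0.01, 20))
  rownames(vals) <- sprintf("s%02d", 1:20)
  out <- filter_prevalence(toy_table(vals), 0.9)
  expect_identical(colnames(out$values), "B")
  expect_identical(attr(out, "dropped_taxa"), "A")

  # boundary: exactly 9 zeros in 10 samples -> 0.9 > 0.9 is FALSE, retained
  vals10 <- cbind(A = c(rep(0, 9), 0.5), B = rep(0.01, 10))
  rownames(vals10) <- sprintf("s%02d", 1:10)
  out10 <- filter_prevalence(toy_table(vals10), 0.9)
  expect_true("A" %in% colnames(out10$values))

  # a taxon with no zeros survives any threshold
  expect_true("B" %in% colnames(filter_prevalence(toy_table(vals), 0)$values))
  expect_error(filter_prevalence(toy_table(vals), 1.5), "\\[0, 1\\]")
})

test_that("filters are idempotent, monotone, and never drop samples", {
  set.seed(5)
  vals <- matrix(runif(200, 0, 0.02), 20, 10)
  vals[sample(length(vals), 120)] <- 0
  rownames(vals) <- sprintf("s%02d", 1:20)
  colnames(vals) <- sprintf("t%02d", 1:10)
  tab <- toy_table(vals)
  for (thr in c(0.001, 0.01)) {
    once <- filter_abundance(tab, thr)
    expect_identical(filter_abundance(once, thr)$values, once$values)
  }
  for (thr in c(0.3, 0.6)) {
    once <- filter_prevalence(tab, thr)
    twice <- filter_prevalence(once, thr)
    expect_identical(twice$values, once$values)
  }
  # raising the abundance threshold never decreases zeros
  zeros <- sapply(c(0, 1e-3, 5e-3, 1e-2), function(t)
    sum(filter_abundance(tab, t)$values == 0))
  expect_true(all(diff(zeros) >= 0))
  # raising the prevalence threshold never decreases retained taxa
  kept <- sapply(c(0.2, 0.5, 0.8, 1), function(t)
    ncol(filter_prevalence(tab, t)$values))
  expect_true(all(diff(kept) >= 0))
  # sample count preserved through the full filter pipeline
  out <- filter_prevalence(filter_abundance(tab, 1e-3), 0.5)
  expect_equal(nrow(out$values), nrow(tab$values))
})

test_that("align_taxa projects onto a target taxon set with zero fill", {
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2,
                 dimnames = list(c("a", "b"), c("t1", "t2")))
  out <- align_taxa(toy_table(vals), c("t2", "t3"))
  expect_identical(colnames(out$values), c("t2", "t3"))
  expect_equal(out$values[, "t2"], c(a = 0.3, b = 0.4))
  expect_equal(out$values[, "t3"], c(a = 0, b = 0))
})
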
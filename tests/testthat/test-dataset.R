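test_that("reading a toy MDR flat file yields a validated dataset", {
  path <- withr::local_tempfile(fileext = ".mdr")
  writeLines(c("SNP1\tSNP2\tClass",
               "0\t1\t1", "2\t0\t1", "1\t1\t0", "0\t2\t0"), path)
  ds <- read_mdr_file(path)
  expect_s3_class(ds, "genotype_dataset")
  expect_equal(ds$n_cases, 2L)
  expect_equal(ds$n_controls, 2L)
  expect_equal(ds$snp_names, c("SNP1", "SNP2"))
  expect_equal(ds$genotypes[2, ], c(SNP1 = 2L, SNP2 = 0L))
})

test_that("rows with a missing token are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".mdr")
  writeLines(c("A\tB\tClass", "0\t1\t1", "NA\t0\t1", "1\t1\t0"), path)
  expect_message(ds <- read_mdr_file(path), "dropped 1 row")
  expect_equal(n_individuals(ds), 2L)
})

test_that("malformed rows and degenerate class columns are rejected", {
  path <- withr::local_tempfile(fileext = ".mdr")
  writeLines(c("A\tB\tClass", "0\t1\t1", "2\t0", "1\t1\t0"), path)
  expect_error(read_mdr_file(path), "line 3")
  writeLines(c("A\tB\tClass", "0\t1\t1", "1\t1\t1"), path)
  expect_error(read_mdr_file(path), "at least one case and one control")
})

test_that("write/read round trip is the identity, in both dialects", {
  for (dialect in c("mdr-tab", "csv")) {
    for (seed in 1:5) {
      ds <- random_dataset(40, 6, seed = seed)
      path <- withr::local_tempfile()
      write_mdr_file(ds, path, dialect)
      back <- read_mdr_file(path, dialect)
      expect_equal(back$genotypes, ds$genotypes)
      expect_equal(back$labels, ds$labels)
      expect_equal(back$snp_names, ds$snp_names)
    }
  }
})

test_that("a study-sized synthetic dataset round trips exactly", {
  ds <- generate_dataset(study_profile_spec(), 77, seed = 11)
  expect_equal(ds$n_cases, 193L)
  expect_equal(ds$n_controls, 704L)
  path <- withr::local_tempfile()
  write_mdr_file(ds, path)
  back <- read_mdr_file(path)
  expect_equal(back$genotypes, ds$genotypes)
  expect_equal(back$labels, ds$labels)
})

test_that("writing a dataset with no SNP columns errors", {
  ds <- random_dataset(10, 2, seed = 1)
  ds$snp_names <- character(0)
  expect_error(write_mdr_file(ds, withr::local_tempfile()), "no SNP columns")
})

test_that("cv plans partition individuals into near-equal folds, deterministically", {
  ds <- random_dataset(10, 2, seed = 3)
  plan <- make_cv_plan(ds, 5, seed = 9)
  expect_equal(sort(unique(plan$assignments)), 1:5)
  expect_true(all(table(plan$assignments) == 2L))
  plan2 <- make_cv_plan(ds, 5, seed = 9)
  expect_identical(plan$assignments, plan2$assignments)
  expect_false(identical(plan$assignments,
                         make_cv_plan(ds, 5, seed = 10)$assignments))
  # partition: every individual in exactly one fold
  expect_length(plan$assignments, n_individuals(ds))
})

test_that("non-stratified training-fold imbalance drifts like a random split", {
  # 193 cases / 704 controls, 100 seeds x 10 folds: the control:case ratio
  # of the training complements should centre on the cohort ratio 3.65 with
  # visible spread (roughly 3.4-4.0), unlike a stratified split.
  ds <- genotype_dataset(matrix(0L, 897, 2), c(rep(1L, 193), rep(0L, 704)))
  ratios <- unlist(lapply(1:100, function(s) {
    training_fold_ratios(ds, make_cv_plan(ds, 10, seed = s))
  }))
  expect_equal(mean(ratios), 3.65, tolerance = 0.02)
  expect_gt(stats::sd(ratios), 0.05)
  expect_lt(stats::sd(ratios), 0.2)
  expect_lt(min(ratios), 3.55)
  expect_gt(max(ratios), 3.75)
  strat <- training_fold_ratios(ds, make_cv_plan(ds, 10, seed = 1,
                                                 stratified = TRUE))
  expect_lt(max(strat) - min(strat), 0.1)
})

test_that("undersampling keeps all cases and hits the floor-count of controls", {
  ds <- genotype_dataset(matrix(rep(0:2, length.out = 897 * 3), 897, 3),
                         c(rep(1L, 193), rep(0L, 704)))
  u1 <- undersample(ds, 1, seed = 5)
  expect_equal(u1$n_cases, 193L)
  expect_equal(u1$n_controls, 193L)
  u2 <- undersample(ds, 2, seed = 5)
  expect_equal(u2$n_controls, 386L)
  # ratio equal to current keeps every control
  u_all <- undersample(ds, 704 / 193, seed = 5)
  expect_equal(u_all$n_controls, 704L)
  expect_error(undersample(ds, 5, seed = 5), "up-sampling")
  # genotype rows of retained controls are a sub-multiset of the originals
  orig_keys <- apply(ds$genotypes[ds$labels == 0L, ], 1, paste, collapse = ",")
  kept_keys <- apply(u1$genotypes[u1$labels == 0L, ], 1, paste, collapse = ",")
  expect_true(all(table(kept_keys) <= table(orig_keys)[names(table(kept_keys))]))
  expect_identical(undersample(ds, 1, seed = 5)$genotypes, u1$genotypes)
})
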
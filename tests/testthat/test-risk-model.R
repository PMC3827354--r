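test_that("cell counting reproduces published per-cell breakdowns and totals", {
  ds <- fixture_from_cells(cells_40_56())
  ct <- count_cells(ds, c(1, 2))
  expect_equal(ct$train_cases, 193L)
  expect_equal(ct$train_controls, 704L)
  got <- ct$cells[base::order(ct$cells$key), ]
  expect_equal(got$case_count, c(114L, 57L, 5L, 17L))
  expect_equal(got$control_count, c(342L, 280L, 27L, 55L))
  # single-individual dataset: one cell, one count
  ds1 <- genotype_dataset(matrix(c(1L, 2L), 1, 2), 1L)
  ct1 <- count_cells(ds1, c(1, 2))
  expect_equal(nrow(ct1$cells), 1L)
  expect_equal(ct1$cells$case_count, 1L)
  expect_equal(ct1$cells$control_count, 0L)
})

test_that("cell totals always match the dataset (brute-force recount)", {
  for (seed in 1:10) {
    ds <- random_dataset(50, 5, seed = seed)
    ct <- count_cells(ds, c(2, 4))
    expect_equal(sum(ct$cells$case_count), ds$n_cases)
    expect_equal(sum(ct$cells$control_count), ds$n_controls)
    # recount one cell by hand
    key <- ct$cells$key[1]
    codes <- as.integer(strsplit(key, ",")[[1]])
    rows <- ds$genotypes[, 2] == codes[1] & ds$genotypes[, 4] == codes[2]
    expect_equal(ct$cells$case_count[1], sum(ds$labels[rows] == 1L))
  }
})

test_that("classic ratio scores match the published per-cell values", {
  expect_equal(round(score_cell_ratio(114, 342), 2), 0.33)
  expect_equal(score_cell_ratio(5, 4), 1.25)
  expect_equal(score_cell_ratio(7, 0), Inf)
  expect_equal(score_cell_ratio(0, 9), 0)
  expect_error(score_cell_ratio(0, 0), "no defined score")
})

test_that("percentage-ratio scores match the published worked example", {
  expect_equal(round(score_cell_percentage_ratio(114, 342, 193, 704), 2), 1.22)
  expect_equal(round(score_cell_percentage_ratio(57, 280, 193, 704), 2), 0.74)
  expect_equal(round(score_cell_percentage_ratio(5, 27, 193, 704), 2), 0.68)
  expect_equal(round(score_cell_percentage_ratio(17, 55, 193, 704), 2), 1.13)
  # balanced-data reduction to the classic ratio
  for (cc in c(0, 3, 10)) for (kk in c(1, 4)) {
    expect_equal(score_cell_percentage_ratio(cc, kk, 80, 80),
                 score_cell_ratio(cc, kk))
  }
})

test_that("percentage-ratio is invariant to rescaling the case arm", {
  for (f in c(2, 5, 10)) {
    expect_equal(score_cell_percentage_ratio(3 * f, 40, 25 * f, 300),
                 score_cell_percentage_ratio(3, 40, 25, 300))
  }
})

test_that("cell labeling reproduces both published 2-locus models", {
  ct <- cell_table_from_counts(cells_40_56())
  er <- label_cells(ct, "percentage_ratio", 1)
  labels <- stats::setNames(er$cells$label, er$cells$key)
  expect_equal(labels[["0,0"]], "high")   # 114:342, score 1.22
  expect_equal(labels[["0,1"]], "low")    # 57:280
  expect_equal(labels[["1,0"]], "low")    # 5:27
  expect_equal(labels[["1,1"]], "high")   # 17:55
  # classic ratio labels the same table all-low: every cell is control-heavy
  e <- label_cells(ct, "ratio", 1)
  expect_true(all(e$cells$label == "low"))
  # second model, classic ratio
  e2 <- label_cells(cell_table_from_counts(cells_55_64()), "ratio", 1)
  labels2 <- stats::setNames(e2$cells$label, e2$cells$key)
  expect_equal(unname(labels2[c("0,0", "0,1", "1,0")]),
               c("low", "high", "high"))
})

test_that("labels respond monotonically to count changes", {
  for (seed in 1:20) {
    tbl <- withr::with_seed(seed, {
      n <- sample(2:6, 1)
      stats::setNames(lapply(seq_len(n), function(i) sample(0:30, 2)),
                      paste0(seq_len(n), ",0"))
    })
    tbl <- Filter(function(v) sum(v) > 0, tbl)
    if (length(tbl) == 0) next
    for (classifier in c("ratio", "percentage_ratio")) {
      m <- label_cells(cell_table_from_counts(tbl), classifier, 1)
      i <- withr::with_seed(seed + 100, sample(nrow(m$cells), 1))
      bumped <- tbl
      bumped[[m$cells$key[i]]][1] <- bumped[[m$cells$key[i]]][1] + 5L
      m2 <- label_cells(cell_table_from_counts(bumped), classifier, 1)
      # raising a cell's case count never flips that cell high -> low
      if (m$cells$label[i] == "high") {
        expect_equal(m2$cells$label[m2$cells$key == m$cells$key[i]], "high")
      }
    }
  }
})

test_that("percentage-ratio and ratio labelings agree on balanced tables", {
  for (seed in 1:25) {
    tbl <- withr::with_seed(seed, {
      n <- sample(2:5, 1)
      counts <- lapply(seq_len(n), function(i) sample(1:20, 2))
      stats::setNames(counts, paste0(seq_len(n), ",0"))
    })
    # force balance by mirroring the totals
    tot <- Reduce(`+`, tbl)
    tbl[[length(tbl) + 1L]] <- c(tot[2], tot[1])
    names(tbl)[length(tbl)] <- paste0(length(tbl), ",1")
    ct <- cell_table_from_counts(tbl)
    expect_equal(ct$train_cases, ct$train_controls)
    expect_equal(label_cells(ct, "percentage_ratio", 1)$cells$label,
                 label_cells(ct, "ratio", 1)$cells$label)
  }
})

test_that("threshold ties go to high-risk and zero-count cells follow the limits", {
  tbl <- list("0" = c(5L, 5L), "1" = c(4L, 0L), "2" = c(0L, 6L))
  for (classifier in c("ratio", "percentage_ratio")) {
    m <- label_cells(cell_table_from_counts(tbl), classifier, 1)
    labels <- stats::setNames(m$cells$label, m$cells$key)
    expect_equal(unname(labels[c("1", "2")]), c("high", "low"))
  }
  # score exactly at T under the classic ratio: 5:5 = 1 >= 1 -> high
  m <- label_cells(cell_table_from_counts(tbl), "ratio", 1)
  expect_equal(m$cells$label[m$cells$key == "0"], "high")
})

test_that("a risk model serializes to valid JSON", {
  m <- label_cells(cell_table_from_counts(cells_40_56()), "percentage_ratio")
  parsed <- jsonlite::fromJSON(risk_model_json(m))
  expect_equal(parsed$classifier, "percentage_ratio")
  expect_equal(nrow(parsed$cells), 4L)
})
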
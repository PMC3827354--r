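#' Tabulate case and control counts per genotype combination
#'
#' Partitions a dataset's individuals into the cells of the n-dimensional
#' genotype space spanned by a set of loci, counting cases and controls in
#' each observed cell. Only observed cells appear in the result.
#'
#' @param dataset a `genotype_dataset`.
#' @param locus_set integer vector of SNP column indices (1-based, strictly
#'   increasing) defining the genotype combination.
#' @return An object of class `cell_table`: list with `locus_set`,
#'   `cells` (data.frame with `key`, `case_count`, `control_count`),
#'   `train_cases`, `train_controls`. Keys are genotype codes joined by ",".
#' @examples
#' ds <- genotype_dataset(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2),
#'                        c(1, 1, 0, 0))
#' count_cells(ds, c(1, 2))
#' @export
count_cells <- function(dataset, locus_set) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  locus_set <- as.integer(locus_set)
  if (length(locus_set) < 1L || anyNA(locus_set) ||
      any(locus_set < 1L) || any(locus_set > ncol(dataset$genotypes))) {
    stop("locus_set indices out of range")
  }
  if (is.unsorted(locus_set, strictly = TRUE)) {
    stop("locus_set indices must be strictly increasing")
  }
  g <- dataset$genotypes[, locus_set, drop = FALSE]
  key <- do.call(paste, c(asplit(g, 2), sep = ","))
  is_case <- dataset$labels == 1L
  keys <- unique(key)
  case_count <- as.integer(table(factor(key[is_case], levels = keys)))
  control_count <- as.integer(table(factor(key[!is_case], levels = keys)))
  structure(
    list(
      locus_set = locus_set,
      cells = data.frame(key = keys, case_count = case_count,
                         control_count = control_count,
                         stringsAsFactors = FALSE),
      train_cases = dataset$n_cases,
      train_controls = dataset$n_controls
    ),
    class = "cell_table"
  )
}

#' Build a cell table directly from counts
#'
#' Constructs a `cell_table` from externally supplied per-cell counts, e.g.
#' counts transcribed from a published contingency breakdown.
#'
#' @param cells named list or named integer-pair vectors: names are genotype
#'   keys (codes joined by ","), each value `c(case_count, control_count)`.
#' @param locus_set locus indices the cells refer to (default `1:n` where
#'   `n` is the tuple length of the first key).
#' @return a `cell_table`.
#' @export
cell_table_from_counts <- function(cells, locus_set = NULL) {
  if (length(cells) == 0L) stop("at least one cell is required")
  keys <- names(cells)
  if (is.null(keys) || any(!nzchar(keys))) stop("cells must be named by genotype key")
  m <- do.call(rbind, lapply(cells, function(v) {
    if (length(v) != 2L || any(v < 0)) stop("each cell needs c(case_count, control_count) >= 0")
    as.integer(v)
  }))
  n <- length(strsplit(keys[1L], ",", fixed = TRUE)[[1L]])
  if (is.null(locus_set)) locus_set <- seq_len(n)
  structure(
    list(
      locus_set = as.integer(locus_set),
      cells = data.frame(key = keys, case_count = m[, 1L],
                         control_count = m[, 2L], stringsAsFactors = FALSE),
      train_cases = sum(m[, 1L]),
      train_controls = sum(m[, 2L])
    ),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table over loci (", paste(x$locus_set, collapse = ", "), "): ",
      nrow(x$cells), " observed cells, ", x$train_cases, " cases / ",
      x$train_controls, " controls\n", sep = "")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Classic case:control ratio score of a genotype cell
#'
#' The score of a cell under the classic MDR classifier: the raw ratio of
#' cases to controls in the cell. A cell with cases but no controls scores
#' `Inf` (high-risk at any finite threshold); a cell with controls but no
#' cases scores 0.
#'
#' @param case_count,control_count non-negative cell counts, not both zero.
#' @return the ratio `case_count / control_count` with the above conventions.
#' @export
score_cell_ratio <- function(case_count, control_count) {
  if (any(case_count < 0) || any(control_count < 0)) stop("counts must be non-negative")
  if (any(case_count == 0 & control_count == 0)) {
    stop("cell with zero cases and zero controls has no defined score")
  }
  ifelse(control_count == 0, Inf, case_count / control_count)
}

#' Percentage-ratio score of a genotype cell
#'
#' The imbalance-corrected classifier score: the cell's share of all cases
#' divided by its share of all controls,
#' `(case_count / P*) / (control_count / N*)`, where `P*` and `N*` are the
#' case and control totals of the training set. With balanced data
#' (`P* = N*`) this reduces to [score_cell_ratio()]. For example, a cell
#' holding 114 of 193 cases and 342 of 704 controls scores
#' `(704 * 114) / (193 * 342) = 1.22`, i.e. the cell is enriched for cases
#' relative to the cohort even though controls outnumber cases 3:1 inside it.
#'
#' @param case_count,control_count non-negative cell counts.
#' @param p_star,n_star training-set totals of cases and controls (>= 1).
#' @return the percentage ratio, with the zero/infinity conventions of
#'   [score_cell_ratio()].
#' @export
score_cell_percentage_ratio <- function(case_count, control_count, p_star, n_star) {
  if (p_star < 1 || n_star < 1) stop("p_star and n_star must be at least 1")
  if (any(case_count < 0) || any(control_count < 0)) stop("counts must be non-negative")
  if (any(case_count == 0 & control_count == 0)) {
    stop("cell with zero cases and zero controls has no defined score")
  }
  ifelse(control_count == 0, Inf,
         (n_star * case_count) / (p_star * control_count))
}

#' Label every cell of a cell table high- or low-risk
#'
#' Applies one of the two classifiers to every observed cell and labels the
#' cell high-risk when its score is greater than or equal to the threshold
#' `T` (ties go to high-risk), low-risk otherwise. Cells with cases but no
#' controls score `Inf` and are always high-risk; cells with controls but no
#' cases score 0 and are always low-risk.
#'
#' @param cell_table a `cell_table`.
#' @param classifier `"ratio"` (classic, [score_cell_ratio()]) or
#'   `"percentage_ratio"` ([score_cell_percentage_ratio()]).
#' @param threshold decision threshold `T` (> 0); default 1 for both
#'   classifiers.
#' @return An object of class `risk_model`: list with `locus_set`,
#'   `classifier`, `threshold`, `train_cases`, `train_controls`, and `cells`
#'   (the cell table augmented with `score` and `label` in
#'   `c("high", "low")`).
#' @export
label_cells <- function(cell_table,
                        classifier = c("ratio", "percentage_ratio"),
                        threshold = 1) {
  stopifnot(inherits(cell_table, "cell_table"))
  classifier <- match.arg(classifier)
  if (threshold <= 0) stop("threshold must be positive")
  cells <- cell_table$cells
  score <- if (classifier == "ratio") {
    score_cell_ratio(cells$case_count, cells$control_count)
  } else {
    score_cell_percentage_ratio(cells$case_count, cells$control_count,
                                cell_table$train_cases,
                                cell_table$train_controls)
  }
  cells$score <- score
  cells$label <- ifelse(score >= threshold, "high", "low")
  structure(
    list(
      locus_set = cell_table$locus_set,
      classifier = classifier,
      threshold = threshold,
      train_cases = cell_table$train_cases,
      train_controls = cell_table$train_controls,
      cells = cells
    ),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model (", x$classifier, ", T = ", x$threshold, ") over loci (",
      paste(x$locus_set, collapse = ", "), ")\n", sep = "")
  shown <- x$cells
  shown$score <- round(shown$score, 2)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Serialize a risk model to JSON
#' @param model a `risk_model`.
#' @return a JSON string.
#' @export
risk_model_json <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::toJSON(list(
    locus_set = model$locus_set,
    classifier = model$classifier,
    threshold = model$threshold,
    train_cases = model$train_cases,
    train_controls = model$train_controls,
    cells = model$cells
  ), auto_unbox = TRUE, digits = NA)
}
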
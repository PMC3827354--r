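#' Construct a case-control genotype dataset
#'
#' The central container of the package: an integer genotype matrix
#' (rows = individuals, columns = SNPs) together with a binary class label
#' per individual (1 = case, 0 = control).
#'
#' @param genotypes integer matrix of genotype codes (non-negative; typically
#'   0/1/2 for the three genotypes of a biallelic SNP). Rows are individuals.
#' @param labels integer or logical vector, one per row; 1/TRUE = case,
#'   0/FALSE = control.
#' @param snp_names character vector of unique SNP identifiers; defaults to
#'   the matrix column names, or `SNP1..SNPk`.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `labels`, `snp_names`, `n_cases`, `n_controls`.
#' @examples
#' g <- matrix(c(0, 1, 2, 0, 1, 1, 0, 2), ncol = 2)
#' genotype_dataset(g, c(1, 1, 0, 0))
#' @export
genotype_dataset <- function(genotypes, labels, snp_names = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  labels <- as.integer(labels)
  if (nrow(genotypes) != length(labels)) {
    stop("number of genotype rows (", nrow(genotypes),
         ") does not match number of labels (", length(labels), ")")
  }
  if (anyNA(genotypes)) stop("genotype matrix contains missing values")
  if (any(genotypes < 0L)) stop("genotype codes must be non-negative integers")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (control) or 1 (case)")
  }
  if (is.null(snp_names)) snp_names <- colnames(genotypes)
  if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(genotypes)))
  snp_names <- as.character(snp_names)
  if (length(snp_names) != ncol(genotypes)) {
    stop("snp_names length does not match number of SNP columns")
  }
  if (anyDuplicated(snp_names)) stop("snp_names must be unique")
  colnames(genotypes) <- snp_names
  structure(
    list(
      genotypes  = genotypes,
      labels     = labels,
      snp_names  = snp_names,
      n_cases    = sum(labels == 1L),
      n_controls = sum(labels == 0L)
    ),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset: ", nrow(x$genotypes), " individuals (",
      x$n_cases, " cases / ", x$n_controls, " controls), ",
      length(x$snp_names), " SNPs\n", sep = "")
  invisible(x)
}

#' Number of individuals in a dataset
#' @param dataset a `genotype_dataset`.
#' @return integer row count.
#' @export
n_individuals <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  nrow(dataset$genotypes)
}

#' Subset a genotype dataset by individual
#' @param dataset a `genotype_dataset`.
#' @param idx integer or logical row index.
#' @return a `genotype_dataset` restricted to `idx`.
#' @export
subset_individuals <- function(dataset, idx) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  genotype_dataset(dataset$genotypes[idx, , drop = FALSE],
                   dataset$labels[idx],
                   dataset$snp_names)
}

sep_for_dialect <- function(dialect) {
  dialect <- match.arg(dialect, c("mdr-tab", "csv"))
  if (dialect == "csv") "," else "\t"
}

#' Read a genotype dataset from an MDR flat file
#'
#' The MDR flat-file convention: a header row with SNP names followed by the
#' class-column name, then one row per individual with integer genotype codes
#' and the class in the last column (1 = case, 0 = control). The CSV dialect
#' is identical with a comma separator. Rows containing the missing-value
#' token are dropped and the dropped count reported as a message.
#'
#' @param path file to read.
#' @param dialect `"mdr-tab"` (default, tab-separated) or `"csv"`.
#' @param na_token missing-value token (default `"NA"`).
#' @return a `genotype_dataset`.
#' @seealso [write_mdr_file()]
#' @export
read_mdr_file <- function(path, dialect = c("mdr-tab", "csv"), na_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep_for_dialect(dialect)
  nfields <- utils::count.fields(path, sep = sep, quote = "", comment.char = "")
  if (length(nfields) < 2L) stop("file has no data rows: ", path)
  bad <- which(nfields != nfields[1L])
  if (length(bad)) {
    stop("malformed row: line ", bad[1L] + 0L, " has ", nfields[bad[1L]],
         " fields, expected ", nfields[1L])
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", na.strings = na_token,
                          check.names = FALSE, colClasses = "integer")
  if (ncol(df) < 2L) stop("need at least one SNP column plus a class column")
  complete <- stats::complete.cases(df)
  if (!all(complete)) {
    message("read_mdr_file: dropped ", sum(!complete),
            " row(s) containing missing values")
    df <- df[complete, , drop = FALSE]
  }
  classes <- df[[ncol(df)]]
  if (!all(classes %in% c(0L, 1L))) {
    stop("class column must contain only 0 (control) and 1 (case)")
  }
  geno <- as.matrix(df[, -ncol(df), drop = FALSE])
  ds <- genotype_dataset(geno, classes, colnames(df)[-ncol(df)])
  if (ds$n_cases == 0L || ds$n_controls == 0L) {
    stop("dataset must contain at least one case and one control after loading")
  }
  ds
}

#' Write a genotype dataset to an MDR flat file
#'
#' Inverse of [read_mdr_file()]: the written file reads back into an equal
#' dataset.
#'
#' @param dataset a `genotype_dataset`.
#' @param path output file.
#' @param dialect `"mdr-tab"` or `"csv"`.
#' @param class_name header name for the class column.
#' @return `path`, invisibly.
#' @export
write_mdr_file <- function(dataset, path, dialect = c("mdr-tab", "csv"),
                           class_name = "Class") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (length(dataset$snp_names) == 0L) stop("dataset has no SNP columns")
  sep <- sep_for_dialect(dialect)
  df <- as.data.frame(dataset$genotypes)
  df[[class_name]] <- dataset$labels
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Build a cross-validation plan
#'
#' Assigns every individual to one of `n_folds` folds. The default
#' (non-stratified) scheme permutes individuals uniformly at random and deals
#' them round-robin, so fold sizes differ by at most one but the case:control
#' ratio varies from fold to fold — the behaviour of a plain random split of
#' an imbalanced cohort. With `stratified = TRUE` cases and controls are
#' dealt separately so every fold mirrors the overall ratio.
#'
#' @param dataset a `genotype_dataset`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed; the plan is a deterministic function of it.
#' @param stratified deal cases and controls separately (default `FALSE`).
#' @return an object of class `cv_plan`: list with `n_folds`, `assignments`
#'   (fold index per individual), `seed`, `stratified`.
#' @export
make_cv_plan <- function(dataset, n_folds = 10L, seed, stratified = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- n_individuals(dataset)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (n < n_folds) stop("dataset has fewer rows (", n, ") than folds")
  if (missing(seed)) stop("seed is required: every stochastic operation takes an explicit seed")
  assignments <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      for (cls in c(1L, 0L)) {
        idx <- which(dataset$labels == cls)
        perm <- sample(idx)
        assignments[perm] <- rep_len(seq_len(n_folds), length(perm))
      }
    } else {
      perm <- sample.int(n)
      assignments[perm] <- rep_len(seq_len(n_folds), n)
    }
  })
  for (f in seq_len(n_folds)) {
    train_labels <- dataset$labels[assignments != f]
    if (!any(train_labels == 1L) || !any(train_labels == 0L)) {
      stop("training complement of fold ", f, " has no ",
           if (any(train_labels == 1L)) "controls" else "cases",
           "; use stratified = TRUE or a larger dataset")
    }
  }
  structure(
    list(n_folds = n_folds, assignments = assignments,
         seed = as.integer(seed), stratified = stratified),
    class = "cv_plan"
  )
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("cv_plan: ", x$n_folds, " folds over ", length(x$assignments),
      " individuals (seed ", x$seed,
      if (x$stratified) ", stratified" else "", ")\n", sep = "")
  invisible(x)
}

#' Control:case ratio of each training set in a CV plan
#'
#' For each fold, the ratio of controls to cases in that fold's training
#' complement. Useful for auditing how much a non-stratified split lets the
#' imbalance drift across folds.
#'
#' @param dataset a `genotype_dataset`.
#' @param plan a `cv_plan` built on it.
#' @return numeric vector of length `n_folds`.
#' @export
training_fold_ratios <- function(dataset, plan) {
  stopifnot(inherits(plan, "cv_plan"))
  vapply(seq_len(plan$n_folds), function(f) {
    lab <- dataset$labels[plan$assignments != f]
    sum(lab == 0L) / sum(lab == 1L)
  }, numeric(1))
}

#' Under-sample controls to a target control:case ratio
#'
#' Retains all cases and subsamples controls uniformly at random without
#' replacement down to `floor(n_cases * target_ratio)`. Row order of the
#' retained individuals is preserved.
#'
#' @param dataset a `genotype_dataset`.
#' @param target_ratio desired controls per case; must not exceed the current
#'   ratio (up-sampling is not supported).
#' @param seed integer seed.
#' @return a `genotype_dataset` with the reduced control group.
#' @export
undersample <- function(dataset, target_ratio, seed) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (missing(seed)) stop("seed is required")
  current <- dataset$n_controls / dataset$n_cases
  if (target_ratio > current) {
    stop("target_ratio (", target_ratio, ") exceeds current control:case ratio (",
         round(current, 3), "); up-sampling is not supported")
  }
  n_keep <- floor(dataset$n_cases * target_ratio)
  if (n_keep < 1L) stop("target_ratio leaves no controls")
  ctrl_idx <- which(dataset$labels == 0L)
  keep_ctrl <- withr::with_seed(as.integer(seed), sample(ctrl_idx, n_keep))
  keep <- sort(c(which(dataset$labels == 1L), keep_ctrl))
  subset_individuals(dataset, keep)
}
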
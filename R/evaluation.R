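#' Apply a risk model to a dataset
#'
#' Routes every individual through the model: the individual's genotype
#' combination is looked up among the model's cells, and the individual is
#' predicted high- or low-risk by that cell's label. Individuals whose
#' genotype combination was never observed when the model was fitted are
#' predicted low-risk (the conservative choice toward the majority class)
#' and counted in `unseen_cell_individuals` so the effect can be audited.
#'
#' @param model a `risk_model`.
#' @param dataset a `genotype_dataset` whose columns cover the model's loci.
#' @return An object of class `contingency_table`: list with integer `TP`,
#'   `FP`, `FN`, `TN` and `unseen_cell_individuals`. High-risk cases count
#'   as TP, high-risk controls as FP, low-risk cases as FN, low-risk
#'   controls as TN.
#' @export
apply_model <- function(model, dataset) {
  stopifnot(inherits(model, "risk_model"), inherits(dataset, "genotype_dataset"))
  if (max(model$locus_set) > ncol(dataset$genotypes)) {
    stop("dataset does not cover the model's locus set")
  }
  g <- dataset$genotypes[, model$locus_set, drop = FALSE]
  key <- do.call(paste, c(asplit(g, 2), sep = ","))
  pos <- match(key, model$cells$key)
  high <- !is.na(pos) & model$cells$label[pos] == "high"
  is_case <- dataset$labels == 1L
  contingency_table(
    TP = sum(high & is_case),
    FP = sum(high & !is_case),
    FN = sum(!high & is_case),
    TN = sum(!high & !is_case),
    unseen_cell_individuals = sum(is.na(pos))
  )
}

#' Construct a 2x2 contingency table
#'
#' @param TP,FP,FN,TN non-negative integer counts: cases and controls
#'   predicted high-risk (TP, FP) and low-risk (FN, TN).
#' @param unseen_cell_individuals how many of the evaluated individuals fell
#'   in genotype cells absent at fit time (they are in FN/TN).
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(TP, FP, FN, TN, unseen_cell_individuals = 0L) {
  v <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (anyNA(v) || any(v < 0)) stop("contingency counts must be non-negative")
  structure(
    list(TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN),
         TN = as.integer(TN),
         unseen_cell_individuals = as.integer(unseen_cell_individuals)),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(c("pred high", "pred low"),
                              c("case", "control")))
  print(m)
  if (x$unseen_cell_individuals > 0L) {
    cat("(", x$unseen_cell_individuals,
        " individuals fell in cells unseen at fit time)\n", sep = "")
  }
  invisible(x)
}

#' Raw misclassification error
#'
#' The fraction of evaluated individuals assigned to the wrong class:
#' `(FP + FN) / (TP + FP + FN + TN)`. Under heavy class imbalance this
#' error can be driven arbitrarily close to the minority-class frequency by
#' always predicting the majority class, which is what motivates
#' [error_balanced()].
#'
#' @param ct a `contingency_table` with at least one evaluated individual.
#' @return error in `[0, 1]`.
#' @export
error_standard <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  total <- ct$TP + ct$FP + ct$FN + ct$TN
  if (total == 0L) stop("no individuals evaluated")
  (ct$FP + ct$FN) / total
}

#' Balanced classification error
#'
#' One minus the arithmetic mean of sensitivity and specificity:
#' `1 - (TP/(TP+FN) + TN/(TN+FP)) / 2`. Both classes contribute equally
#' regardless of their sizes; with exactly balanced classes
#' (`TP + FN = FP + TN`) it coincides algebraically with [error_standard()].
#' A classifier that always predicts one class scores exactly 0.5.
#'
#' @param ct a `contingency_table`; both classes must have at least one
#'   evaluated individual.
#' @return error in `[0, 1]`.
#' @export
error_balanced <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  if (ct$TP + ct$FN == 0L) stop("no cases evaluated: balanced error undefined")
  if (ct$FP + ct$TN == 0L) stop("no controls evaluated: balanced error undefined")
  p <- ct$TP + ct$FN
  n <- ct$FP + ct$TN
  # integer-ratio form: bit-identical to error_standard() when p == n
  (ct$FN * n + ct$FP * p) / (2 * p * n)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (TP * TN) / (FP * FN)` with the log-scale (Woolf) interval
#' `exp(log(OR) +/- z * sqrt(1/TP + 1/FP + 1/FN + 1/TN))`. If any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to all four cells (a
#' message is emitted).
#'
#' @param ct a `contingency_table`.
#' @param z normal quantile for the interval (default 1.96 for 95%).
#' @return named numeric vector `c(or, low, high)`.
#' @export
odds_ratio_ci <- function(ct, z = 1.96) {
  stopifnot(inherits(ct, "contingency_table"))
  cells <- c(ct$TP, ct$FP, ct$FN, ct$TN)
  if (any(cells == 0L)) {
    message("odds_ratio_ci: zero cell present; applying Haldane-Anscombe +0.5")
    cells <- cells + 0.5
  }
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  se <- sqrt(sum(1 / cells))
  c(or = or, low = exp(log(or) - z * se), high = exp(log(or) + z * se))
}

#' Full statistics of a contingency table
#'
#' Computes both error rates, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, balanced accuracy (`1 -` balanced error), the Woolf
#' odds-ratio interval and a Pearson chi-square p-value (1 df, no continuity
#' correction) for the association between predicted risk group and class.
#'
#' @param ct a `contingency_table`.
#' @return An object of class `model_stats`: list with `error_standard`,
#'   `error_balanced`, `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `odds_ratio`, `or_ci_low`, `or_ci_high`, `chi2_p`.
#' @export
model_stats <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  eb <- error_balanced(ct)
  or <- suppressMessages(odds_ratio_ci(ct))
  m <- matrix(c(ct$TP, ct$FP, ct$FN, ct$TN), 2, 2)
  chi2_p <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    NA_real_
  } else {
    # asymptotic p-value; small expected counts make it approximate
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  }
  structure(
    list(
      error_standard = error_standard(ct),
      error_balanced = eb,
      sensitivity = ct$TP / (ct$TP + ct$FN),
      specificity = ct$TN / (ct$TN + ct$FP),
      balanced_accuracy = 1 - eb,
      odds_ratio = unname(or["or"]),
      or_ci_low = unname(or["low"]),
      or_ci_high = unname(or["high"]),
      chi2_p = chi2_p
    ),
    class = "model_stats"
  )
}

#' @export
print.model_stats <- function(x, ...) {
  cat(sprintf(
    paste0("error (raw) %.2f | error (balanced) %.2f | accuracy (balanced) %.2f\n",
           "sensitivity %.3f | specificity %.3f\n",
           "OR %.2f (%.2f-%.2f) | chi-square p %.3g\n"),
    x$error_standard, x$error_balanced, x$balanced_accuracy,
    x$sensitivity, x$specificity,
    x$odds_ratio, x$or_ci_low, x$or_ci_high, x$chi2_p))
  invisible(x)
}
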
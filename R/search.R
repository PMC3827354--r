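#' Method definitions
#'
#' Three MDR variants are supported:
#' * `mdr` — classic: case:control ratio classifier, raw misclassification
#'   error.
#' * `mdr_e` — ratio classifier, balanced error.
#' * `mdr_er` — percentage-ratio classifier, balanced error; the variant
#'   designed for imbalanced cohorts.
#'
#' @param method method name.
#' @return list with `classifier` and `error` (`"standard"` or `"balanced"`).
#' @keywords internal
method_spec <- function(method = c("mdr", "mdr_e", "mdr_er")) {
  method <- match.arg(method)
  switch(method,
    mdr    = list(classifier = "ratio",            error = "standard"),
    mdr_e  = list(classifier = "ratio",            error = "balanced"),
    mdr_er = list(classifier = "percentage_ratio", error = "balanced"))
}

#' Enumerate all locus sets of a given order
#'
#' All `choose(n_snps, order)` combinations of SNP column indices, in
#' lexicographic order. This order defines "found first" for every
#' tie-break in the package.
#'
#' @param n_snps number of SNP columns.
#' @param order combination size (1 <= order <= n_snps).
#' @return integer matrix with `order` rows; each column is one locus set.
#' @examples
#' enumerate_locus_sets(4, 2)  # 6 pairs
#' @export
enumerate_locus_sets <- function(n_snps, order) {
  n_snps <- as.integer(n_snps)
  order <- as.integer(order)
  if (order < 1L || order > n_snps) stop("order must be between 1 and n_snps")
  m <- utils::combn(n_snps, order)
  storage.mode(m) <- "integer"
  m
}

locus_key <- function(locus_set) paste(locus_set, collapse = ",")

encode_loci <- function(genotypes, locus_set, base) {
  id <- genotypes[, locus_set[1L]]
  for (j in locus_set[-1L]) id <- id * base + genotypes[, j]
  id
}

#' Evaluate one cross-validation fold
#'
#' Enumerates every locus set of the given order, fits the method's risk
#' model on the training set, and keeps the set with the minimum training
#' error (ties broken by enumeration order, i.e. the set found first). The
#' chosen model is then applied to the held-out test set to obtain its
#' prediction error under the same error functional; test individuals whose
#' genotype cell was not observed in training are predicted low-risk.
#'
#' @param train,test disjoint `genotype_dataset`s with identical SNP columns.
#' @param order locus-set size.
#' @param method `"mdr"`, `"mdr_e"` or `"mdr_er"` (see [method_spec()]).
#' @param threshold classifier threshold `T` (default 1).
#' @return list with `best_locus_set` (integer vector), `training_error`,
#'   `prediction_error` (NA if the test fold lacks one class under the
#'   balanced functional).
#' @export
run_fold <- function(train, test, order, method = c("mdr", "mdr_e", "mdr_er"),
                     threshold = 1) {
  method <- match.arg(method)
  spec <- method_spec(method)
  if (train$n_cases == 0L || train$n_controls == 0L) {
    stop("training set must contain at least one case and one control")
  }
  sets <- enumerate_locus_sets(ncol(train$genotypes), order)
  base <- max(train$genotypes, test$genotypes) + 1L
  nb <- as.integer(base^order)
  gtr <- train$genotypes
  case_tr <- train$labels == 1L
  p_star <- train$n_cases
  n_star <- train$n_controls

  best_j <- NA_integer_
  best_err <- Inf
  best_high <- NULL
  best_obs <- NULL
  for (j in seq_len(ncol(sets))) {
    ls <- sets[, j]
    id <- encode_loci(gtr, ls, base)
    pc <- tabulate(id[case_tr] + 1L, nb)
    nc <- tabulate(id[!case_tr] + 1L, nb)
    obs <- (pc + nc) > 0L
    sc <- if (spec$classifier == "ratio") pc / nc else (n_star * pc) / (p_star * nc)
    sc[nc == 0L & pc > 0L] <- Inf
    high <- obs & !is.na(sc) & sc >= threshold
    TP <- sum(pc[high])
    FP <- sum(nc[high])
    TN <- n_star - FP
    err <- if (spec$error == "standard") {
      (FP + (p_star - TP)) / (p_star + n_star)
    } else {
      # integer-ratio form so ties agree exactly with the raw error when
      # the training classes are balanced
      ((p_star - TP) * n_star + FP * p_star) / (2 * p_star * n_star)
    }
    if (err < best_err) {
      best_err <- err
      best_j <- j
      best_high <- high
      best_obs <- obs
    }
  }

  ls <- sets[, best_j]
  id_te <- encode_loci(test$genotypes, ls, base)
  high_te <- best_high[id_te + 1L]           # unseen cells carry FALSE via obs mask
  case_te <- test$labels == 1L
  TPte <- sum(high_te & case_te)
  FPte <- sum(high_te & !case_te)
  p_te <- sum(case_te)
  n_te <- sum(!case_te)
  pred_err <- if (spec$error == "standard") {
    if (p_te + n_te == 0L) NA_real_ else (FPte + (p_te - TPte)) / (p_te + n_te)
  } else {
    if (p_te == 0L || n_te == 0L) NA_real_
    else ((p_te - TPte) * n_te + FPte * p_te) / (2 * p_te * n_te)
  }
  list(best_locus_set = ls, training_error = best_err,
       prediction_error = pred_err)
}

#' Exhaustive cross-validated search for the best locus set
#'
#' Runs [run_fold()] on every fold of a cross-validation plan, tallies how
#' often each locus set wins a fold (the cross-validation consistency, CVC),
#' and selects the final model by: highest CVC, then lowest mean prediction
#' error over the folds it won, then enumeration order (found first). The
#' final model is refit on the full dataset and its statistics computed
#' there.
#'
#' @param dataset a `genotype_dataset`.
#' @param order locus-set size.
#' @param method `"mdr"`, `"mdr_e"` or `"mdr_er"`.
#' @param cv_plan a `cv_plan` from [make_cv_plan()].
#' @param threshold classifier threshold `T`.
#' @return An object of class `mdr_search`: list with `method`, `order`,
#'   `fold_results` (one [run_fold()] result per fold, with `fold_index`),
#'   `cvc` (named integer vector, locus key -> folds won), `final_locus_set`,
#'   `final_model` (a `risk_model` refit on all data), `final_table`
#'   (its `contingency_table` on all data), `final_stats` (a `model_stats`),
#'   `threshold`.
#' @export
run_search <- function(dataset, order, method = c("mdr", "mdr_e", "mdr_er"),
                       cv_plan, threshold = 1) {
  method <- match.arg(method)
  stopifnot(inherits(cv_plan, "cv_plan"))
  spec <- method_spec(method)

  fold_results <- vector("list", cv_plan$n_folds)
  for (f in seq_len(cv_plan$n_folds)) {
    train <- subset_individuals(dataset, cv_plan$assignments != f)
    test <- subset_individuals(dataset, cv_plan$assignments == f)
    fr <- run_fold(train, test, order, method, threshold)
    fr$fold_index <- f
    fold_results[[f]] <- fr
  }

  keys <- vapply(fold_results, function(fr) locus_key(fr$best_locus_set),
                 character(1))
  cvc <- table(keys)
  cand_keys <- names(cvc)
  cand_sets <- lapply(strsplit(cand_keys, ",", fixed = TRUE), as.integer)
  mean_pred <- vapply(cand_keys, function(k) {
    mean(vapply(fold_results[keys == k],
                function(fr) fr$prediction_error, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  # lexicographic rank of each candidate tuple = enumeration order
  lex <- do.call(base::order, as.data.frame(do.call(rbind, cand_sets)))
  lex_rank <- integer(length(cand_keys))
  lex_rank[lex] <- seq_along(lex)
  pick <- base::order(-as.integer(cvc), mean_pred, lex_rank)[1L]
  final_set <- cand_sets[[pick]]

  final_model <- label_cells(count_cells(dataset, final_set),
                             classifier = spec$classifier,
                             threshold = threshold)
  final_table <- apply_model(final_model, dataset)
  structure(
    list(
      method = method, order = as.integer(order),
      fold_results = fold_results,
      cvc = stats::setNames(as.integer(cvc), cand_keys),
      final_locus_set = final_set,
      final_model = final_model,
      final_table = final_table,
      final_stats = model_stats(final_table),
      threshold = threshold
    ),
    class = "mdr_search"
  )
}

#' @export
print.mdr_search <- function(x, ...) {
  best_key <- locus_key(x$final_locus_set)
  cat("mdr_search (", x$method, ", order ", x$order, "): best model (",
      best_key, "), CVC ", x$cvc[[best_key]], "/",
      length(x$fold_results), "\n", sep = "")
  print(x$final_stats)
  invisible(x)
}

#' Repeat the cross-validated search over many random CV splits
#'
#' Runs [run_search()] with `n_repeats` distinct CV seeds (derived as
#' `base_seed + 0:(n_repeats-1)`), tallies how often each locus set is the
#' final model, and reports the modal ("best candidate") model with its
#' statistics on the full dataset. Ties on frequency go to the
#' lexicographically first locus set.
#'
#' @param dataset a `genotype_dataset`.
#' @param order locus-set size.
#' @param method `"mdr"`, `"mdr_e"` or `"mdr_er"`.
#' @param n_repeats number of repeated CV runs (>= 1).
#' @param base_seed integer; run `i` uses seed `base_seed + i - 1`.
#' @param n_folds folds per run (default 10).
#' @param stratified passed to [make_cv_plan()].
#' @param threshold classifier threshold `T`.
#' @return An object of class `mdr_repeated`: list with `method`, `order`,
#'   `n_repeats`, `frequencies` (named integer vector, locus key -> times
#'   selected), `modal_locus_set`, `modal_frequency`, `modal_model`,
#'   `modal_table`, `modal_stats`, and `per_run` (data.frame of seed, final
#'   locus key, CVC of the final model in that run).
#' @export
repeated_runs <- function(dataset, order, method = c("mdr", "mdr_e", "mdr_er"),
                          n_repeats, base_seed, n_folds = 10L,
                          stratified = FALSE, threshold = 1) {
  method <- match.arg(method)
  if (n_repeats < 1L) stop("n_repeats must be at least 1")
  spec <- method_spec(method)
  seeds <- as.integer(base_seed) + seq_len(n_repeats) - 1L
  finals <- character(n_repeats)
  final_cvc <- integer(n_repeats)
  for (i in seq_len(n_repeats)) {
    plan <- make_cv_plan(dataset, n_folds, seed = seeds[i],
                         stratified = stratified)
    res <- run_search(dataset, order, method, plan, threshold)
    finals[i] <- locus_key(res$final_locus_set)
    final_cvc[i] <- res$cvc[[finals[i]]]
  }
  freq <- table(finals)
  cand <- names(freq)
  cand_sets <- lapply(strsplit(cand, ",", fixed = TRUE), as.integer)
  lex <- do.call(base::order, as.data.frame(do.call(rbind, cand_sets)))
  lex_rank <- integer(length(cand)); lex_rank[lex] <- seq_along(lex)
  pick <- base::order(-as.integer(freq), lex_rank)[1L]
  modal_set <- cand_sets[[pick]]
  modal_model <- label_cells(count_cells(dataset, modal_set),
                             classifier = spec$classifier,
                             threshold = threshold)
  modal_table <- apply_model(modal_model, dataset)
  structure(
    list(
      method = method, order = as.integer(order), n_repeats = n_repeats,
      frequencies = stats::setNames(as.integer(freq), cand),
      modal_locus_set = modal_set,
      modal_frequency = as.integer(freq[[pick]]),
      modal_model = modal_model,
      modal_table = modal_table,
      modal_stats = model_stats(modal_table),
      per_run = data.frame(seed = seeds, final = finals, cvc = final_cvc,
                           stringsAsFactors = FALSE),
      threshold = threshold
    ),
    class = "mdr_repeated"
  )
}

#' @export
print.mdr_repeated <- function(x, ...) {
  cat("mdr_repeated (", x$method, ", order ", x$order, "): best candidate (",
      locus_key(x$modal_locus_set), "), consistency ", x$modal_frequency,
      "/", x$n_repeats, "\n", sep = "")
  print(x$modal_stats)
  invisible(x)
}

#' Landscape of all models of one order
#'
#' Evaluates every locus set of the given order on the full dataset under
#' the method's classifier, sorts all models by balanced error, and keeps
#' `n_samples` of them by systematic (equal-stride) sampling. For each
#' retained model it reports TP, TN, the log10 of the TP and TN percentages
#' (e.g. TP = 131 of 193 cases is 67.88%, log10 value 1.83; a zero count
#' gives NA), both error rates, and the number of high- and low-risk cells.
#'
#' @param dataset a `genotype_dataset`.
#' @param order locus-set size; `choose(n_snps, order)` must be at least
#'   `n_samples`.
#' @param method `"mdr"`, `"mdr_e"` or `"mdr_er"`.
#' @param n_samples models to retain (default 100).
#' @param threshold classifier threshold `T`.
#' @return data.frame, one row per sampled model, sorted by non-decreasing
#'   balanced error: `model` (locus key), `TP`, `TN`, `log10_tp_pct`,
#'   `log10_tn_pct`, `error_balanced`, `error_standard`, `n_high`, `n_low`.
#' @export
model_landscape <- function(dataset, order, method = c("mdr", "mdr_e", "mdr_er"),
                            n_samples = 100L, threshold = 1) {
  method <- match.arg(method)
  spec <- method_spec(method)
  sets <- enumerate_locus_sets(ncol(dataset$genotypes), order)
  m <- ncol(sets)
  if (m < n_samples) {
    stop("only ", m, " models of order ", order, " exist; need at least ",
         n_samples)
  }
  base <- max(dataset$genotypes) + 1L
  nb <- as.integer(base^order)
  is_case <- dataset$labels == 1L
  p <- dataset$n_cases
  n <- dataset$n_controls

  recs <- vapply(seq_len(m), function(j) {
    ls <- sets[, j]
    id <- encode_loci(dataset$genotypes, ls, base)
    pc <- tabulate(id[is_case] + 1L, nb)
    nc <- tabulate(id[!is_case] + 1L, nb)
    obs <- (pc + nc) > 0L
    sc <- if (spec$classifier == "ratio") pc / nc else (n * pc) / (p * nc)
    sc[nc == 0L & pc > 0L] <- Inf
    high <- obs & !is.na(sc) & sc >= threshold
    TP <- sum(pc[high]); FP <- sum(nc[high])
    TN <- n - FP; FN <- p - TP
    c(TP = TP, TN = TN,
      error_balanced = ((p - TP) * n + FP * p) / (2 * p * n),
      error_standard = (FP + FN) / (p + n),
      n_high = sum(high), n_low = sum(obs & !high))
  }, numeric(6))

  ord <- base::order(recs["error_balanced", ])
  take <- ord[ceiling(seq_len(n_samples) * m / n_samples)]
  # re-sort retained models by error (systematic stride preserves order)
  df <- data.frame(
    model = vapply(take, function(j) locus_key(sets[, j]), character(1)),
    TP = recs["TP", take],
    TN = recs["TN", take],
    log10_tp_pct = ifelse(recs["TP", take] > 0,
                          log10(100 * recs["TP", take] / p), NA_real_),
    log10_tn_pct = ifelse(recs["TN", take] > 0,
                          log10(100 * recs["TN", take] / n), NA_real_),
    error_balanced = recs["error_balanced", take],
    error_standard = recs["error_standard", take],
    n_high = recs["n_high", take],
    n_low = recs["n_low", take],
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}
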
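# Independent brute-force re-implementation of one cross-validation fold,
# used as an oracle against run_fold(). Deliberately shares no code with the
# package internals: cells are keyed by pasted strings, counts accumulated
# per unique key, individuals routed one at a time.
oracle_run_fold <- function(train, test, order, method, threshold = 1) {
  combs <- utils::combn(ncol(train$genotypes), order, simplify = FALSE)
  use_pct <- method == "mdr_er"
  balanced <- method %in% c("mdr_e", "mdr_er")
  p_star <- sum(train$labels == 1L)
  n_star <- sum(train$labels == 0L)

  cell_score <- function(cc, kk) {
    if (kk == 0L) return(Inf)
    if (cc == 0L) return(0)
    if (use_pct) (cc / p_star) / (kk / n_star) else cc / kk
  }

  best <- NULL
  for (ls in combs) {
    keys <- apply(train$genotypes[, ls, drop = FALSE], 1L, paste, collapse = "|")
    high_keys <- character(0)
    tp <- 0L; fp <- 0L
    for (k in unique(keys)) {
      rows <- keys == k
      cc <- sum(train$labels[rows] == 1L)
      kk <- sum(train$labels[rows] == 0L)
      if (cell_score(cc, kk) >= threshold) {
        high_keys <- c(high_keys, k)
        tp <- tp + cc
        fp <- fp + kk
      }
    }
    fn <- p_star - tp
    tn <- n_star - fp
    # single-division rational form so exact ties stay exact in floats
    err <- if (balanced) (fn * n_star + fp * p_star) / (2 * p_star * n_star)
           else (fp + fn) / (p_star + n_star)
    if (is.null(best) || err < best$err) {
      best <- list(ls = ls, err = err, high_keys = high_keys)
    }
  }

  tp <- 0L; fp <- 0L; p_te <- 0L; n_te <- 0L
  for (i in seq_len(nrow(test$genotypes))) {
    k <- paste(test$genotypes[i, best$ls], collapse = "|")
    is_case <- test$labels[i] == 1L
    if (is_case) p_te <- p_te + 1L else n_te <- n_te + 1L
    if (k %in% best$high_keys) {
      if (is_case) tp <- tp + 1L else fp <- fp + 1L
    }
  }
  pred <- if (balanced) {
    if (p_te == 0L || n_te == 0L) NA_real_
    else ((p_te - tp) * n_te + fp * p_te) / (2 * p_te * n_te)
  } else {
    (fp + (p_te - tp)) / (p_te + n_te)
  }
  list(best_locus_set = best$ls, training_error = best$err,
       prediction_error = pred)
}
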
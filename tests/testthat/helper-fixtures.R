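# Published per-cell case:control breakdowns of the two 2-locus models used
# as worked examples throughout the suite. Keys are genotype tuples of the
# reconstructed fixture dataset (the original genotype codes are immaterial:
# only the per-cell counts matter to the classifiers).
cells_40_56 <- function() {
  list("0,0" = c(114L, 342L), "0,1" = c(57L, 280L),
       "1,0" = c(5L, 27L),   "1,1" = c(17L, 55L))
}

cells_55_64 <- function() {
  list("0,0" = c(174L, 689L), "0,1" = c(5L, 4L), "1,0" = c(14L, 11L))
}

# Random dataset with both classes guaranteed present.
random_dataset <- function(n, k, p_case = 0.3, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:2, n * k, replace = TRUE), n, k)
    lab <- stats::rbinom(n, 1L, p_case)
    lab[1:2] <- c(1L, 0L)
    genotype_dataset(g, lab)
  })
}

# Frozen generator conditions for the planted-effect experiments: a 1:4
# imbalanced cohort with a moderate two-locus XOR effect at which neither
# method recovers the causal pair every time.
planted_spec <- function() {
  penetrance_spec(causal_loci = c(1L, 2L),
                  penetrance = xor_penetrance(baseline = 0.10, effect = 0.25),
                  mafs = 0.3, n_cases = 50L, n_controls = 200L)
}

flat_spec <- function(p = 0.3, n_cases = 150L, n_controls = 350L) {
  keys <- names(xor_penetrance())
  penetrance_spec(causal_loci = c(1L, 2L),
                  penetrance = stats::setNames(rep(p, length(keys)), keys),
                  mafs = 0.3, n_cases = n_cases, n_controls = n_controls)
}
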
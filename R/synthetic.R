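#' Specify a penetrance model for synthetic case-control data
#'
#' A penetrance table maps each genotype combination at the causal loci to a
#' disease probability; it is the standard device for planting an epistatic
#' effect in simulated data. Genotypes are coded 0/1/2 (copies of the minor
#' allele) and drawn per SNP under Hardy-Weinberg equilibrium from its minor
#' allele frequency.
#'
#' @param causal_loci integer indices (within the simulated SNP panel) of
#'   the interacting loci.
#' @param penetrance named numeric vector: names are genotype keys at the
#'   causal loci (codes joined by ",", e.g. `"0,2"`), values are disease
#'   probabilities in `[0, 1]`. Every one of the `3^k` combinations must be
#'   present.
#' @param mafs minor-allele frequencies in `(0, 0.5]`: a scalar recycled to
#'   all SNPs, or one value per SNP.
#' @param n_cases,n_controls target group sizes (the generator fills both
#'   quotas exactly).
#' @return an object of class `penetrance_spec`.
#' @seealso [generate_dataset()], [xor_penetrance()]
#' @export
penetrance_spec <- function(causal_loci, penetrance, mafs, n_cases, n_controls) {
  causal_loci <- as.integer(causal_loci)
  if (anyDuplicated(causal_loci)) stop("causal loci must be distinct")
  k <- length(causal_loci)
  want <- apply(expand.grid(rep(list(0:2), k)), 1, paste, collapse = ",")
  if (is.null(names(penetrance)) || !all(want %in% names(penetrance))) {
    stop("penetrance must name all ", 3^k, " genotype combinations")
  }
  if (any(penetrance < 0) || any(penetrance > 1)) {
    stop("penetrance values must lie in [0, 1]")
  }
  if (any(mafs <= 0) || any(mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
  if (n_cases < 1L || n_controls < 1L) stop("need at least one case and one control")
  structure(
    list(causal_loci = causal_loci, penetrance = penetrance[want],
         mafs = mafs, n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls)),
    class = "penetrance_spec"
  )
}

#' XOR-style two-locus penetrance table
#'
#' A convenience constructor for the classic epistatic pattern with no
#' marginal effects: risk is elevated when exactly one of the two loci
#' carries a minor allele (heterosis-like XOR pattern), baseline otherwise.
#'
#' @param baseline disease probability off-pattern.
#' @param effect disease probability on-pattern.
#' @return named numeric vector usable as `penetrance` in
#'   [penetrance_spec()].
#' @export
xor_penetrance <- function(baseline = 0.05, effect = 0.3) {
  g <- expand.grid(a = 0:2, b = 0:2)
  on <- xor(g$a == 1, g$b == 1)
  stats::setNames(ifelse(on, effect, baseline),
                  paste(g$a, g$b, sep = ","))
}

hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Generate an imbalanced case-control dataset with a planted effect
#'
#' Rejection sampling: individuals are drawn one batch at a time, genotypes
#' sampled per SNP under Hardy-Weinberg equilibrium, disease status sampled
#' from the penetrance of the individual's causal genotype combination, and
#' individuals kept until exactly `n_cases` cases and `n_controls` controls
#' have been collected. Non-causal SNPs are independent of status, so the
#' case-control sampling introduces no spurious association outside the
#' causal loci.
#'
#' @param spec a `penetrance_spec`.
#' @param n_snps total SNP panel size (>= number of causal loci).
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @param max_draws bound on total individuals drawn before the generator
#'   gives up (guards against unreachable quotas, e.g. near-zero penetrance
#'   everywhere with a large case target).
#' @return a `genotype_dataset` with exactly the requested group sizes.
#' @export
generate_dataset <- function(spec, n_snps, seed,
                             max_draws = 1000L * (spec$n_cases + spec$n_controls)) {
  stopifnot(inherits(spec, "penetrance_spec"))
  n_snps <- as.integer(n_snps)
  if (n_snps < length(spec$causal_loci)) {
    stop("n_snps must cover the causal loci")
  }
  if (max(spec$causal_loci) > n_snps) stop("causal locus index exceeds n_snps")
  if (missing(seed)) stop("seed is required")
  mafs <- rep_len(spec$mafs, n_snps)
  need_case <- spec$n_cases
  need_ctrl <- spec$n_controls
  keep_geno <- vector("list", 0L)
  keep_lab <- integer(0)
  drawn <- 0L

  withr::with_seed(as.integer(seed), {
    while (need_case > 0L || need_ctrl > 0L) {
      b <- max(64L, 2L * (need_case + need_ctrl))
      if (drawn + b > max_draws) b <- max_draws - drawn
      if (b <= 0L) {
        stop("generator did not reach the case/control quotas within ",
             max_draws, " draws; penetrance targets may be unreachable")
      }
      g <- vapply(seq_len(n_snps), function(j) {
        sample.int(3L, b, replace = TRUE, prob = hwe_probs(mafs[j])) - 1L
      }, integer(b))
      if (b == 1L) g <- matrix(g, nrow = 1L)
      key <- do.call(paste, c(asplit(g[, spec$causal_loci, drop = FALSE], 2),
                              sep = ","))
      p <- spec$penetrance[key]
      status <- as.integer(stats::runif(b) < p)
      drawn <- drawn + b
      take <- (status == 1L & cumsum(status == 1L) <= need_case) |
              (status == 0L & cumsum(status == 0L) <= need_ctrl)
      if (any(take)) {
        keep_geno[[length(keep_geno) + 1L]] <- g[take, , drop = FALSE]
        keep_lab <- c(keep_lab, status[take])
        need_case <- spec$n_cases - sum(keep_lab == 1L)
        need_ctrl <- spec$n_controls - sum(keep_lab == 0L)
      }
    }
  })
  genotype_dataset(do.call(rbind, keep_geno), keep_lab)
}

#' Default emulation profile of the study cohort
#'
#' A `penetrance_spec` mirroring the chronic-dialysis mitochondrial D-loop
#' cohort the method was developed on: 193 cases, 704 controls (control:case
#' ratio 3.65:1), 77 SNPs, with a moderate two-locus XOR effect planted so
#' the panel is not pure noise. The real cohort is not distributed; this is
#' a synthetic stand-in with the same shape and imbalance.
#'
#' @param causal_loci two loci carrying the planted effect.
#' @param baseline,effect penetrance off/on the XOR pattern.
#' @param maf minor-allele frequency for every SNP.
#' @return a `penetrance_spec`; pass to [generate_dataset()] with
#'   `n_snps = 77`.
#' @export
study_profile_spec <- function(causal_loci = c(40L, 56L),
                               baseline = 0.1, effect = 0.35, maf = 0.3) {
  penetrance_spec(causal_loci = causal_loci,
                  penetrance = xor_penetrance(baseline, effect),
                  mafs = maf, n_cases = 193L, n_controls = 704L)
}

#' Reconstruct a dataset from published per-cell counts
#'
#' Builds a `genotype_dataset` whose [count_cells()] on the first `k` SNP
#' columns reproduces the supplied cell counts exactly (k = tuple length of
#' the keys). This turns a printed per-genotype case/control breakdown into
#' an executable fixture. Padding SNPs, filled with uniform random codes
#' 0/1/2 independent of everything else, can be appended after the `k`
#' designated columns.
#'
#' @param cells named list: names are genotype keys (codes joined by ","),
#'   values `c(case_count, control_count)`.
#' @param n_pad_snps number of noise SNPs to append (default 0).
#' @param seed integer seed for the padding (required if `n_pad_snps > 0`).
#' @return a `genotype_dataset` with `sum(cases)` cases and `sum(controls)`
#'   controls; the designated loci are columns `1:k`.
#' @export
fixture_from_cells <- function(cells, n_pad_snps = 0L, seed = NULL) {
  ct <- cell_table_from_counts(cells)
  k <- length(strsplit(ct$cells$key[1L], ",", fixed = TRUE)[[1L]])
  rows <- list()
  labs <- integer(0)
  for (i in seq_len(nrow(ct$cells))) {
    codes <- as.integer(strsplit(ct$cells$key[i], ",", fixed = TRUE)[[1L]])
    if (length(codes) != k) stop("all keys must have the same tuple length")
    nn <- ct$cells$case_count[i] + ct$cells$control_count[i]
    if (nn == 0L) next
    rows[[length(rows) + 1L]] <-
      matrix(rep(codes, each = nn), nrow = nn)
    labs <- c(labs, rep(c(1L, 0L),
                        c(ct$cells$case_count[i], ct$cells$control_count[i])))
  }
  if (length(rows) == 0L) stop("all cells are empty")
  g <- do.call(rbind, rows)
  if (n_pad_snps > 0L) {
    if (is.null(seed)) stop("seed is required when padding SNPs are requested")
    pad <- withr::with_seed(as.integer(seed), {
      matrix(sample(0:2, nrow(g) * n_pad_snps, replace = TRUE),
             nrow = nrow(g))
    })
    g <- cbind(g, pad)
  }
  genotype_dataset(g, labs)
}
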
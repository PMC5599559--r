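# Stage-two verification: modified G-test with sparse-genotype exclusion,
# Hardy-Weinberg expected counts and Bonferroni thresholding.

#' Expected counts under Hardy-Weinberg and cross-locus independence
#'
#' For each SNP of the combination the minor-allele frequency is estimated
#' from the pooled sample, q = (n_het + 2 n_hommin) / (2n); per-locus genotype
#' probabilities under HWE are (1-q)^2, 2q(1-q), q^2, and the joint
#' genotype-combination probability is their product across loci (linkage
#' equilibrium). The expected count in phenotype column j is that probability
#' times the phenotype total n_j, row-aligned to the observed table.
#'
#' Expected mass sitting on genotype combinations absent from the data is not
#' redistributed, so column sums only reach n_j when every combination is
#' observed. A monomorphic SNP (q = 0 or 1) concentrates the expected mass on
#' one genotype; it is flagged via attribute `monomorphic`, not an error.
#'
#' @param dataset A [case_control_dataset()].
#' @param combo A [snp_combination()].
#' @param observed Optional pre-computed `genotype_contingency` for the same
#'   combination (saves a counting pass).
#' @return I x 2 numeric matrix of expected counts aligned to
#'   `observed$genotype_keys`, with attribute `monomorphic` (logical per
#'   locus).
#' @export
hwe_expected_counts <- function(dataset, combo, observed = NULL) {
  combo <- snp_combination(combo, dataset$n_snps)
  if (is.null(observed)) observed <- count_genotype_contingency(dataset, combo)
  n <- dataset$n
  probs <- matrix(0, 3L, length(combo))
  mono <- logical(length(combo))
  for (l in seq_along(combo)) {
    g <- dataset$genotypes[, combo[l]]
    q <- (sum(g == 1L) + 2 * sum(g == 2L)) / (2 * n)
    probs[, l] <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    mono[l] <- q == 0 || q == 1
  }
  keys <- observed$genotype_keys
  pi_hwe <- rep(1, nrow(keys))
  for (l in seq_len(ncol(keys)))
    pi_hwe <- pi_hwe * probs[keys[, l] + 1L, l]
  expected <- outer(pi_hwe, observed$col_totals)
  colnames(expected) <- colnames(observed$counts)
  attr(expected, "monomorphic") <- mono
  expected
}

#' Expected counts under phenotype independence
#'
#' The classical contingency-table null: E_ij = n_i n_j / n, conditioning on
#' the observed genotype row totals. Unlike [hwe_expected_counts()] this
#' tests phenotype independence alone (not joint HWE fit), and the resulting
#' G statistic is calibrated against chi-square with (I-1)(J-1) degrees of
#' freedom; see the methods vignette for why the HWE variant is not.
#'
#' @param observed A `genotype_contingency`.
#' @return I x 2 numeric matrix of expected counts.
#' @export
independence_expected_counts <- function(observed) {
  expected <- outer(observed$row_totals, observed$col_totals) / observed$n
  colnames(expected) <- colnames(observed$counts)
  expected
}

#' Modified G statistic with sparse-genotype exclusion
#'
#' Computes \eqn{G = 2 \sum_i \sum_j O_{ij} \ln(O_{ij}/E_{ij})} (terms with
#' \eqn{O_{ij} = 0} contribute 0) over genotype rows that pass the sparsity
#' rule, and the correspondingly reduced degrees of freedom
#' \eqn{(I_{kept} - 1)(J - 1)}.
#'
#' Sparsity rule: a genotype row is excluded when its smallest observed count
#' across the phenotype columns is below `xi` (default 5). A kept row with
#' some \eqn{E_{ij} = 0} but \eqn{O_{ij} > 0} would diverge; such rows are
#' excluded with a warning and listed alongside the sparse ones.
#'
#' @param observed A `genotype_contingency`.
#' @param expected Numeric matrix of the same shape, row-aligned (e.g. from
#'   [hwe_expected_counts()]).
#' @param xi Non-negative sparsity threshold; `xi = 0` keeps every row
#'   (conventional G-test).
#' @return An object of class `g_test_result`: `g`, `df`,
#'   `excluded_genotypes` (labels like `"0-2"`), `kept` (logical per row),
#'   `untestable` (`TRUE` when df < 1; no p-value is meaningful then).
#'   `p_value` is `NA` until filled by [g_test_pvalue()] or [g_test()].
#' @export
g_statistic <- function(observed, expected, xi = 5L) {
  O <- observed$counts
  E <- as.matrix(expected)
  if (!all(dim(E) == dim(O)))
    stop("observed and expected tables must share dimensions")
  if (xi < 0) stop("xi must be non-negative")
  keep <- pmin(O[, 1L], O[, 2L]) >= xi
  div <- keep & apply(E == 0 & O > 0, 1L, any)
  if (any(div)) {
    warning("g_statistic: ", sum(div),
            " genotype row(s) with zero expected but positive observed ",
            "count excluded (infinite divergence)")
    keep <- keep & !div
  }
  Ok <- O[keep, , drop = FALSE]
  Ek <- E[keep, , drop = FALSE]
  terms <- ifelse(Ok > 0, Ok * log(Ok / Ek), 0)
  g <- 2 * sum(terms)
  df <- (sum(keep) - 1L) * (ncol(O) - 1L)
  labels <- .key_labels(observed$genotype_keys)
  structure(
    list(g = g, df = df, p_value = NA_real_,
         excluded_genotypes = labels[!keep], kept = keep,
         untestable = df < 1L, threshold = NA_real_),
    class = "g_test_result")
}

#' Chi-square tail probability of a G statistic
#'
#' @param g Non-negative G statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail chi-square probability.
#' @export
g_test_pvalue <- function(g, df) {
  if (any(df < 1L)) stop("df < 1: the table is untestable, not a p-value")
  if (any(g < 0)) stop("g must be non-negative")
  stats::pchisq(g, df, lower.tail = FALSE)
}

#' One-call modified G-test of a SNP combination
#'
#' Counts the contingency table, builds expected counts (`"hwe"` by default,
#' matching the published method; `"independence"` for the calibrated
#' conditional test), computes the sparse-adjusted G statistic and fills in
#' the p-value when testable.
#'
#' @inheritParams hwe_expected_counts
#' @param xi Sparsity threshold passed to [g_statistic()].
#' @param expected_mode `"hwe"` or `"independence"`.
#' @return A `g_test_result` with `p_value` set (NA if untestable).
#' @export
g_test <- function(dataset, combo, xi = 5L,
                   expected_mode = c("hwe", "independence")) {
  expected_mode <- match.arg(expected_mode)
  observed <- count_genotype_contingency(dataset, combo)
  expected <- if (expected_mode == "hwe")
    hwe_expected_counts(dataset, combo, observed)
  else independence_expected_counts(observed)
  res <- g_statistic(observed, expected, xi = xi)
  # With HWE expecteds and row exclusion the kept observed and expected
  # totals need not match, so G can dip below zero (fit better than
  # expected); the tail probability is then taken at 0, i.e. p = 1.
  if (!res$untestable) res$p_value <- g_test_pvalue(max(res$g, 0), res$df)
  res
}

#' @export
print.g_test_result <- function(x, ...) {
  cat("modified G-test: G =", format(x$g, digits = 6), ", df =", x$df)
  if (x$untestable) cat("  [untestable]")
  else if (!is.na(x$p_value)) cat(", p =", format(x$p_value, digits = 4))
  cat("\n")
  if (length(x$excluded_genotypes))
    cat("excluded genotype rows:",
        paste(x$excluded_genotypes, collapse = ", "), "\n")
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of hypotheses (e.g. [combination_count()] of the
#'   panel).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}
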
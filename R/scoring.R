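# Stage-one evaluation functions: Bayesian K2 score, Gini impurity and joint
# genotype entropy, all computed from one shared contingency pass.
#
# Direction convention (fixed package-wide): all three scores are minimized.
# The K2 marginal likelihood is a product of factorial ratios that underflows
# for realistic sample sizes, so it is represented as the negative natural log
# of that product; a lower value means a larger marginal likelihood, matching
# the lower-is-stronger direction of Gini and entropy.

# Internal score kernels operating on a bare I x 2 count matrix.
.k2_from_counts <- function(counts) {
  ni <- rowSums(counts)
  # -ln prod_i [ (J-1)! / (n_i+J-1)! * prod_j n_ij! ], J = 2
  sum(lgamma(ni + 2)) - nrow(counts) * lgamma(2) - sum(lgamma(counts + 1))
}

.gini_from_counts <- function(counts) {
  ni <- rowSums(counts)
  keep <- ni > 0
  if (!any(keep)) return(0)
  n <- sum(ni)
  ci <- counts[keep, , drop = FALSE]
  nik <- ni[keep]
  sum((nik / n) * (1 - rowSums((ci / nik)^2)))
}

.entropy_from_counts <- function(counts) {
  ni <- rowSums(counts)
  p <- ni[ni > 0] / sum(ni)
  -sum(p * log2(p))
}

#' Bayesian K2 score of a contingency table
#'
#' Negative natural log of the K2 marginal likelihood
#' \eqn{\prod_i (J-1)!/(n_i+J-1)! \prod_j n_{ij}!}, evaluated in the
#' log-gamma domain so it is finite for any counts. Lower values indicate a
#' stronger genotype-phenotype association.
#'
#' @param table A `genotype_contingency` (see [count_genotype_contingency()]).
#' @return A single non-negative number.
#' @export
k2_score <- function(table) .k2_from_counts(table$counts)

#' Gini impurity score of a contingency table
#'
#' \eqn{\sum_i (n_i/n) (1 - \sum_j (n_{ij}/n_i)^2)}: the expected phenotype
#' impurity across genotype combinations. 0 means every observed genotype
#' combination maps to a single phenotype; the maximum for two phenotypes is
#' 0.5. Rows with \eqn{n_i = 0} contribute nothing.
#'
#' @inheritParams k2_score
#' @return A number in \[0, 0.5\] for two phenotype states.
#' @export
gini_score <- function(table) .gini_from_counts(table$counts)

#' Joint genotype entropy of a SNP combination
#'
#' Base-2 entropy of the genotype-combination marginal \eqn{P_i = n_i/n};
#' the phenotype column is ignored entirely (\eqn{0 \log 0 \equiv 0}). Used
#' as a phenotype-blind heuristic: combinations overlapping a concentrated
#' (low-divergence) causal genotype distribution tend to score lower.
#'
#' @inheritParams k2_score
#' @return A number in \[0, k log2(3)\] bits.
#' @export
joint_entropy <- function(table) .entropy_from_counts(table$counts)

#' Create an evaluation counter
#'
#' A mutable counter of score evaluations; every [score_combination()] call
#' increments it by exactly one. The count is the basis of the MEs metric
#' (mean number of combination evaluations before the true model is found).
#'
#' @return An environment with integer field `n`.
#' @export
new_eval_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e
}

#' Score a SNP combination under all three objectives at once
#'
#' Performs a single contingency pass and derives the K2, Gini and
#' joint-entropy scores from it — the three objectives share one count, so
#' one call costs one evaluation regardless of how many harmony memories
#' consume the result.
#'
#' @param dataset A [case_control_dataset()].
#' @param combo A [snp_combination()].
#' @param counter Optional [new_eval_counter()]; incremented by 1.
#' @return A list of class `score_triple` with fields `k2`, `gini`,
#'   `entropy` (all minimized).
#' @export
score_combination <- function(dataset, combo, counter = NULL) {
  counts <- .contingency_counts(dataset$genotypes, dataset$phenotype, combo)
  if (!is.null(counter)) counter$n <- counter$n + 1L
  structure(list(k2 = .k2_from_counts(counts),
                 gini = .gini_from_counts(counts),
                 entropy = .entropy_from_counts(counts)),
            class = "score_triple")
}

#' Test whether a combination is synergistically associated with phenotype
#'
#' A k-way combination is synergistic when its score is strictly stronger
#' (lower) than the score of every nonempty proper subset of its loci; ties
#' fail the strict comparison. All 2^k - 2 subsets are enumerated, so k is
#' capped (default 6).
#'
#' Single-locus subsets are scored on the same dataset with the combination
#' reduced to that locus, so the comparison is between nested association
#' models of the same individuals.
#'
#' @param dataset A [case_control_dataset()].
#' @param combo A [snp_combination()] with k >= 2.
#' @param score Which objective to compare under: `"k2"` or `"gini"`.
#' @param max_k Refuse combinations larger than this (subset blow-up guard).
#' @return `TRUE` or `FALSE`.
#' @export
is_synergistic <- function(dataset, combo, score = c("k2", "gini"),
                           max_k = 6L) {
  score <- match.arg(score)
  combo <- snp_combination(combo, dataset$n_snps)
  k <- length(combo)
  if (k > max_k)
    stop("is_synergistic: k = ", k, " exceeds the subset-enumeration cap (",
         max_k, ")")
  kern <- if (score == "k2") .k2_from_counts else .gini_from_counts
  full <- kern(.contingency_counts(dataset$genotypes, dataset$phenotype,
                                   combo))
  for (m in seq_len(k - 1L)) {
    subs <- utils::combn(combo, m)
    for (j in seq_len(ncol(subs))) {
      s <- kern(.contingency_counts(dataset$genotypes, dataset$phenotype,
                                    subs[, j]))
      if (!(full < s)) return(FALSE)
    }
  }
  TRUE
}
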
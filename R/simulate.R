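# Penetrance-table epistasis simulator: marginal-effect (multiplicative and
# threshold) two-locus families solved to a target heritability, a
# constrained stochastic search for no-marginal-effect (k = 3..5) models, and
# replicate case/control dataset generation with truth files.

.hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# All 3^k genotype combinations (rows) with their product-HWE probabilities.
.genotype_grid <- function(mafs) {
  k <- length(mafs)
  G <- as.matrix(expand.grid(rep(list(0:2), k)))[, k:1, drop = FALSE]
  dimnames(G) <- NULL
  p <- rep(1, nrow(G))
  for (l in seq_len(k)) p <- p * .hwe_probs(mafs[l])[G[, l] + 1L]
  list(G = G, p = p)
}

#' Construct a penetrance model
#'
#' @param mafs Minor-allele frequency per causal locus, each in (0, 0.5].
#' @param table Numeric vector of 3^k penetrances in \[0, 1\], ordered with
#'   the first locus as the most significant base-3 digit (genotype (0,0),
#'   (0,1), (0,2), (1,0), ...).
#' @param model_class One of `"multiplicative"`, `"threshold"`,
#'   `"dnme_searched"`, `"custom"`.
#' @return A list of class `penetrance_model` with `k`, `mafs`, `table`,
#'   `prevalence` (K), `h2` and `model_class`.
#' @export
penetrance_model <- function(mafs, table, model_class = "custom") {
  mafs <- as.numeric(mafs)
  if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must be in (0, 0.5]")
  k <- length(mafs)
  table <- as.numeric(table)
  if (length(table) != 3^k)
    stop("penetrance table must have 3^k = ", 3^k, " entries")
  if (any(table < 0 | table > 1)) stop("penetrances must be in [0, 1]")
  gr <- .genotype_grid(mafs)
  K <- sum(gr$p * table)
  if (K <= 0 || K >= 1)
    stop("prevalence K = ", K, " is degenerate; heritability undefined")
  h2 <- sum(gr$p * (table - K)^2) / (K * (1 - K))
  structure(list(k = k, mafs = mafs, table = table, prevalence = K,
                 h2 = h2, model_class = model_class),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("penetrance_model (", x$model_class, "): k =", x$k,
      ", MAF =", paste(format(x$mafs, digits = 3), collapse = "/"),
      ", K =", format(x$prevalence, digits = 4),
      ", h2 =", format(x$h2, digits = 4), "\n")
  invisible(x)
}

#' Broad-sense heritability of a penetrance model
#'
#' \eqn{h^2 = \sum_g p_g (f_g - K)^2 / (K(1-K))} with \eqn{p_g} the
#' product-HWE genotype probabilities and \eqn{K = \sum_g p_g f_g} the
#' population prevalence — the standard penetrance-variance heritability used
#' by table-based epistasis generators.
#'
#' @param model A [penetrance_model()].
#' @return A non-negative number.
#' @export
heritability <- function(model) {
  gr <- .genotype_grid(model$mafs)
  K <- sum(gr$p * model$table)
  if (K <= 0 || K >= 1) stop("prevalence is degenerate; h2 undefined")
  sum(gr$p * (model$table - K)^2) / (K * (1 - K))
}

#' Marginal penetrance of one causal locus
#'
#' Conditional disease probability for each single-locus genotype,
#' marginalized over the other loci under their HWE weights. A model has no
#' marginal effect at a locus when all three values equal the prevalence K.
#'
#' @param model A [penetrance_model()].
#' @param locus Locus index in 1..k.
#' @return Numeric vector of length 3 (genotypes 0, 1, 2).
#' @export
marginal_penetrance <- function(model, locus) {
  if (locus < 1L || locus > model$k) stop("locus out of range")
  gr <- .genotype_grid(model$mafs)
  vapply(0:2, function(a) {
    w <- gr$p * (gr$G[, locus] == a)
    sum(w * model$table) / sum(w)
  }, 0)
}

# Largest marginal deviation from prevalence across loci and genotypes.
.max_marginal_dev <- function(model) {
  max(vapply(seq_len(model$k), function(l)
    max(abs(marginal_penetrance(model, l) - model$prevalence)), 0))
}

#' Build a two-locus marginal-effect disease model at a target heritability
#'
#' Penetrance families over the number of disease (minor) alleles
#' \eqn{g_1 + g_2}:
#' \describe{
#'   \item{multiplicative}{\eqn{f = b (1+\theta)^{g_1+g_2}} — risk grows
#'     multiplicatively with each disease allele.}
#'   \item{threshold}{\eqn{f = b} until \eqn{g_1 + g_2 \ge 2}, then
#'     \eqn{b(1+\theta)} — no risk increase before the allele count passes
#'     the threshold.}
#' }
#' The effect size \eqn{\theta} is solved numerically so the model's
#' heritability hits `h2_target` within 1e-6.
#'
#' @param model_class `"multiplicative"` or `"threshold"`.
#' @param maf Shared minor-allele frequency of the two loci.
#' @param h2_target Target heritability, in (0, 0.2].
#' @param baseline Baseline penetrance b.
#' @return A [penetrance_model()].
#' @export
build_dme_model <- function(model_class = c("multiplicative", "threshold"),
                            maf, h2_target, baseline = 0.1) {
  model_class <- match.arg(model_class)
  if (h2_target <= 0 || h2_target > 0.2)
    stop("h2_target must be in (0, 0.2]")
  gr <- .genotype_grid(c(maf, maf))
  alleles <- rowSums(gr$G)
  f_of <- function(theta) {
    if (model_class == "multiplicative") baseline * (1 + theta)^alleles
    else baseline * ifelse(alleles >= 2, 1 + theta, 1)
  }
  theta_max <- if (model_class == "multiplicative")
    (1 / baseline)^(1 / 4) - 1 else 1 / baseline - 1
  h2_of <- function(theta) {
    f <- f_of(theta)
    K <- sum(gr$p * f)
    sum(gr$p * (f - K)^2) / (K * (1 - K))
  }
  h2_hi <- h2_of(theta_max)
  if (h2_hi < h2_target)
    stop("h2_target = ", h2_target, " unreachable for the ", model_class,
         " family at maf = ", maf, ", baseline = ", baseline,
         "; attainable range is (0, ", format(h2_hi, digits = 4), "]")
  theta <- stats::uniroot(function(t) h2_of(t) - h2_target,
                          c(0, theta_max), tol = 1e-12)$root
  m <- penetrance_model(c(maf, maf), f_of(theta), model_class)
  if (abs(m$h2 - h2_target) > 1e-6)
    stop("failed to hit h2_target: got ", m$h2)
  m
}

#' Search for a no-marginal-effect (DNME) penetrance model
#'
#' Stochastic construction of a k-locus penetrance table with a strong joint
#' effect (heritability near `h2_target`) and per-locus marginal penetrances
#' flat at the prevalence. A random perturbation is projected onto the
#' linear subspace where every single-locus HWE-weighted marginal equals the
#' prevalence, rescaled to the target heritability, clipped to \[0, 1\], and
#' polished by alternating projections; candidate tables are retried until
#' both acceptance checks pass:
#' `max_g |marginal - K| < marginal_tol` at every locus and
#' `|h2 - h2_target| < 0.1 h2_target`.
#'
#' Different seeds give different tables; non-uniqueness is expected.
#'
#' @param k Number of causal loci (3..5 typical; k = 2 allowed).
#' @param maf Shared minor-allele frequency of the causal loci.
#' @param h2_target Target heritability.
#' @param prevalence Population prevalence K the table is centered on.
#' @param marginal_tol Acceptance tolerance on the marginal deviation
#'   (penetrance units).
#' @param max_restarts Random restarts before giving up.
#' @return A [penetrance_model()] with `model_class = "dnme_searched"`.
#' @export
search_dnme_model <- function(k = 3L, maf = 0.25, h2_target = 0.1,
                              prevalence = 0.1, marginal_tol = 0.005,
                              max_restarts = 200L) {
  if (marginal_tol <= 0) stop("marginal_tol must be positive")
  mafs <- rep(maf, k)
  gr <- .genotype_grid(mafs)
  pg <- gr$p
  K <- prevalence
  # Constraint matrix: one row per (locus, genotype); A d = 0 keeps every
  # single-locus marginal (and the prevalence) at K.
  A <- do.call(rbind, lapply(seq_len(k), function(l)
    t(vapply(0:2, function(a) pg * (gr$G[, l] == a), pg))))
  AA <- A %*% t(A) + diag(1e-12, nrow(A))
  project <- function(z) as.vector(z - t(A) %*% solve(AA, A %*% z))
  target_var <- h2_target * K * (1 - K)
  best <- NULL
  best_res <- Inf
  for (r in seq_len(max_restarts)) {
    d <- project(stats::rnorm(length(pg)))
    for (it in 1:50) {                       # alternating projection + clip
      s <- sum(pg * d^2)
      if (s <= 0) break
      d <- d * sqrt(target_var / s)
      f <- pmin(pmax(K + d, 0), 1)
      d2 <- project(f - K)
      if (max(abs(d2 - d)) < 1e-10) { d <- d2; break }
      d <- d2
    }
    f <- pmin(pmax(K + d, 0), 1)
    m <- tryCatch(penetrance_model(mafs, f, "dnme_searched"),
                  error = function(e) NULL)
    if (is.null(m)) next
    dev <- .max_marginal_dev(m)
    res <- max(dev / marginal_tol, abs(m$h2 - h2_target) / (0.1 * h2_target))
    if (res < 1) return(m)
    if (res < best_res) { best_res <- res; best <- m }
  }
  if (is.null(best))
    stop("search_dnme_model: every proposed table had degenerate prevalence")
  stop("search_dnme_model: no table met the acceptance checks in ",
       max_restarts, " restarts; best residuals: marginal dev = ",
       format(.max_marginal_dev(best), digits = 3), ", h2 = ",
       format(best$h2, digits = 4), " (target ", h2_target, ")")
}

#' Generate a replicate case/control dataset from a penetrance model
#'
#' Causal genotype combinations are drawn under HWE and disease status is
#' assigned by rejection sampling against the penetrance table until the
#' case and control quotas are filled (the fixed-quota retrospective design).
#' Background SNPs are drawn independently under HWE with MAFs uniform in
#' `background_maf_range`, independent of phenotype. The causal columns are
#' embedded at random positions in the panel.
#'
#' @param model A [penetrance_model()].
#' @param n_cases,n_controls Sample quotas.
#' @param n_background_snps Background (non-causal) SNP count.
#' @param background_maf_range MAF range of the background SNPs.
#' @param snp_prefix Prefix for generated SNP names.
#' @return List with `dataset` (a [case_control_dataset()]) and `truth`
#'   (class `sim_truth`: `causal_snp_names`, `causal_column_indices`,
#'   `model`).
#' @export
generate_dataset <- function(model, n_cases, n_controls,
                             n_background_snps = 98L,
                             background_maf_range = c(0.05, 0.5),
                             snp_prefix = "SNP") {
  if (n_cases < 1L || n_controls < 1L) stop("sample quotas must be positive")
  gr <- .genotype_grid(model$mafs)
  K <- model$prevalence
  if (K < 1e-4 || K > 1 - 1e-4)
    stop("prevalence ", K, " makes quota sampling pathologically slow")
  draw_group <- function(n_target, as_case) {
    acc_p <- if (as_case) model$table else 1 - model$table
    out <- matrix(0L, 0L, model$k)
    guard <- 0L
    while (nrow(out) < n_target) {
      guard <- guard + 1L
      if (guard > 1000L)
        stop("rejection sampling failed to fill the ",
             if (as_case) "case" else "control", " quota")
      m <- ceiling(1.3 * (n_target - nrow(out)) /
                     max(if (as_case) K else 1 - K, 1e-4))
      gi <- sample.int(nrow(gr$G), m, replace = TRUE, prob = gr$p)
      keep <- stats::runif(m) < acc_p[gi]
      out <- rbind(out, gr$G[gi[keep], , drop = FALSE])
    }
    out[seq_len(n_target), , drop = FALSE]
  }
  causal <- rbind(draw_group(n_controls, FALSE), draw_group(n_cases, TRUE))
  phenotype <- rep(c(0L, 1L), c(n_controls, n_cases))
  n <- n_cases + n_controls
  n_snps <- model$k + n_background_snps
  genotypes <- matrix(0L, n, n_snps)
  causal_cols <- sort(sample.int(n_snps, model$k))
  genotypes[, causal_cols] <- causal
  if (n_background_snps > 0L) {
    bg_cols <- setdiff(seq_len(n_snps), causal_cols)
    mafs <- stats::runif(n_background_snps, background_maf_range[1L],
                         background_maf_range[2L])
    for (j in seq_len(n_background_snps))
      genotypes[, bg_cols[j]] <- sample(0:2, n, replace = TRUE,
                                        prob = .hwe_probs(mafs[j]))
  }
  snp_names <- paste0(snp_prefix, seq_len(n_snps))
  dataset <- case_control_dataset(genotypes, phenotype, snp_names)
  truth <- structure(
    list(causal_snp_names = snp_names[causal_cols],
         causal_column_indices = causal_cols, model = model),
    class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Write / read a simulation truth file (JSON)
#'
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @return `path` (write) or the reconstructed `sim_truth` (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(causal_snp_names = truth$causal_snp_names,
         causal_column_indices = truth$causal_column_indices,
         model = list(k = truth$model$k, mafs = truth$model$mafs,
                      table = truth$model$table,
                      model_class = truth$model$model_class)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(causal_snp_names = x$causal_snp_names,
         causal_column_indices = as.integer(x$causal_column_indices),
         model = penetrance_model(x$model$mafs, x$model$table,
                                  x$model$model_class)),
    class = "sim_truth")
}
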
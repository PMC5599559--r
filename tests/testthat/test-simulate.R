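test_that("heritability matches brute-force enumeration and its symmetries", {
  flat <- penetrance_model(c(0.3, 0.4), rep(0.07, 9L), "custom")
  expect_equal(heritability(flat), 0)

  # single-locus recessive-style table, enumerated by hand over 3 genotypes
  m1 <- penetrance_model(0.5, c(0, 0, 1), "custom")
  p <- c(0.25, 0.5, 0.25)
  K <- sum(p * c(0, 0, 1))
  expect_equal(m1$prevalence, K)
  expect_equal(heritability(m1), sum(p * (c(0, 0, 1) - K)^2) / (K * (1 - K)))

  # at maf = 0.5 relabeling which allele is minor (mirroring every genotype
  # g -> 2 - g) leaves the genotype distribution unchanged, so prevalence
  # and heritability are invariant under the mirrored table
  set.seed(201)
  f <- runif(9)
  grid <- as.matrix(expand.grid(0:2, 0:2))[, 2:1]
  code <- function(G) G[, 1L] * 3L + G[, 2L] + 1L
  f_mirror <- f[order(code(2L - grid))]
  ma <- penetrance_model(c(0.5, 0.5), f, "custom")
  mb <- penetrance_model(c(0.5, 0.5), f_mirror, "custom")
  expect_equal(mb$prevalence, ma$prevalence, tolerance = 1e-12)
  expect_equal(heritability(mb), heritability(ma), tolerance = 1e-12)
})

test_that("marginal penetrance: identity at k = 1, variation for additive", {
  m1 <- penetrance_model(0.3, c(0.1, 0.2, 0.3), "custom")
  expect_equal(marginal_penetrance(m1, 1L), c(0.1, 0.2, 0.3))

  add <- penetrance_model(c(0.25, 0.25),
                          0.05 + 0.08 * rowSums(as.matrix(
                            expand.grid(0:2, 0:2))), "custom")
  marg <- marginal_penetrance(add, 1L)
  expect_gt(max(marg) - min(marg), 0.05)
})

test_that("build_dme_model hits the target heritability for both families", {
  for (cls in c("multiplicative", "threshold")) {
    m <- build_dme_model(cls, maf = 0.2, h2_target = 0.02)
    expect_equal(heritability(m), 0.02, tolerance = 1e-6)
    expect_equal(m$model_class, cls)
    expect_true(all(m$table >= 0 & m$table <= 1))
  }
  m2 <- build_dme_model("multiplicative", maf = 0.5, h2_target = 0.005)
  expect_equal(heritability(m2), 0.005, tolerance = 1e-6)
  expect_error(build_dme_model("multiplicative", maf = 0.05,
                               h2_target = 0.2, baseline = 0.5),
               "attainable range")
})

test_that("search_dnme_model satisfies its acceptance checks", {
  set.seed(203)
  m <- search_dnme_model(k = 3L, maf = 0.25, h2_target = 0.1,
                         marginal_tol = 0.005)
  expect_equal(m$model_class, "dnme_searched")
  expect_lt(abs(m$h2 - 0.1), 0.01)
  for (l in 1:3)
    expect_lt(max(abs(marginal_penetrance(m, l) - m$prevalence)), 0.005)

  # k = 2 with a huge tolerance degenerates to any table near target h2
  m2 <- search_dnme_model(k = 2L, maf = 0.3, h2_target = 0.05,
                          marginal_tol = 10)
  expect_lt(abs(m2$h2 - 0.05), 0.005)

  set.seed(205)
  a <- search_dnme_model(k = 3L, maf = 0.25, h2_target = 0.1)
  set.seed(206)
  b <- search_dnme_model(k = 3L, maf = 0.25, h2_target = 0.1)
  expect_false(isTRUE(all.equal(a$table, b$table)))  # non-uniqueness
})

test_that("generate_dataset emits valid, reproducible datasets with truth", {
  set.seed(207)
  m <- build_dme_model("threshold", 0.2, 0.02)
  sim <- generate_dataset(m, 150L, 100L, n_background_snps = 8L)
  ds <- sim$dataset
  expect_s3_class(ds, "case_control_dataset")
  expect_equal(sum(ds$phenotype), 150L)
  expect_equal(ds$n_snps, 10L)
  expect_equal(ds$snp_names[sim$truth$causal_column_indices],
               sim$truth$causal_snp_names)

  set.seed(999)
  s1 <- generate_dataset(m, 50L, 50L, 5L)
  set.seed(999)
  s2 <- generate_dataset(m, 50L, 50L, 5L)
  expect_identical(s1$dataset$genotypes, s2$dataset$genotypes)
  expect_identical(s1$truth$causal_column_indices,
                   s2$truth$causal_column_indices)
})

test_that("empirical penetrance converges to the table at large n", {
  set.seed(209)
  m <- build_dme_model("threshold", 0.25, 0.05)
  sim <- generate_dataset(m, 15000L, 15000L, n_background_snps = 0L)
  tab <- count_genotype_contingency(sim$dataset, c(1L, 2L))
  # within each genotype row, the case fraction estimates
  # f_g / K normalized by the retrospective design:
  # P(case | g, sampled) = (f/K) / (f/K + (1-f)/(1-K)) for equal quotas
  grid <- epiharmony:::.genotype_grid(m$mafs)
  K <- m$prevalence
  for (i in seq_len(nrow(tab$counts))) {
    g <- tab$genotype_keys[i, ]
    f <- m$table[which(grid$G[, 1L] == g[1L] & grid$G[, 2L] == g[2L])]
    expected_frac <- (f / K) / (f / K + (1 - f) / (1 - K))
    ni <- tab$row_totals[i]
    if (ni < 200L) next
    observed <- tab$counts[i, "case"] / ni
    expect_lt(abs(observed - expected_frac),
              4 * sqrt(expected_frac * (1 - expected_frac) / ni) + 0.01)
  }
})

test_that("background SNPs are HWE-distributed and phenotype-independent", {
  set.seed(211)
  m <- build_dme_model("threshold", 0.2, 0.02)
  sim <- generate_dataset(m, 1000L, 1000L, n_background_snps = 198L)
  ds <- sim$dataset
  bg <- setdiff(seq_len(ds$n_snps), sim$truth$causal_column_indices)

  hwe_p <- vapply(bg, function(j) {
    g <- ds$genotypes[, j]
    q <- (sum(g == 1L) + 2L * sum(g == 2L)) / (2L * ds$n)
    expe <- ds$n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(g + 1L, 3L)
    suppressWarnings(chisq.test(obs, p = expe / sum(expe))$p.value)
  }, 0)
  expect_gte(mean(hwe_p > 0.05), 0.9)

  assoc_p <- vapply(bg, function(j) {
    suppressWarnings(
      chisq.test(table(ds$genotypes[, j], ds$phenotype))$p.value)
  }, 0)
  ks <- suppressWarnings(ks.test(assoc_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth files survive a JSON round trip", {
  set.seed(213)
  m <- search_dnme_model(3L, 0.25, 0.1)
  sim <- generate_dataset(m, 30L, 30L, 4L)
  path <- tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_identical(back$causal_column_indices,
                   sim$truth$causal_column_indices)
  expect_equal(back$model$table, sim$truth$model$table)
  expect_equal(back$model$h2, sim$truth$model$h2)
})
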
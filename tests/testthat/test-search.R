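test_that("initialize_memories fills three memories with shared scored draws", {
  set.seed(101)
  ds <- random_dataset(n = 60L, n_snps = 20L)
  counter <- new_eval_counter()
  init <- initialize_memories(ds, k = 3L, hms = 15L, counter = counter)
  expect_identical(counter$n, 15L)  # one evaluation per combination, not 3
  for (mem in init$memories) {
    expect_equal(nrow(mem$harmonies), 15L)
    expect_false(anyDuplicated(mem$ids) > 0L)
    expect_true(all(apply(mem$harmonies, 1L, function(h) all(diff(h) > 0L))))
    expect_equal(mem$worst_index, which.max(mem$scores))
  }
  expect_identical(init$memories$k2$ids, init$memories$entropy$ids)
})

test_that("initialization respects the taboo table and a fixed seed", {
  ds <- random_dataset(n = 40L, n_snps = 12L)
  tb <- add_niche_region(taboo_table(),
                         structure(list(defining_snps = 5L, radius = 0L),
                                   class = "niche_region"))
  set.seed(7)
  init <- initialize_memories(ds, k = 2L, hms = 10L, taboo = tb)
  expect_false(any(init$combos == 5L))

  set.seed(7)
  init2 <- initialize_memories(ds, k = 2L, hms = 10L, taboo = tb)
  expect_identical(init$combos, init2$combos)
})

test_that("improvise_harmony honors the hmcr extremes", {
  set.seed(103)
  ds <- random_dataset(n = 40L, n_snps = 30L)
  init <- initialize_memories(ds, k = 3L, hms = 8L)
  mems <- init$memories
  member_vals <- lapply(1:3, function(pos)
    unique(unlist(lapply(mems, function(m) m$harmonies[, pos]))))

  for (r in 1:50) {
    h <- improvise_harmony(mems, hmcr = 1, par = 0, n_snps = 30L, k = 3L)
    raw <- sort(h)  # sorted output of memory-position draws
    expect_true(all(diff(raw) > 0L))
  }
  # hmcr = 1, par = 0, pre-dedup components must come from memory positions
  for (r in 1:50) {
    h <- improvise_harmony(mems, hmcr = 1, par = 0, n_snps = 30L, k = 3L,
                           detail = TRUE)
    expect_true(all(attr(h, "from_memory")))
  }
  # hmcr = 0: uniform random, never tabooed
  tb <- add_niche_region(taboo_table(),
                         structure(list(defining_snps = 3L, radius = 0L),
                                   class = "niche_region"))
  for (r in 1:50) {
    h <- improvise_harmony(mems, hmcr = 0, par = 0, n_snps = 30L, k = 3L,
                           taboo = tb)
    expect_false(3L %in% h)
  }
})

test_that("memory-consideration rate matches hmcr in aggregate", {
  set.seed(107)
  ds <- random_dataset(n = 30L, n_snps = 500L)
  init <- initialize_memories(ds, k = 3L, hms = 10L)
  hits <- 0L; total <- 0L
  for (r in 1:10000) {
    h <- improvise_harmony(init$memories, hmcr = 0.9, par = 0.35,
                           n_snps = 500L, k = 3L, detail = TRUE)
    fm <- attr(h, "from_memory")
    if (!is.null(fm)) { hits <- hits + sum(fm); total <- total + length(fm) }
  }
  expect_equal(hits / total, 0.9, tolerance = 0.012)
})

test_that("update_memory implements survival of the fittest with dedup", {
  harmonies <- rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  mem <- harmony_memory(harmonies, c(10, 20, 30), "k2")

  worse <- update_memory(mem, c(7L, 8L), 99)
  expect_false(worse$improved)
  expect_identical(worse$memory$stagnation, 1L)
  expect_identical(worse$memory$harmonies, harmonies)

  better <- update_memory(worse$memory, c(7L, 8L), 15)
  expect_true(better$improved)
  expect_identical(better$memory$stagnation, 0L)
  expect_equal(nrow(better$memory$harmonies), 3L)
  expect_true("7,8" %in% better$memory$ids)
  expect_false("5,6" %in% better$memory$ids)

  dup <- update_memory(better$memory, c(1L, 2L), 1e-9)
  expect_false(dup$improved)  # duplicates rejected regardless of score
})

test_that("identify_niche extracts the convergence core or falls back", {
  shared <- harmony_memory(rbind(c(2L, 9L), c(2L, 5L), c(2L, 7L), c(1L, 3L)),
                           c(4, 3, 2, 1), "k2")
  region <- identify_niche(shared)
  expect_true(2L %in% region$defining_snps)
  expect_equal(region$radius, length(region$defining_snps) - 1L)

  disjoint <- harmony_memory(rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
                             c(3, 1, 2), "gini")
  region2 <- identify_niche(disjoint)
  expect_equal(region2$defining_snps, c(3L, 4L))  # best harmony's set
  expect_equal(region2$radius, 1L)
})

test_that("a strong marginal-effect SNP dominates the identified niche", {
  set.seed(109)
  m <- build_dme_model("threshold", 0.3, 0.05)
  hits <- vapply(1:10, function(r) {
    sim <- generate_dataset(m, 400L, 400L, n_background_snps = 18L)
    ds <- sim$dataset
    combos <- t(utils::combn(ds$n_snps, 2L))
    k2s <- apply(combos, 1L, function(cb) score_combination(ds, cb)$k2)
    top <- order(k2s)[1:10]
    mem <- harmony_memory(combos[top, , drop = FALSE], k2s[top], "k2")
    any(sim$truth$causal_column_indices %in%
          identify_niche(mem)$defining_snps)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("is_tabooed applies the overlap-radius arithmetic", {
  tb <- taboo_table()
  expect_false(is_tabooed(c(1L, 2L, 3L), tb))
  tb <- add_niche_region(tb, structure(list(defining_snps = 5L, radius = 0L),
                                       class = "niche_region"))
  expect_true(is_tabooed(c(2L, 5L), tb))
  expect_false(is_tabooed(c(2L, 6L), tb))
  tb <- add_niche_region(tb, structure(list(defining_snps = c(3L, 7L),
                                            radius = 1L),
                                       class = "niche_region"))
  expect_true(is_tabooed(c(3L, 7L, 9L), tb))
  expect_false(is_tabooed(c(3L, 9L, 11L), tb))
})

test_that("harvest_elites merges, dedups, truncates and is idempotent", {
  mem <- harmony_memory(rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
                        c(3, 1, 2), "k2")
  mems <- list(mem, mem, mem)
  elites <- lapply(1:3, function(i) elite_set(3L))
  elites <- harvest_elites(mems, elites, m = 3L)
  expect_identical(elites[[1L]]$ids, c("3,4", "5,6", "1,2"))  # sorted by score

  again <- harvest_elites(mems, elites, m = 3L)
  expect_identical(again[[1L]], elites[[1L]])

  full <- elite_set(2L)
  full <- epiharmony:::.elite_add(full, rbind(c(9L, 10L), c(11L, 12L)),
                                  c(0.1, 0.2))
  worse <- harvest_elites(list(mem), list(full), m = 3L)[[1L]]
  expect_identical(worse$ids, full$ids)  # all memory members worse
})

test_that("tabooed regions are never evaluated after registration and
           restarted memories avoid them", {
  set.seed(113)
  m <- build_dme_model("threshold", 0.3, 0.05)
  sim <- generate_dataset(m, 300L, 300L, n_background_snps = 28L)
  cfg <- epi_config(k = 2L, hms = 10L, t_max = 800L, stagnation_T = 15L,
                    seed = 99L, trace = TRUE)
  sc <- epi_screen(sim$dataset, cfg)
  expect_gt(sc$restarts, 0L)  # the mechanism actually fired

  # replay the trace against the niche registration times
  for (i in seq_along(sc$niche_events)) {
    regions <- sc$niches[seq_len(3L * i)]
    tb <- taboo_table()
    for (r in regions) tb <- add_niche_region(tb, r)
    after <- sc$trace[sc$trace$eval > sc$niche_events[i], ]
    for (id in after$id) {
      combo <- as.integer(strsplit(id, ",")[[1L]])
      expect_false(is_tabooed(combo, tb))
    }
  }
  for (mem in sc$memories) {
    for (r in seq_len(nrow(mem$harmonies)))
      expect_false(is_tabooed(mem$harmonies[r, ], sc$taboo))
  }
})

test_that("the evaluation budget is respected", {
  set.seed(127)
  ds <- random_dataset(n = 100L, n_snps = 25L)
  cfg <- epi_config(k = 2L, hms = 8L, t_max = 300L, stagnation_T = 10L,
                    seed = 3L)
  sc <- epi_screen(ds, cfg)
  expect_lte(sc$evaluations, 300L + 3L * 8L * (sc$restarts + 1L))
})
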
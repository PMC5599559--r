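# Two-stage orchestration: screening loop with niche restarts -> candidate
# set -> modified G-test verification -> ranked report.

#' Configuration for a two-stage detection run
#'
#' Defaults follow the published parameterization: memory and elite sizes of
#' 50 for panels up to 100 SNPs and 100 above; candidate-set cap 10;
#' HMCR = 0.9, PAR = 0.35; evaluation budget T_max = 4500 for 100-SNP panels
#' and 60000 for 1000-SNP panels; sparsity threshold xi = 5; alpha = 0.05
#' with Bonferroni correction over all C(n_snps, k) combinations.
#'
#' @param k Combination order (>= 2).
#' @param hms Harmony memory size; `NULL` resolves per panel size.
#' @param elite_capacity Elite-archive capacity per objective; `NULL` = hms.
#' @param cs_capacity Candidates kept per objective source when merging the
#'   elite archives into the candidate set.
#' @param hmcr Harmony-memory considering rate.
#' @param par Pitch-adjusting rate.
#' @param stagnation_T Iterations without improvement (in all three memories
#'   simultaneously) that trigger niche identification.
#' @param t_max Evaluation budget; `NULL` resolves per panel size.
#' @param xi G-test sparsity threshold.
#' @param alpha Family-wise error rate for stage two.
#' @param n_tests_mode `"all_combinations"` (Bonferroni over C(n_snps, k),
#'   the conservative default), `"candidates"` (over the candidates actually
#'   tested) or `"fixed"` (use `fixed_threshold` directly).
#' @param fixed_threshold Absolute p-value cutoff when
#'   `n_tests_mode = "fixed"`.
#' @param expected_mode G-test expected counts: `"hwe"` (published method) or
#'   `"independence"` (calibrated conditional test).
#' @param seed Integer seed; every random draw of the run flows from it.
#' @param early_stop_truth Optional integer vector of the known causal SNP
#'   columns (benchmark mode): screening stops when that combination is first
#'   evaluated, which is how the MEs metric is defined.
#' @param trace Record an evaluation trace (combination, scores, niche
#'   events) in the result.
#' @return A list of class `epi_config`.
#' @export
epi_config <- function(k = 2L, hms = NULL, elite_capacity = NULL,
                       cs_capacity = 10L, hmcr = 0.9, par = 0.35,
                       stagnation_T = 50L, t_max = NULL, xi = 5L,
                       alpha = 0.05,
                       n_tests_mode = c("all_combinations", "candidates",
                                        "fixed"),
                       fixed_threshold = NULL,
                       expected_mode = c("hwe", "independence"),
                       seed = NULL, early_stop_truth = NULL, trace = FALSE) {
  n_tests_mode <- match.arg(n_tests_mode)
  expected_mode <- match.arg(expected_mode)
  if (hmcr < 0 || hmcr > 1 || par < 0 || par > 1)
    stop("hmcr and par must be in [0, 1]")
  if (k < 2L) stop("k must be >= 2")
  if (cs_capacity < 1L) stop("cs_capacity must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests_mode == "fixed" && is.null(fixed_threshold))
    stop("n_tests_mode = 'fixed' requires fixed_threshold")
  structure(
    list(k = as.integer(k), hms = hms, elite_capacity = elite_capacity,
         cs_capacity = as.integer(cs_capacity), hmcr = hmcr, par = par,
         stagnation_T = as.integer(stagnation_T), t_max = t_max,
         xi = xi, alpha = alpha, n_tests_mode = n_tests_mode,
         fixed_threshold = fixed_threshold, expected_mode = expected_mode,
         seed = seed,
         early_stop_truth = if (is.null(early_stop_truth)) NULL
                            else sort(as.integer(early_stop_truth)),
         trace = isTRUE(trace)),
    class = "epi_config")
}

# Fill size-dependent defaults against a concrete panel.
.resolve_config <- function(config, n_snps) {
  if (is.null(config$hms)) config$hms <- if (n_snps <= 100L) 50L else 100L
  if (is.null(config$elite_capacity)) config$elite_capacity <- config$hms
  if (is.null(config$t_max))
    config$t_max <- if (n_snps <= 100L) 4500L else 60000L
  config$hms <- as.integer(config$hms)
  config$elite_capacity <- as.integer(config$elite_capacity)
  config$t_max <- as.integer(config$t_max)
  if (config$t_max < 3L * config$hms)
    stop("t_max (", config$t_max, ") must be >= 3 * hms (", 3L * config$hms,
         ")")
  config
}

#' Screening stage: niche harmony search over k-way combinations
#'
#' Runs the improvise / score-once / offer-to-three-memories loop. When all
#' three memories have stagnated for `stagnation_T` iterations, a niche
#' region is identified per memory and registered in the taboo table, the
#' elites are harvested, and the memories are reinitialized outside the
#' tabooed regions. The loop stops at the `t_max` evaluation budget, or as
#' soon as `early_stop_truth` is first evaluated (benchmark mode). The elite
#' archives are then merged — top `cs_capacity` per objective, deduplicated —
#' into the candidate set.
#'
#' @param dataset A [case_control_dataset()].
#' @param config An [epi_config()].
#' @return A list of class `epi_screen_result`: `candidates` (list with
#'   `combos` matrix, `ids`, `scores` data.frame of the three objective
#'   values, `snp_names`), `elites`, `taboo`, `niches`, `evaluations`,
#'   `restarts`, `found` / `mes` (benchmark mode), `exhausted`, `trace`
#'   (optional data.frame), `config`.
#' @export
epi_screen <- function(dataset, config = epi_config()) {
  config <- .resolve_config(config, dataset$n_snps)
  if (!is.null(config$seed)) set.seed(config$seed)
  counter <- new_eval_counter()
  cache <- new.env(parent = emptyenv())
  truth_id <- if (is.null(config$early_stop_truth)) NULL
              else .combo_id(config$early_stop_truth)
  state <- new.env(parent = emptyenv())
  state$found <- FALSE
  state$mes <- NA_integer_
  state$trace <- if (config$trace) vector("list", 0L) else NULL
  score1 <- function(combo) {
    tr <- score_combination(dataset, combo, counter)
    assign(.combo_id(combo), tr, envir = cache)
    if (!is.null(truth_id) && !state$found &&
        identical(.combo_id(combo), truth_id)) {
      state$found <- TRUE
      state$mes <- counter$n
    }
    if (config$trace)
      state$trace[[length(state$trace) + 1L]] <-
        list(eval = counter$n, id = .combo_id(combo),
             k2 = tr$k2, gini = tr$gini, entropy = tr$entropy)
    tr
  }

  taboo <- taboo_table()
  elites <- lapply(1:3, function(i) elite_set(config$elite_capacity))
  niches <- list()
  niche_events <- integer(0)
  restarts <- 0L
  exhausted <- FALSE

  init <- initialize_memories(dataset, config$k, config$hms, taboo,
                              score_fn = score1)
  memories <- init$memories

  while (counter$n < config$t_max && !state$found) {
    cand <- improvise_harmony(memories, config$hmcr, config$par,
                              dataset$n_snps, config$k, taboo)
    if (is.null(cand)) { exhausted <- TRUE; break }
    triple <- score1(cand)
    for (i in seq_along(memories)) {
      upd <- update_memory(memories[[i]], cand,
                           triple[[memories[[i]]$objective]])
      memories[[i]] <- upd$memory
    }
    if (state$found) break
    stagnant <- all(vapply(memories, function(m) m$stagnation, 0L) >=
                      config$stagnation_T)
    if (stagnant && counter$n < config$t_max) {
      for (m in memories) {
        region <- identify_niche(m)
        taboo <- add_niche_region(taboo, region)
        niches[[length(niches) + 1L]] <- region
      }
      niche_events <- c(niche_events, counter$n)
      elites <- harvest_elites(memories, elites, config$hms)
      restarts <- restarts + 1L
      init <- tryCatch(
        initialize_memories(dataset, config$k, config$hms, taboo,
                            score_fn = score1),
        error = function(e) e)
      if (inherits(init, "error")) { exhausted <- TRUE; break }
      memories <- init$memories
    }
  }
  elites <- harvest_elites(memories, elites, config$hms)

  # Merge: top cs_capacity per objective source, deduplicated.
  combos <- NULL; ids <- character(0)
  for (es in elites) {
    if (is.null(es$combos)) next
    take <- seq_len(min(config$cs_capacity, nrow(es$combos)))
    new <- !(es$ids[take] %in% ids)
    combos <- rbind(combos, es$combos[take, , drop = FALSE][new, , drop = FALSE])
    ids <- c(ids, es$ids[take][new])
  }
  if (state$found && !(truth_id %in% ids)) {
    combos <- rbind(combos, matrix(config$early_stop_truth, 1L))
    ids <- c(ids, truth_id)
  }
  scores <- do.call(rbind, lapply(ids, function(id) {
    tr <- get(id, envir = cache)
    data.frame(k2 = tr$k2, gini = tr$gini, entropy = tr$entropy)
  }))
  snp_names <- vapply(seq_along(ids), function(i)
    paste(dataset$snp_names[combos[i, ]], collapse = ","), "")
  o <- order(scores$k2)
  candidates <- list(combos = combos[o, , drop = FALSE], ids = ids[o],
                     scores = scores[o, , drop = FALSE],
                     snp_names = snp_names[o])
  trace_df <- NULL
  if (config$trace && length(state$trace))
    trace_df <- do.call(rbind, lapply(state$trace, as.data.frame))
  structure(
    list(candidates = candidates, elites = elites, taboo = taboo,
         niches = niches, niche_events = niche_events,
         evaluations = counter$n, restarts = restarts,
         found = state$found, mes = state$mes, exhausted = exhausted,
         memories = memories, trace = trace_df, config = config),
    class = "epi_screen_result")
}

#' Verification stage: modified G-test over the candidate set
#'
#' Every candidate is tested with [g_test()] components; the significance
#' threshold is resolved from `n_tests_mode`. Untestable candidates (df < 1)
#' are reported with `untestable = TRUE`, never silently dropped.
#'
#' @param dataset A [case_control_dataset()].
#' @param screened An `epi_screen_result` (or a bare candidate list of the
#'   same shape).
#' @param config An [epi_config()].
#' @return A list of class `epi_result` with `candidates`, `tested` (ranked
#'   data.frame: `snp_names`, `k`, `g`, `df`, `p_value`,
#'   `excluded_genotypes`, `untestable`, `significant`, `threshold`),
#'   `significant` (subset), plus screening diagnostics carried through.
#' @export
epi_verify <- function(dataset, screened, config = NULL) {
  if (is.null(config)) config <- screened$config
  config <- .resolve_config(config, dataset$n_snps)
  cand <- if (inherits(screened, "epi_screen_result")) screened$candidates
          else screened
  if (is.null(cand$combos) || nrow(cand$combos) == 0L)
    stop("no candidates to verify")
  n_cand <- nrow(cand$combos)
  threshold <- switch(
    config$n_tests_mode,
    all_combinations = bonferroni_threshold(
      config$alpha, combination_count(dataset$n_snps, config$k)),
    candidates = bonferroni_threshold(config$alpha, n_cand),
    fixed = config$fixed_threshold)
  rows <- vector("list", n_cand)
  for (i in seq_len(n_cand)) {
    combo <- cand$combos[i, ]
    res <- g_test(dataset, combo, xi = config$xi,
                  expected_mode = config$expected_mode)
    rows[[i]] <- data.frame(
      snp_names = paste(dataset$snp_names[combo], collapse = ","),
      k = length(combo), g = res$g, df = res$df, p_value = res$p_value,
      excluded_genotypes = paste(res$excluded_genotypes, collapse = ";"),
      untestable = res$untestable,
      significant = !res$untestable && !is.na(res$p_value) &&
        res$p_value < threshold,
      threshold = threshold, stringsAsFactors = FALSE)
  }
  tested <- do.call(rbind, rows)
  tested$combo_id <- cand$ids
  tested <- tested[order(tested$p_value), ]
  rownames(tested) <- NULL
  structure(
    list(candidates = cand, tested = tested,
         significant = tested[tested$significant, ],
         threshold = threshold,
         evaluations_used = if (!is.null(screened$evaluations))
           screened$evaluations else NA_integer_,
         restarts = screened$restarts, niches = screened$niches,
         found = screened$found, mes = screened$mes,
         config = config),
    class = "epi_result")
}

#' Full two-stage detection run
#'
#' [epi_screen()] followed by [epi_verify()], with wall time and provenance
#' (seed, configuration, package version) attached.
#'
#' @inheritParams epi_screen
#' @return An `epi_result` (see [epi_verify()]) with `wall_time` (seconds)
#'   and `provenance`.
#' @export
epi_run <- function(dataset, config = epi_config()) {
  t0 <- proc.time()[["elapsed"]]
  screened <- epi_screen(dataset, config)
  result <- epi_verify(dataset, screened, screened$config)
  result$wall_time <- proc.time()[["elapsed"]] - t0
  result$trace <- screened$trace
  result$provenance <- list(
    package = "epiharmony",
    version = as.character(utils::packageVersion("epiharmony")),
    seed = config$seed)
  result
}

#' @export
print.epi_result <- function(x, ...) {
  cat("Two-stage detection result\n")
  cat("  evaluations used:", x$evaluations_used,
      " restarts:", x$restarts, "\n")
  cat("  candidates tested:", nrow(x$tested),
      " significant:", nrow(x$significant),
      " (threshold ", format(x$threshold, digits = 4), ")\n", sep = "")
  if (nrow(x$significant))
    print(x$significant[, c("snp_names", "g", "df", "p_value")],
          row.names = FALSE)
  invisible(x)
}

#' Write a run's outputs to a directory
#'
#' Emits `config.json`, `candidates.tsv`, `results.tsv` and, when tracing was
#' enabled, `trace.tsv`. Files contain no timestamps, so identical
#' (dataset, config, seed) runs produce byte-identical output.
#'
#' @param result An `epi_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  cfg$early_stop_truth <- NULL
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cand <- data.frame(snp_names = result$candidates$snp_names,
                     result$candidates$scores)
  utils::write.table(cand, file.path(dir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$tested, file.path(dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$trace))
    utils::write.table(result$trace, file.path(dir, "trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
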
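# Niche harmony-search core: three objective-specific harmony memories,
# harmony improvisation, stagnation-triggered niche identification with a
# taboo table of converged regions, and elite archives.
#
# The improvisation, niche and taboo rules are reconstructions of the standard
# discrete harmony-search operator set (memory consideration at rate HMCR,
# pitch adjustment at rate PAR, random choice otherwise) specialized to sorted
# SNP index sets; the niche is the set of loci the memory has converged on and
# the taboo test is an index-overlap bound, which directly implements the
# stated purpose of banning re-exploration of a converged locus.

.combo_id <- function(combo) paste(combo, collapse = ",")

#' Create a harmony memory
#'
#' @param harmonies HMS x k integer matrix, one sorted combination per row.
#' @param scores Numeric score per harmony under `objective`.
#' @param objective One of `"k2"`, `"gini"`, `"entropy"`.
#' @return A list of class `harmony_memory` with fields `harmonies`, `scores`,
#'   `ids`, `objective`, `worst_index`, `stagnation`.
#' @export
harmony_memory <- function(harmonies, scores, objective) {
  ids <- apply(harmonies, 1L, paste, collapse = ",")
  if (anyDuplicated(ids)) stop("harmony memory must not contain duplicates")
  structure(
    list(harmonies = harmonies, scores = as.numeric(scores), ids = ids,
         objective = objective, worst_index = which.max(scores),
         stagnation = 0L),
    class = "harmony_memory")
}

#' Empty taboo table
#' @return A list of class `taboo_table` holding niche regions.
#' @export
taboo_table <- function() structure(list(regions = list()), class = "taboo_table")

#' Register a niche region in a taboo table
#' @param taboo A [taboo_table()].
#' @param region A niche region from [identify_niche()].
#' @return The updated taboo table (identical regions are not duplicated).
#' @export
add_niche_region <- function(taboo, region) {
  key <- paste(region$defining_snps, collapse = ",")
  keys <- vapply(taboo$regions,
                 function(r) paste(r$defining_snps, collapse = ","), "")
  if (!(key %in% keys)) taboo$regions[[length(taboo$regions) + 1L]] <- region
  taboo
}

#' Taboo membership test
#'
#' A combination is tabooed when it overlaps some recorded niche region in
#' strictly more than `radius` SNP indices. The test is pure: identical
#' inputs always give identical answers.
#'
#' @param combo Sorted integer SNP indices.
#' @param taboo A [taboo_table()].
#' @return `TRUE` or `FALSE`.
#' @export
is_tabooed <- function(combo, taboo) {
  for (r in taboo$regions) {
    if (sum(combo %in% r$defining_snps) > r$radius) return(TRUE)
  }
  FALSE
}

# Uniform random non-tabooed sorted combination, or NULL after max_tries.
.random_combo <- function(n_snps, k, taboo, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    cand <- sort(sample.int(n_snps, k))
    if (!is_tabooed(cand, taboo)) return(cand)
  }
  NULL
}

#' Initialize the three harmony memories
#'
#' Draws `hms` distinct random non-tabooed k-way combinations, scores each
#' once (a single contingency pass yields all three objective values), and
#' fills the K2, Gini and entropy memories with the same combinations under
#' their respective scores — `hms` evaluations total, not `3 hms`.
#'
#' @param dataset A [case_control_dataset()].
#' @param k Combination order.
#' @param hms Harmony memory size (>= 2).
#' @param taboo A [taboo_table()]; tabooed combinations are never drawn.
#' @param counter Optional evaluation counter.
#' @param score_fn Scoring hook `(combo) -> score_triple`; defaults to
#'   [score_combination()] on `dataset`. The pipeline injects an instrumented
#'   version.
#' @return List with `memories` (list of three `harmony_memory`: k2, gini,
#'   entropy), `combos` (the hms x k matrix) and `triples` (list of
#'   `score_triple`).
#' @export
initialize_memories <- function(dataset, k, hms, taboo = taboo_table(),
                                counter = NULL, score_fn = NULL) {
  if (hms < 2L) stop("hms must be >= 2")
  if (is.null(score_fn))
    score_fn <- function(combo) score_combination(dataset, combo, counter)
  combos <- matrix(0L, hms, k)
  ids <- character(hms)
  filled <- 0L
  tries <- 0L
  while (filled < hms) {
    tries <- tries + 1L
    if (tries > 1000L * hms)
      stop("search exhaustion: cannot draw ", hms,
           " distinct non-tabooed combinations")
    cand <- .random_combo(dataset$n_snps, k, taboo)
    if (is.null(cand))
      stop("search exhaustion: taboo table covers the whole space")
    id <- .combo_id(cand)
    if (id %in% ids[seq_len(filled)]) next
    filled <- filled + 1L
    combos[filled, ] <- cand
    ids[filled] <- id
  }
  triples <- vector("list", hms)
  for (i in seq_len(hms)) triples[[i]] <- score_fn(combos[i, ])
  memories <- lapply(c("k2", "gini", "entropy"), function(obj) {
    harmony_memory(combos, vapply(triples, `[[`, 0, obj), obj)
  })
  names(memories) <- c("k2", "gini", "entropy")
  list(memories = memories, combos = combos, triples = triples)
}

#' Improvise a new harmony
#'
#' For each of the k positions independently: with probability `hmcr` the
#' value is taken from that position of a uniformly random harmony in a
#' uniformly chosen memory (memory consideration), then with probability
#' `par` the drawn index is shifted by +/-1 (pitch adjustment, reflecting at
#' the panel boundary); with probability `1 - hmcr` the index is drawn
#' uniformly from the panel. Duplicate indices are redrawn uniformly, the
#' result is sorted, and tabooed candidates are rejected and regenerated
#' (bounded retries, then a pure random non-tabooed draw).
#'
#' Pitch adjustment on column indices carries no biological meaning (adjacent
#' columns are unrelated loci); at the stated PAR it acts as mild noise on
#' the memory-consideration draw.
#'
#' @param memories List of three `harmony_memory` objects.
#' @param hmcr Harmony-memory considering rate, in \[0, 1\].
#' @param par Pitch-adjusting rate, in \[0, 1\].
#' @param n_snps Panel size.
#' @param k Combination order.
#' @param taboo A [taboo_table()].
#' @param max_retries Taboo-rejection retries before the random fallback.
#' @param detail If `TRUE`, attach attribute `from_memory` (logical per
#'   position, pre-dedup) for instrumentation.
#' @return A sorted integer combination, or `NULL` on search exhaustion.
#' @export
improvise_harmony <- function(memories, hmcr, par, n_snps, k,
                              taboo = taboo_table(), max_retries = 50L,
                              detail = FALSE) {
  if (hmcr < 0 || hmcr > 1 || par < 0 || par > 1)
    stop("hmcr and par must be in [0, 1]")
  for (try in seq_len(max_retries)) {
    idx <- integer(k)
    from_mem <- logical(k)
    for (pos in seq_len(k)) {
      if (stats::runif(1) < hmcr) {
        m <- memories[[sample.int(length(memories), 1L)]]
        v <- m$harmonies[sample.int(nrow(m$harmonies), 1L), pos]
        from_mem[pos] <- TRUE
        if (stats::runif(1) < par) {
          v <- v + sample(c(-1L, 1L), 1L)
          if (v < 1L) v <- 2L          # reflect at the boundaries
          if (v > n_snps) v <- n_snps - 1L
        }
      } else {
        v <- sample.int(n_snps, 1L)
      }
      idx[pos] <- v
    }
    guard <- 0L
    while (anyDuplicated(idx)) {
      dup <- which(duplicated(idx))
      idx[dup] <- sample.int(n_snps, length(dup))
      guard <- guard + 1L
      if (guard > 100L) break
    }
    if (anyDuplicated(idx)) next
    idx <- sort(idx)
    if (!is_tabooed(idx, taboo)) {
      if (detail) attr(idx, "from_memory") <- from_mem
      return(idx)
    }
  }
  .random_combo(n_snps, k, taboo)  # NULL signals search exhaustion
}

#' Offer a candidate to a harmony memory
#'
#' Survival of the fittest: if the candidate scores strictly better than the
#' current worst member and is not already present, it replaces the worst.
#' The stagnation counter resets on improvement and increments otherwise.
#'
#' @param memory A `harmony_memory`.
#' @param candidate Sorted integer combination.
#' @param candidate_score Its score under this memory's objective.
#' @return List with the updated `memory` and logical `improved`.
#' @export
update_memory <- function(memory, candidate, candidate_score) {
  id <- .combo_id(candidate)
  improved <- FALSE
  if (!(id %in% memory$ids)) {
    wi <- memory$worst_index
    if (candidate_score < memory$scores[wi]) {
      memory$harmonies[wi, ] <- candidate
      memory$scores[wi] <- candidate_score
      memory$ids[wi] <- id
      memory$worst_index <- which.max(memory$scores)
      improved <- TRUE
    }
  }
  memory$stagnation <- if (improved) 0L else memory$stagnation + 1L
  list(memory = memory, improved = improved)
}

#' Identify the niche region a stagnant memory has converged on
#'
#' The defining loci are the SNP indices appearing in strictly more than half
#' of the memory's harmonies (the convergence core); if no index reaches a
#' majority, the best harmony's full index set is used. The radius is the
#' allowed overlap, `|defining_snps| - 1` capped at `k - 1`, so with a
#' single-locus core any combination containing that locus is tabooed.
#'
#' @param memory A `harmony_memory` (typically with stagnation >= T).
#' @return A list of class `niche_region`: `defining_snps`, `radius`,
#'   `best_member` (list with `combo` and `score`), `objective`.
#' @export
identify_niche <- function(memory) {
  k <- ncol(memory$harmonies)
  hms <- nrow(memory$harmonies)
  cnt <- table(as.vector(memory$harmonies))
  core <- as.integer(names(cnt)[cnt > hms / 2])
  bi <- which.min(memory$scores)
  best <- list(combo = memory$harmonies[bi, ], score = memory$scores[bi])
  if (length(core) == 0L) core <- best$combo
  structure(
    list(defining_snps = sort(core),
         radius = min(length(core) - 1L, k - 1L),
         best_member = best, objective = memory$objective),
    class = "niche_region")
}

#' Empty elite archive
#' @param capacity Maximum number of members retained.
#' @return A list of class `elite_set`.
#' @export
elite_set <- function(capacity) {
  structure(
    list(capacity = as.integer(capacity),
         combos = NULL, scores = numeric(0), ids = character(0)),
    class = "elite_set")
}

.elite_add <- function(es, combos, scores) {
  ids <- apply(combos, 1L, paste, collapse = ",")
  new <- !(ids %in% es$ids)
  if (any(new)) {
    es$combos <- rbind(es$combos, combos[new, , drop = FALSE])
    es$scores <- c(es$scores, scores[new])
    es$ids <- c(es$ids, ids[new])
  }
  o <- order(es$scores)
  keep <- o[seq_len(min(length(o), es$capacity))]
  es$combos <- es$combos[keep, , drop = FALSE]
  es$scores <- es$scores[keep]
  es$ids <- es$ids[keep]
  es
}

#' Harvest the best memory members into the elite archives
#'
#' The top `m` harmonies of each memory are merged into the corresponding
#' elite set; duplicates are dropped and each set is truncated to capacity by
#' score. Harvesting the same memory twice is idempotent.
#'
#' @param memories List of three `harmony_memory` objects (k2, gini, entropy).
#' @param elite_sets List of three [elite_set()] objects in the same order.
#' @param m Number of members to harvest per memory (<= HMS).
#' @return The updated list of elite sets.
#' @export
harvest_elites <- function(memories, elite_sets, m) {
  for (i in seq_along(memories)) {
    mem <- memories[[i]]
    m_i <- min(m, nrow(mem$harmonies))
    top <- order(mem$scores)[seq_len(m_i)]
    elite_sets[[i]] <- .elite_add(elite_sets[[i]],
                                  mem$harmonies[top, , drop = FALSE],
                                  mem$scores[top])
  }
  elite_sets
}
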
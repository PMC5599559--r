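# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's computation paths: log-factorials
# are summed from integer logs (not lgamma), tallies are naive nested loops.

logfact <- function(m) if (m < 2L) 0 else sum(log(seq_len(m)))

# Direct evaluation of the K2 marginal-likelihood product in log domain.
k2_oracle <- function(counts) {
  total <- 0
  for (i in seq_len(nrow(counts))) {
    ni <- sum(counts[i, ])
    term <- logfact(ni + 1L)                       # ln (n_i + J - 1)!, J = 2
    for (j in seq_len(ncol(counts))) term <- term - logfact(counts[i, j])
    total <- total + term
  }
  total
}

gini_oracle <- function(counts) {
  counts <- unname(counts)
  n <- sum(counts)
  total <- 0
  for (i in seq_len(nrow(counts))) {
    ni <- sum(counts[i, ])
    if (ni == 0) next
    imp <- 1
    for (j in seq_len(ncol(counts))) imp <- imp - (counts[i, j] / ni)^2
    total <- total + (ni / n) * imp
  }
  total
}

entropy_oracle <- function(counts) {
  n <- sum(counts)
  total <- 0
  for (i in seq_len(nrow(counts))) {
    ni <- sum(counts[i, ])
    if (ni == 0) next
    total <- total - (ni / n) * log2(ni / n)
  }
  total
}

# Random contingency table as the package builds them (observed rows only).
random_table <- function(I = NULL, max_count = 60L) {
  if (is.null(I)) I <- sample(1:9, 1L)
  counts <- matrix(sample(0:max_count, 2L * I, replace = TRUE), I, 2L)
  if (all(counts == 0L)) counts[1L, 1L] <- 1L
  keys <- cbind(sample(0:2, I, replace = TRUE), seq_len(I) %% 3L)
  contingency_table(counts, keys)
}

# Random valid dataset.
random_dataset <- function(n = 50L, n_snps = 5L) {
  g <- matrix(sample(0:2, n * n_snps, replace = TRUE), n, n_snps)
  ph <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
  case_control_dataset(g, ph)
}

# Brute-force contingency tally: nested loop over individuals, rows keyed by
# the genotype tuple string.
brute_contingency <- function(dataset, combo) {
  tal <- list()
  for (i in seq_len(dataset$n)) {
    key <- paste(dataset$genotypes[i, combo], collapse = "-")
    if (is.null(tal[[key]])) tal[[key]] <- c(0L, 0L)
    j <- dataset$phenotype[i] + 1L
    tal[[key]][j] <- tal[[key]][j] + 1L
  }
  tal
}

# The worked sparse 2-way example shipped with the package (observed counts
# of a case/control 2-SNP contingency table with three near-empty genotype
# columns).
sparse_2way_fixture <- function() {
  path <- system.file("extdata", "sparse_2way_counts.tsv",
                      package = "epiharmony")
  df <- read.delim(path, stringsAsFactors = FALSE)
  keys <- do.call(rbind, lapply(strsplit(df$genotype, "-"), as.integer))
  contingency_table(cbind(control = df$control, case = df$case), keys)
}
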
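# Core domain types: case/control genotype datasets, k-way SNP combinations,
# and genotype-combination x phenotype contingency tables.

#' Construct and validate a case/control genotype dataset
#'
#' The central data container of the package: an individuals-by-SNPs genotype
#' matrix coded by minor-allele dosage (0 = homozygous major, 1 = heterozygous,
#' 2 = homozygous minor) together with a binary phenotype (1 = case,
#' 0 = control).
#'
#' @param genotypes Integer matrix, individuals in rows, SNPs in columns,
#'   values in \{0, 1, 2\}.
#' @param phenotype Integer vector of 0/1 disease status, one per individual.
#' @param snp_names Character vector of SNP identifiers, one per column.
#'   Defaults to the column names of `genotypes`, or `SNP1..SNPm`.
#'
#' @return An object of class `case_control_dataset`: a list with elements
#'   `genotypes`, `phenotype`, `snp_names`, `n` (sample count) and
#'   `n_snps`.
#'
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L, 0L, 2L), nrow = 4)
#' ds <- case_control_dataset(g, c(0L, 0L, 1L, 1L), c("rs1", "rs2"))
#' ds$n_snps
#' @export
case_control_dataset <- function(genotypes, phenotype, snp_names = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (is.null(snp_names)) {
    snp_names <- colnames(genotypes)
    if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(genotypes)))
  }
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length (", length(phenotype),
         ") does not match genotype row count (", nrow(genotypes), ")")
  if (length(snp_names) != ncol(genotypes))
    stop("snp_names length does not match genotype column count")
  if (ncol(genotypes) < 2L)
    stop("a dataset needs at least 2 SNP columns")
  bad <- which(!(genotypes %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(genotypes)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(genotypes)) + 1L
    stop("invalid genotype value '", genotypes[bad[1L]], "' at row ", i,
         ", column '", snp_names[j], "' (must be 0, 1 or 2)")
  }
  if (any(!(phenotype %in% c(0L, 1L))))
    stop("phenotype values must be 0 (control) or 1 (case)")
  if (!any(phenotype == 1L) || !any(phenotype == 0L))
    stop("dataset must contain at least one case and one control")
  dimnames(genotypes) <- NULL
  structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_names = as.character(snp_names),
         n = nrow(genotypes), n_snps = ncol(genotypes)),
    class = "case_control_dataset")
}

#' @export
print.case_control_dataset <- function(x, ...) {
  cat("case_control_dataset:", x$n, "individuals (",
      sum(x$phenotype == 1L), "cases /", sum(x$phenotype == 0L),
      "controls ),", x$n_snps, "SNPs\n")
  invisible(x)
}

#' Read a delimited genotype table
#'
#' Reads a text genotype matrix with a header of SNP names and a binary
#' phenotype column. Rows containing any missing genotype are dropped; the
#' number of dropped rows is attached as attribute `dropped`.
#'
#' Dialects:
#' \describe{
#'   \item{`tsv` / `csv`}{One individual per row, genotype cells 0/1/2,
#'     phenotype column named by `phenotype_col` (default `"Class"`) coded
#'     0/1.}
#'   \item{`plink_raw`}{Whitespace-separated additive-coded export: leading
#'     bookkeeping columns (FID, IID, PAT, MAT, SEX) are ignored, the
#'     `PHENOTYPE` column coded 1/2 is recoded to 0/1, and a trailing
#'     `_<allele>` suffix on SNP column names is stripped.}
#' }
#'
#' @param path Path to the file.
#' @param dialect One of `"tsv"`, `"csv"`, `"plink_raw"`.
#' @param phenotype_col Name of the phenotype column (`tsv`/`csv` dialects).
#' @return A validated [case_control_dataset()].
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "csv", "plink_raw"),
                                phenotype_col = "Class") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- switch(dialect, tsv = "\t", csv = ",", plink_raw = "")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (dialect == "plink_raw") {
    drop_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX"), names(df))
    phen <- df[["PHENOTYPE"]]
    if (is.null(phen)) stop("plink_raw file lacks a PHENOTYPE column")
    df <- df[, setdiff(names(df), c(drop_cols, "PHENOTYPE")), drop = FALSE]
    names(df) <- sub("_[ACGT0-9]+$", "", names(df))
    phen <- ifelse(phen == 2, 1L, ifelse(phen == 1, 0L, NA_integer_))
  } else {
    if (!(phenotype_col %in% names(df)))
      stop("phenotype column '", phenotype_col, "' not found in ", path)
    phen <- df[[phenotype_col]]
    df <- df[, setdiff(names(df), phenotype_col), drop = FALSE]
  }
  if (ncol(df) < 2L) stop("fewer than 2 SNP columns in ", path)
  gm <- as.matrix(df)
  if (is.character(gm)) {
    suppressWarnings(storage.mode(gm) <- "numeric")
  }
  bad <- which(!is.na(gm) & !(gm %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(gm)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(gm)) + 1L
    stop("malformed genotype value at data row ", i, ", column '",
         colnames(gm)[j], "' of ", path, " (must be 0, 1 or 2)")
  }
  keep <- stats::complete.cases(gm) & !is.na(phen)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message("read_genotype_table: dropped ", dropped,
            " row(s) with missing genotypes")
  ds <- case_control_dataset(gm[keep, , drop = FALSE],
                             as.integer(phen[keep]), colnames(gm))
  attr(ds, "dropped") <- dropped
  ds
}

#' Write a dataset as a delimited genotype table
#'
#' Inverse of [read_genotype_table()] for the `tsv`/`csv` dialects; a
#' write-then-read round trip reproduces the dataset exactly.
#'
#' @param dataset A [case_control_dataset()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param phenotype_col Phenotype column name to emit.
#' @export
write_genotype_table <- function(dataset, path, dialect = c("tsv", "csv"),
                                 phenotype_col = "Class") {
  dialect <- match.arg(dialect)
  df <- as.data.frame(dataset$genotypes)
  names(df) <- dataset$snp_names
  df[[phenotype_col]] <- dataset$phenotype
  utils::write.table(df, path, sep = if (dialect == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a k-way SNP combination
#'
#' A combination is a strictly increasing vector of k >= 2 distinct 1-based
#' SNP column indices. Internally combinations are plain sorted integer
#' vectors; user-facing reports always translate them to SNP names.
#'
#' @param indices Integer vector of SNP column indices.
#' @param n_snps Optional SNP count to bound-check against.
#' @return The validated (sorted) integer vector.
#' @export
snp_combination <- function(indices, n_snps = NULL) {
  indices <- as.integer(indices)
  if (length(indices) < 2L) stop("a SNP combination needs k >= 2 loci")
  if (anyDuplicated(indices)) stop("SNP indices must be distinct")
  indices <- sort(indices)
  if (indices[1L] < 1L) stop("SNP indices are 1-based")
  if (!is.null(n_snps) && indices[length(indices)] > n_snps)
    stop("SNP index ", indices[length(indices)], " exceeds n_snps = ", n_snps)
  indices
}

# Integer genotype key per individual for a combination: first SNP is the most
# significant base-3 digit, so key order is lexicographic in the genotype tuple.
.geno_key <- function(genotypes, combo) {
  k <- length(combo)
  as.integer(genotypes[, combo, drop = FALSE] %*% 3^((k - 1L):0))
}

# Hot path used by the scoring stage: observed-rows-only I x 2 count matrix
# (col 1 = controls, col 2 = cases), no key decoding, no class baggage.
.contingency_counts <- function(genotypes, phenotype, combo) {
  k <- length(combo)
  nc <- 3L^k
  key <- .geno_key(genotypes, combo)
  case <- phenotype == 1L
  cc <- tabulate(key[case] + 1L, nc)
  ct <- tabulate(key[!case] + 1L, nc)
  obs <- which((cc + ct) > 0L)
  cbind(ct[obs], cc[obs])
}

.decode_keys <- function(codes, k) {
  out <- matrix(0L, length(codes), k)
  for (j in k:1) {
    out[, j] <- codes %% 3L
    codes <- codes %/% 3L
  }
  out
}

.key_labels <- function(keys) apply(keys, 1L, paste, collapse = "-")

#' Count the genotype-combination x phenotype contingency table
#'
#' One pass over individuals; rows are keyed by the k-tuple of genotype values
#' and only genotype combinations actually observed in the data appear
#' (I <= 3^k). Row order is canonical: lexicographic in the genotype tuple.
#'
#' @param dataset A [case_control_dataset()].
#' @param combo A [snp_combination()] (sorted integer indices).
#' @return An object of class `genotype_contingency`: `counts` (I x 2 integer
#'   matrix, columns `control`, `case`), `genotype_keys` (I x k matrix of
#'   0/1/2), `row_totals`, `col_totals`, `n`, `k`, `combo`.
#' @export
count_genotype_contingency <- function(dataset, combo) {
  combo <- snp_combination(combo, dataset$n_snps)
  k <- length(combo)
  nc <- 3L^k
  key <- .geno_key(dataset$genotypes, combo)
  case <- dataset$phenotype == 1L
  cc <- tabulate(key[case] + 1L, nc)
  ct <- tabulate(key[!case] + 1L, nc)
  obs <- which((cc + ct) > 0L)
  counts <- cbind(control = ct[obs], case = cc[obs])
  contingency_table(counts, .decode_keys(obs - 1L, k), combo = combo)
}

#' Assemble a contingency table from explicit counts
#'
#' Mostly useful for feeding printed or hand-built tables straight into the
#' scoring and G-test functions.
#'
#' @param counts I x 2 non-negative integer matrix (columns control, case).
#' @param genotype_keys I x k matrix of genotype values 0/1/2, one row per
#'   count row.
#' @param combo Optional SNP indices the table was counted on.
#' @return A `genotype_contingency` object.
#' @export
contingency_table <- function(counts, genotype_keys, combo = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (ncol(counts) != 2L) stop("counts must have 2 phenotype columns")
  if (any(counts < 0L)) stop("counts must be non-negative")
  genotype_keys <- as.matrix(genotype_keys)
  if (nrow(genotype_keys) != nrow(counts))
    stop("genotype_keys must have one row per count row")
  colnames(counts) <- c("control", "case")
  structure(
    list(counts = counts, genotype_keys = genotype_keys,
         row_totals = rowSums(counts), col_totals = colSums(counts),
         n = sum(counts), k = ncol(genotype_keys), combo = combo),
    class = "genotype_contingency")
}

#' @export
print.genotype_contingency <- function(x, ...) {
  cat("genotype_contingency:", nrow(x$counts), "observed genotype rows, k =",
      x$k, ", n =", x$n, "\n")
  m <- cbind(genotype = .key_labels(x$genotype_keys),
             as.data.frame(x$counts))
  print(m, row.names = FALSE)
  invisible(x)
}

#' Exact binomial coefficient
#'
#' Number of candidate k-way SNP combinations among n loci, C(n, k), computed
#' in exact integer arithmetic (errors out rather than losing precision past
#' 2^53).
#'
#' @param n Number of SNPs (positive integer).
#' @param k Combination order, 1 <= k <= n.
#' @return C(n, k) as a double holding an exact integer.
#' @examples
#' combination_count(100, 3)  # 161700
#' @export
combination_count <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  if (length(n) != 1L || length(k) != 1L || n < 1 || k < 1 ||
      n != floor(n) || k != floor(k))
    stop("n and k must be positive integers")
  if (k > n) stop("k (", k, ") exceeds n (", n, ")")
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) {
    if (r * (n - k + i) > 2^53)
      stop("combination_count: exact integer overflow for C(", n, ",", k, ")")
    r <- round(r * (n - k + i) / i)  # exact at every step: r = C(n-k+i, i)
  }
  r
}
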
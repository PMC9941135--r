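#' Filter lowly expressed genes by counts per million
#'
#' Keeps genes with `cpm >= threshold` in at least `min_samples` samples,
#' where `cpm = count / library_size * 1e6`.
#'
#' @param counts Nonnegative count matrix, genes x samples, with rownames.
#' @param threshold CPM threshold (default 1).
#' @param min_samples Minimal number of samples meeting the threshold
#'   (default 1).
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Character vector of retained gene IDs.
#' @export
cpm_filter <- function(counts, threshold = 1, min_samples = 1L,
                       lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), length(lib_sizes) == ncol(counts))
  if (any(lib_sizes == 0)) stop("zero library size", call. = FALSE)
  cpm <- sweep(counts, 2L, lib_sizes, "/") * 1e6
  keep <- rowSums(cpm >= threshold) >= min_samples
  rownames(counts)[keep]
}

#' Threshold a differential-expression table
#'
#' Partitions genes into up, down and not-significant using the standard
#' cutoffs: up when `fdr <= 0.05` and `lfc >= 0.585` (a 50% increase), down
#' when `fdr <= 0.05` and `lfc <= -0.585` (a 33% decrease), `ns` otherwise.
#' Boundary values are included.
#'
#' @param table Data.frame with columns `gene`, `lfc`, `fdr`.
#' @param lfc_min Absolute log2 fold-change cutoff (default 0.585).
#' @param fdr_max FDR cutoff (default 0.05).
#' @return The table with a `direction` factor column added (`up`, `down`,
#'   `ns`), plus attributes `up` and `down` holding the gene ID vectors.
#' @export
deg_threshold <- function(table, lfc_min = 0.585, fdr_max = 0.05) {
  stopifnot(all(c("gene", "lfc", "fdr") %in% names(table)),
            all(table$fdr >= 0 & table$fdr <= 1))
  dir <- ifelse(table$fdr <= fdr_max & table$lfc >= lfc_min, "up",
         ifelse(table$fdr <= fdr_max & table$lfc <= -lfc_min, "down", "ns"))
  table$direction <- factor(dir, levels = c("up", "down", "ns"))
  attr(table, "up") <- table$gene[dir == "up"]
  attr(table, "down") <- table$gene[dir == "down"]
  table
}

#' One-sided hypergeometric overlap test
#'
#' Tests whether two gene sets drawn from a common universe overlap more than
#' expected by chance: with universe size N, |set_a| = n, |set_b| = K and
#' overlap k, the upper-tail p-value is
#' \deqn{p = \sum_{j=k}^{\min(n,K)} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}.}
#' Gene IDs are whitespace-trimmed, compared case-sensitively and
#' de-duplicated. The universe must be supplied explicitly (e.g. all genes
#' surviving the expression filter); there is no defensible default.
#'
#' @param set_a,set_b Character vectors of gene IDs, subsets of `universe`.
#' @param universe Character vector of all testable gene IDs.
#' @return A one-row data.frame: `universe_size, set_a_size, set_b_size,
#'   overlap, p_value`.
#' @examples
#' hypergeom_overlap(letters[1:5], letters[1:5], letters[1:10])
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  trim <- function(x) unique(trimws(as.character(x)))
  set_a <- trim(set_a); set_b <- trim(set_b); universe <- trim(universe)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("IDs not in universe: ",
         paste(utils::head(c(out_a, out_b), 10L), collapse = ", "),
         call. = FALSE)
  N <- length(universe); n <- length(set_a); K <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(universe_size = N, set_a_size = n, set_b_size = K,
             overlap = k, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (a thin wrapper around [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Read a one-ID-per-line gene list
#'
#' @param path Text file, one gene ID per line; blank lines ignored.
#' @return Character vector of IDs.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
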
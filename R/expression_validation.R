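#' Read a gene x sample count matrix
#'
#' Tab-separated table with a `gene` column followed by one integer count
#' column per sample.
#'
#' @param path `.tsv` path (optionally gzipped).
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, "gene", "count matrix")
  g <- as.character(dt$gene)
  if (anyDuplicated(g)) stop("count matrix: duplicate gene ids",
                             call. = FALSE)
  m <- as.matrix(dt[, !"gene"])
  mode(m) <- "numeric"
  if (any(m < 0, na.rm = TRUE))
    stop("count matrix: negative counts", call. = FALSE)
  rownames(m) <- g
  m
}

#' Median-of-ratios normalization
#'
#' Library-size correction for count matrices: the reference for each gene is
#' its geometric mean across samples (over genes with all-positive counts);
#' each sample's size factor is the median of its count/reference ratios over
#' those genes, and normalized counts are raw counts divided by the size
#' factor. Scaling one sample's counts by a constant scales its size factor
#' by the same constant and leaves its normalized profile unchanged.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param pseudocount value added to every count before computing references
#'   (default 0). Needed when no gene has all-positive counts.
#' @return List with `normalized` (same shape as `counts`) and
#'   `size_factors` (named per sample).
#' @export
median_of_ratios <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L)
    return(list(normalized = counts,
                size_factors = stats::setNames(1, colnames(counts))))
  work <- counts + pseudocount
  all_pos <- rowSums(work > 0) == ncol(work)
  if (!any(all_pos))
    stop("median_of_ratios: no gene with all-positive counts; ",
         "consider pseudocount > 0", call. = FALSE)
  ref <- exp(rowMeans(log(work[all_pos, , drop = FALSE])))
  sf <- apply(work[all_pos, , drop = FALSE], 2, function(cnt)
    stats::median(cnt / ref))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Mean normalized expression per bucket
#'
#' @param normalized normalized matrix from [median_of_ratios()].
#' @param sample_buckets named (or positionally matched) character vector
#'   sample -> bucket.
#' @param log_transform take `log2(x + 1)` of normalized counts before
#'   averaging (off by default).
#' @return Gene x bucket matrix of mean normalized expression.
#' @export
bucket_expression <- function(normalized, sample_buckets,
                              log_transform = FALSE) {
  if (!is.null(names(sample_buckets)))
    sample_buckets <- sample_buckets[colnames(normalized)]
  stopifnot(length(sample_buckets) == ncol(normalized))
  x <- if (log_transform) log2(normalized + 1) else normalized
  bks <- sort(unique(as.character(sample_buckets)))
  out <- vapply(bks, function(b)
    rowMeans(x[, sample_buckets == b, drop = FALSE]),
    numeric(nrow(normalized)))
  dimnames(out) <- list(rownames(normalized), bks)
  out
}

#' Correlate scores with expression, with permutation significance
#'
#' Pearson correlation between a gene score vector (one bucket's aggregated
#' scores) and a gene expression vector (another — possibly the same —
#' bucket's mean normalized expression), computed on the overlapping genes.
#' Significance is the add-one empirical p-value of |r| against `n_perm`
#' permutations of the expression vector's gene labels (two-sided).
#'
#' @param pre_vec named numeric vector gene -> score.
#' @param expr_vec named numeric vector gene -> expression.
#' @param n_perm number of permutations (default 1000; 0 skips the
#'   permutation test and returns `NA` for `p_perm`).
#' @param seed integer seed for the permutations.
#' @return List: `r`, `p_perm`, `n_genes` (overlap size), `n_perm`.
#' @export
correlate <- function(pre_vec, expr_vec, n_perm = 1000, seed = NULL) {
  genes <- intersect(names(pre_vec), names(expr_vec))
  if (length(genes) < 3)
    stop("correlate: fewer than 3 overlapping genes", call. = FALSE)
  x <- unname(pre_vec[genes])
  y <- unname(expr_vec[genes])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlate: zero variance in one of the vectors", call. = FALSE)
  r <- stats::cor(x, y)
  p_perm <- NA_real_
  if (n_perm > 0) {
    p_perm <- with_seed(seed, {
      null_r <- vapply(seq_len(n_perm), function(i)
        abs(stats::cor(x, y[sample.int(length(y))])), numeric(1))
      empirical_p(abs(r), null_r)
    })
  }
  list(r = r, p_perm = p_perm, n_genes = length(genes), n_perm = n_perm)
}

#' Score-vs-expression correlation grid
#'
#' Computes the full matrix of correlations between every score bucket and
#' every expression bucket — matched pairs on the diagonal, mismatched pairs
#' off it. In validated data the matched-bucket correlation should be the
#' highest in its row.
#'
#' @param gene_pre gene-level score table from [aggregate_gene_pre()].
#' @param expr gene x bucket expression matrix from [bucket_expression()].
#' @param n_perm permutations per cell (default 1000).
#' @param seed base seed; each grid cell uses a deterministic offset.
#' @return `data.table` with columns `pre_bucket`, `expr_bucket`, `r`,
#'   `p_perm`, `n_genes`, `matched`.
#' @export
correlation_grid <- function(gene_pre, expr, n_perm = 1000, seed = NULL) {
  gp <- as.data.table(gene_pre)
  require_columns(gp, c("gene", "bucket", "pre"), "gene score table")
  rows <- list()
  i <- 0L
  for (pb in sort(unique(gp$bucket))) {
    v <- gp[bucket == pb]
    pre_vec <- stats::setNames(v$pre, v$gene)
    for (eb in colnames(expr)) {
      i <- i + 1L
      res <- correlate(pre_vec, expr[, eb], n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else seed + i)
      rows[[i]] <- data.table(pre_bucket = pb, expr_bucket = eb,
                              r = res$r, p_perm = res$p_perm,
                              n_genes = res$n_genes,
                              matched = identical(pb, eb))
    }
  }
  rbindlist(rows)
}
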
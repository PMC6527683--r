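library(data.table)

# ---- tiny in-code fixtures ------------------------------------------------

# two-SNP, one-gene worked example: PEX with 3 experiments on s1, repressor
# with 1 experiment on s2, single bucket "T" (total = 4)
toy_catalogue <- function() {
  data.table(
    snp_id = c("s1", "s2"),
    feature_id = c("f1", "f2"),
    feature_type = c("enhancer", "h3k27me3"),
    reg_class = c("PEX", "R"),
    cell_raw = c("T_cell_1", "T_cell_1"),
    bucket = c("T", "T"),
    n_experiments = c(3L, 1L),
    target_gene = c("G", "G"))
}

toy_region_snps <- function() list(`1` = c("s1", "s2"))

write_toy_effects <- function(rows, path = tempfile(fileext = ".tsv")) {
  write_tsv_helper(rows, path)
  path
}

write_tsv_helper <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  path
}

# random classified mini-catalogue over a handful of SNPs/genes/buckets
random_mini_catalogue <- function(n_rows, n_snps = 6, n_genes = 4,
                                  buckets = c("T", "B")) {
  data.table(
    snp_id = sample(paste0("s", seq_len(n_snps)), n_rows, replace = TRUE),
    feature_id = paste0("f", seq_len(n_rows)),
    feature_type = "enhancer",
    reg_class = sample(c("PEX", "R", "ZQI"), n_rows, replace = TRUE),
    cell_raw = "x",
    bucket = sample(buckets, n_rows, replace = TRUE),
    n_experiments = sample.int(9L, n_rows, replace = TRUE),
    target_gene = sample(paste0("g", seq_len(n_genes)), n_rows,
                         replace = TRUE))
}

random_region_snps <- function(n_snps = 6, n_regions = 2) {
  snps <- paste0("s", seq_len(n_snps))
  split(snps, sample.int(n_regions, n_snps, replace = TRUE))
}

# ---- independent oracles --------------------------------------------------

# Brute-force score oracle: explicit triple loop over regions, SNPs and
# catalogue rows; shares no code with compute_pre().
oracle_pre <- function(region_snps, catalogue, dosage = NULL) {
  totals <- list()
  for (i in seq_len(nrow(catalogue))) {
    b <- catalogue$bucket[i]
    totals[[b]] <- (totals[[b]] %||% 0) + catalogue$n_experiments[i]
  }
  out <- list()
  for (r in names(region_snps)) {
    for (s in region_snps[[r]]) {
      d <- if (is.null(dosage)) 1 else dosage[[s]]
      for (i in seq_len(nrow(catalogue))) {
        if (catalogue$snp_id[i] != s) next
        sg <- switch(catalogue$reg_class[i], PEX = 1, R = -1, ZQI = 0)
        w <- sg * catalogue$n_experiments[i] / totals[[catalogue$bucket[i]]]
        key <- paste(catalogue$target_gene[i], r, catalogue$bucket[i],
                     sep = "|")
        out[[key]] <- (out[[key]] %||% 0) + d * w
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pre_as_oracle_list <- function(pre) {
  out <- list()
  for (i in seq_len(nrow(pre)))
    out[[paste(pre$gene[i], pre$region[i], pre$bucket[i], sep = "|")]] <-
      pre$pre[i]
  out
}

# Brute-force connected components by boolean transitive closure of the
# adjacency matrix; independent of the union-find used by the package.
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- (adj | diag(TRUE, n))
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- match(apply(reach, 1, paste, collapse = ""),
                unique(apply(reach, 1, paste, collapse = "")))
  comp
}

oracle_lcc <- function(adj) {
  if (nrow(adj) == 0) return(list(nodes = 0L, edges = 0L))
  comp <- oracle_components(adj)
  sizes <- table(comp)
  best <- as.integer(names(sizes)[which.max(sizes)])
  members <- which(comp == best)
  list(nodes = length(members),
       edges = sum(adj[members, members, drop = FALSE]) / 2)
}

# small simulation config for fast unit tests (not the acceptance defaults)
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_regions = 6, snps_per_region = 3, n_genes = 60,
             causal_gene_fraction = 0.2, planted_module_size = 10,
             ppi_nodes = 60, n_subjects = 40, n_samples_per_bucket = 4,
             seed = seed, ...)
}
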
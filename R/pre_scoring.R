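#' Total experiment counts per cell bucket
#'
#' The normalization denominators of the score: the sum of supporting
#' experiment counts over every catalogue row in each bucket. Dividing each
#' feature's weight by its bucket total removes the bias toward well-studied
#' cell types. Zero-weight (ZQI) rows are counted by default because the
#' denominator is the number of experiments conducted, not the number of
#' signed ones; set `include_zqi = FALSE` for the alternative convention.
#'
#' @param catalogue classified catalogue from [load_catalogue()] /
#'   [classify_catalogue()] (columns `bucket`, `n_experiments`, `reg_class`).
#' @param include_zqi count inert-class experiments in the totals (default
#'   `TRUE`).
#' @return Named numeric vector bucket -> total experiments.
#' @export
bucket_totals <- function(catalogue, include_zqi = TRUE) {
  cat_dt <- as.data.table(catalogue)
  require_columns(cat_dt, c("bucket", "n_experiments"), "catalogue")
  if (!nrow(cat_dt)) stop("bucket_totals: empty catalogue", call. = FALSE)
  if (!include_zqi) cat_dt <- cat_dt[reg_class != "ZQI"]
  tot <- cat_dt[, .(total = sum(as.numeric(n_experiments))), by = bucket]
  stats::setNames(tot$total, tot$bucket)
}

class_sign <- function(reg_class) {
  s <- rep(0, length(reg_class))
  s[reg_class == "PEX"] <- 1
  s[reg_class == "R"] <- -1
  s
}

#' Per-feature weighted weights
#'
#' One weighted weight (WW) per catalogue row: the signed experiment count
#' divided by the bucket's total experiment count. The sign is +1 for
#' promoter/enhancer/transcription evidence (PEX), -1 for repressive evidence
#' (R) and 0 for inert features (ZQI).
#'
#' @param catalogue classified catalogue rows.
#' @param totals named bucket totals from [bucket_totals()]; computed from
#'   `catalogue` when `NULL`.
#' @return The catalogue with an added numeric `ww` column.
#' @export
compute_ww <- function(catalogue, totals = NULL) {
  cat_dt <- copy(as.data.table(catalogue))
  require_columns(cat_dt, c("bucket", "reg_class", "n_experiments"),
                  "catalogue")
  if (is.null(totals)) totals <- bucket_totals(cat_dt)
  missing_b <- setdiff(unique(cat_dt$bucket), names(totals))
  if (length(missing_b))
    stop("compute_ww: no experiment total for bucket(s): ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  denom <- unname(totals[cat_dt$bucket])
  if (any(denom <= 0))
    stop("compute_ww: non-positive bucket total", call. = FALSE)
  cat_dt[, ww := class_sign(reg_class) * as.numeric(n_experiments) / denom]
  cat_dt[]
}

eqtl_to_features <- function(eqtl) {
  eq <- as.data.table(eqtl)
  require_columns(eq, c("snp_id", "target_gene", "bucket", "effect_sign"),
                  "eQTL table")
  data.table(
    snp_id = eq$snp_id,
    feature_id = paste0("eqtl:", eq$snp_id, ":", eq$target_gene, ":",
                        eq$bucket),
    feature_type = "eqtl",
    reg_class = ifelse(eq$effect_sign > 0, "PEX", "R"),
    cell_raw = eq$bucket,
    bucket = eq$bucket,
    n_experiments = 1L,
    target_gene = eq$target_gene)
}

#' Compute Predicted Regulatory Effect scores
#'
#' The central quantity of the pipeline: for every (gene, region, cell bucket)
#' triple, the sum over the region's SNPs and each SNP's catalogue features
#' targeting the gene in that bucket of the feature's weighted weight, scaled
#' by the SNP's risk-allele dosage,
#' \deqn{PRE(g, r, b) = \sum_{s \in r} d(s) \sum_{f: s \to g, b} ww(f).}
#' At population level every associated SNP carries dosage 1; supplying a
#' per-subject dosage vector yields that subject's individual scores, and the
#' two agree exactly when all dosages are 1.
#'
#' eQTL records, when supplied, enter as single-experiment pseudo-features
#' whose sign is the direction of the risk-allele effect on expression; they
#' are also counted in the bucket totals when those are computed here.
#'
#' @param region_snps named list region id -> SNP id vector, from
#'   [expand_ld()].
#' @param catalogue classified catalogue.
#' @param totals bucket totals; when `NULL` (recommended) they are computed
#'   from the catalogue plus any eQTL pseudo-features.
#' @param eqtl optional eQTL table from [read_eqtl()].
#' @param dosage optional named numeric vector SNP id -> risk-allele dosage in
#'   \[0, 2\]. `NULL` means population mode (dosage 1 everywhere).
#' @param impute_missing policy for SNPs absent from `dosage`: `"one"`
#'   (default, population value) or `"zero"`. Imputed SNPs are counted in the
#'   `n_imputed` attribute.
#' @return `data.table` with columns `gene`, `region`, `bucket`, `pre`; one
#'   row per triple with at least one contributing catalogue row.
#' @export
compute_pre <- function(region_snps, catalogue, totals = NULL, eqtl = NULL,
                        dosage = NULL, impute_missing = c("one", "zero")) {
  impute_missing <- match.arg(impute_missing)
  cat_dt <- as.data.table(catalogue)
  if (!is.null(eqtl) && nrow(as.data.table(eqtl)))
    cat_dt <- rbindlist(list(cat_dt, eqtl_to_features(eqtl)),
                        use.names = TRUE, fill = TRUE)
  if (is.null(totals)) totals <- bucket_totals(cat_dt)
  cat_dt <- compute_ww(cat_dt, totals)

  snp_region <- rbindlist(lapply(names(region_snps), function(r)
    data.table(region = r, snp_id = region_snps[[r]])))
  if (is.null(snp_region) || !nrow(snp_region))
    return(data.table(gene = character(), region = character(),
                      bucket = character(), pre = numeric()))

  rows <- merge(snp_region, cat_dt[, .(snp_id, target_gene, bucket, ww)],
                by = "snp_id", allow.cartesian = TRUE)
  if (!nrow(rows))
    return(data.table(gene = character(), region = character(),
                      bucket = character(), pre = numeric()))

  n_imputed <- 0L
  if (is.null(dosage)) {
    rows[, dose := 1]
  } else {
    d <- unname(dosage[rows$snp_id])
    miss <- is.na(d)
    n_imputed <- length(unique(rows$snp_id[miss]))
    d[miss] <- if (impute_missing == "one") 1 else 0
    if (any(d < 0 | d > 2))
      stop("compute_pre: dosages must lie in [0, 2]", call. = FALSE)
    rows[, dose := d]
  }

  pre <- rows[, .(pre = sum(dose * ww)),
              by = .(gene = target_gene, region, bucket)]
  setorder(pre, gene, region, bucket)
  data.table::setattr(pre, "n_imputed", n_imputed)
  pre[]
}

#' Aggregate scores over regions
#'
#' Collapses a (gene, region, bucket) score table to gene-level scores per
#' bucket by summing over regions. Genes contributed to by more than one
#' region are counted in the `n_multi_region` attribute.
#'
#' @param pre score table from [compute_pre()].
#' @return `data.table` with columns `gene`, `bucket`, `pre`.
#' @export
aggregate_gene_pre <- function(pre) {
  pre_dt <- as.data.table(pre)
  if (!nrow(pre_dt))
    return(data.table(gene = character(), bucket = character(),
                      pre = numeric()))
  require_columns(pre_dt, c("gene", "region", "bucket", "pre"), "pre matrix")
  multi <- pre_dt[, .(n = length(unique(region))), by = gene][n > 1L]
  out <- pre_dt[, .(pre = sum(pre)), by = .(gene, bucket)]
  setorder(out, gene, bucket)
  data.table::setattr(out, "n_multi_region", nrow(multi))
  out[]
}

#' Reshape gene-level scores to a wide gene x bucket table
#'
#' @param gene_pre table from [aggregate_gene_pre()].
#' @param fill value for (gene, bucket) cells with no evidence (default 0).
#' @return Wide `data.table`, one row per gene, one column per bucket.
#' @export
pre_wide <- function(gene_pre, fill = 0) {
  data.table::dcast(as.data.table(gene_pre), gene ~ bucket,
                    value.var = "pre", fill = fill)
}

#' Percentile cutoff on a score distribution
#'
#' Linear-interpolation percentile (R quantile type 7) of a bucket's score
#' distribution. Downstream selection keeps genes strictly above the cutoff
#' and strictly positive, so ties at the cutoff are excluded and a constant
#' distribution selects nothing.
#'
#' @param values numeric scores (one bucket's full distribution).
#' @param q percentile in \[0, 100\]; the sensitivity analysis uses 10, 25
#'   and 50.
#' @return The cutoff value.
#' @export
pre_percentile_cutoff <- function(values, q) {
  values <- values[!is.na(values)]
  if (!length(values))
    stop("pre_percentile_cutoff: empty value collection", call. = FALSE)
  stopifnot(q >= 0, q <= 100)
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

#' Select high-scoring genes in one bucket
#'
#' @param gene_pre named numeric vector gene -> score for one bucket.
#' @param q percentile threshold (default 25).
#' @return Character vector of genes with score strictly above both the
#'   `q`-th percentile cutoff and zero.
#' @export
select_high_pre <- function(gene_pre, q = 25) {
  if (!length(gene_pre)) return(character())
  cut <- pre_percentile_cutoff(gene_pre, q)
  names(gene_pre)[gene_pre > cut & gene_pre > 0]
}

#' Write score tables
#'
#' Long format: columns `gene`, `region`, `bucket` (plus `subject` when
#' present) and `pre`. See [pre_wide()] for the heatmap-ready layout.
#'
#' @param pre score table.
#' @param path output `.tsv` path.
#' @export
write_pre <- function(pre, path) write_tsv(as.data.table(pre), path)
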
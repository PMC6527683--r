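#' Read a subject x SNP dosage table
#'
#' Tab-separated table with a `subject_id` column followed by one column per
#' SNP holding risk-allele dosages in \[0, 2\] (hard genotype counts or
#' imputed fractional dosages).
#'
#' @param path `.tsv` path (optionally gzipped).
#' @return Numeric matrix, SNPs in rows, subjects in columns.
#' @export
read_dosage_tsv <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, "subject_id", "dosage table")
  subj <- as.character(dt$subject_id)
  if (anyDuplicated(subj))
    stop("dosage table: duplicate subject_id", call. = FALSE)
  m <- as.matrix(dt[, !"subject_id"])
  mode(m) <- "numeric"
  if (any(m < 0 | m > 2, na.rm = TRUE))
    stop("dosage table: dosages must lie in [0, 2]", call. = FALSE)
  t(structure(m, dimnames = list(subj, colnames(m))))
}

#' Derive risk-allele dosages from a VCF
#'
#' Reads genotypes with \pkg{vcfR} and converts them to risk-allele counts
#' against the declared risk allele of each effect. When the risk allele
#' matches ALT the dosage is the ALT-allele count; when it matches REF the
#' count is flipped (`2 - alt count`); when it matches neither, the SNP is
#' dropped with a warning (allele-flip detection).
#'
#' @param path VCF path (optionally gzipped).
#' @param effects effect table from [read_effect_list()] carrying
#'   `snp_id` and `risk_allele`.
#' @return Numeric dosage matrix, SNPs x subjects; missing genotypes are
#'   `NA` (imputation is deferred to [compute_pre()]'s policy).
#' @export
read_genotypes_vcf <- function(path, effects) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # ALT allele count per genotype string (handles phased and unphased)
  alt_count <- function(g) {
    g <- sub(":.*$", "", g)
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(a == "1"), numeric(1)))
  }
  dn <- apply(gt, 2, alt_count)
  if (is.null(dim(dn))) dn <- matrix(dn, nrow = nrow(gt),
                                     dimnames = dimnames(gt))
  rownames(dn) <- fix$ID
  eff <- as.data.table(effects)
  keep <- intersect(eff$snp_id, rownames(dn))
  dn <- dn[keep, , drop = FALSE]
  ra <- stats::setNames(eff$risk_allele, eff$snp_id)[keep]
  ref <- stats::setNames(fix$REF, fix$ID)[keep]
  alt <- stats::setNames(fix$ALT, fix$ID)[keep]
  is_alt <- ra == alt
  is_ref <- ra == ref
  drop <- !(is_alt | is_ref)
  if (any(drop)) {
    warning("read_genotypes_vcf: risk allele matches neither REF nor ALT ",
            "for ", sum(drop), " SNP(s); dropped", call. = FALSE)
    dn <- dn[!drop, , drop = FALSE]
    is_ref <- is_ref[!drop]
  }
  dn[is_ref, ] <- 2 - dn[is_ref, , drop = FALSE]
  dn
}

#' Individual score matrix for one subject
#'
#' Delegates to [compute_pre()] with the subject's dosage vector: each SNP's
#' contribution is scaled by the number of risk alleles the subject carries,
#' so a subject homozygous for every risk allele scores exactly twice the
#' population value and a subject carrying none scores zero.
#'
#' @param dosages named numeric vector SNP -> dosage for one subject, or a
#'   dosage matrix from [read_dosage_tsv()] plus `subject_id`.
#' @param subject_id column to take when `dosages` is a matrix.
#' @inheritParams compute_pre
#' @return Score table as from [compute_pre()].
#' @export
subject_pre <- function(dosages, region_snps, catalogue, totals = NULL,
                        subject_id = NULL, eqtl = NULL,
                        impute_missing = c("one", "zero")) {
  if (is.matrix(dosages)) {
    if (is.null(subject_id))
      stop("subject_pre: subject_id required with a dosage matrix",
           call. = FALSE)
    if (!subject_id %in% colnames(dosages))
      stop("subject_pre: subject ", subject_id,
           " absent from the genotype input", call. = FALSE)
    dosages <- dosages[, subject_id]
  }
  compute_pre(region_snps, catalogue, totals = totals, eqtl = eqtl,
              dosage = dosages, impute_missing = impute_missing)
}

# (gene, bucket) x SNP weight matrix: entry = sum over regions and features
# of ww for that SNP targeting that gene in that bucket. Cohort scores are
# then a single sparse matrix product W %*% D.
ww_matrix <- function(region_snps, catalogue, totals = NULL, eqtl = NULL) {
  cat_dt <- as.data.table(catalogue)
  if (!is.null(eqtl) && nrow(as.data.table(eqtl)))
    cat_dt <- rbindlist(list(cat_dt, eqtl_to_features(eqtl)),
                        use.names = TRUE, fill = TRUE)
  if (is.null(totals)) totals <- bucket_totals(cat_dt)
  cat_dt <- compute_ww(cat_dt, totals)
  snp_region <- rbindlist(lapply(names(region_snps), function(r)
    data.table(region = r, snp_id = region_snps[[r]])))
  rows <- merge(snp_region, cat_dt[, .(snp_id, target_gene, bucket, ww)],
                by = "snp_id", allow.cartesian = TRUE)
  agg <- rows[, .(ww = sum(ww)), by = .(gene = target_gene, bucket, snp_id)]
  gb <- unique(agg[, .(gene, bucket)])
  setorder(gb, gene, bucket)
  gb[, key := paste(gene, bucket, sep = "\r")]
  snps <- sort(unique(agg$snp_id))
  W <- Matrix::sparseMatrix(
    i = match(paste(agg$gene, agg$bucket, sep = "\r"), gb$key),
    j = match(agg$snp_id, snps),
    x = agg$ww, dims = c(nrow(gb), length(snps)),
    dimnames = list(gb$key, snps))
  list(W = W, genes = gb$gene, buckets = gb$bucket, snps = snps)
}

#' Cohort-wide gene-level scores from a dosage matrix
#'
#' Vectorized individual scoring for a whole cohort: gene x bucket scores
#' (summed over regions) for every subject at once.
#'
#' @param dosage_matrix SNP x subject matrix from [read_dosage_tsv()] or
#'   [read_genotypes_vcf()].
#' @inheritParams compute_pre
#' @return List with `scores` (a dense (gene, bucket) x subject matrix),
#'   `genes` and `buckets` (row annotations), and `subjects`.
#' @export
cohort_pre <- function(dosage_matrix, region_snps, catalogue, totals = NULL,
                       eqtl = NULL, impute_missing = c("one", "zero")) {
  impute_missing <- match.arg(impute_missing)
  wm <- ww_matrix(region_snps, catalogue, totals = totals, eqtl = eqtl)
  D <- matrix(if (impute_missing == "one") 1 else 0,
              nrow = length(wm$snps), ncol = ncol(dosage_matrix),
              dimnames = list(wm$snps, colnames(dosage_matrix)))
  have <- intersect(wm$snps, rownames(dosage_matrix))
  dd <- dosage_matrix[have, , drop = FALSE]
  dd[is.na(dd)] <- if (impute_missing == "one") 1 else 0
  D[have, ] <- dd
  S <- as.matrix(wm$W %*% D)
  list(scores = S, genes = wm$genes, buckets = wm$buckets,
       subjects = colnames(dosage_matrix))
}

#' Per-subject risk network metrics
#'
#' Thresholds one subject's gene-level scores in one bucket at the `q`-th
#' percentile of that subject's own score distribution (strictly positive,
#' strictly above the cutoff — the same selection rule as at population
#' level) and measures the induced subnetwork of the cell interactome.
#'
#' @param gene_scores named numeric vector gene -> score for one subject and
#'   bucket (aggregated over regions).
#' @param interactome the bucket's `cell_interactome`.
#' @param q percentile threshold (default 25, the headline setting).
#' @param min_lcc_nodes eligibility threshold (default 15).
#' @return One-row `data.table` of metrics; all-zero score vectors yield
#'   zeroed metrics flagged ineligible.
#' @export
subject_network <- function(gene_scores, interactome, q = 25,
                            min_lcc_nodes = 15) {
  sel <- select_high_pre(gene_scores, q = q)
  if (!length(sel))
    return(data.table(n_selected = 0L, n_nodes = 0L, n_edges = 0L,
                      lcc_nodes = 0L, lcc_edges = 0L, eligible = FALSE))
  sub <- extract_subnetwork(interactome, sel, min_lcc_nodes = min_lcc_nodes)
  m <- sub$metrics
  data.table(n_selected = length(sel), n_nodes = m$n_nodes,
             n_edges = m$n_edges, lcc_nodes = m$lcc_nodes,
             lcc_edges = m$lcc_edges, eligible = m$eligible)
}

#' Risk network metrics for every subject in a cohort
#'
#' @param cohort result of [cohort_pre()].
#' @param interactomes named list bucket -> `cell_interactome`; metrics are
#'   computed for each bucket present in both the scores and this list.
#' @inheritParams subject_network
#' @return `data.table` with one row per (subject, bucket) and the metric
#'   columns of [subject_network()].
#' @export
cohort_networks <- function(cohort, interactomes, q = 25,
                            min_lcc_nodes = 15) {
  buckets <- intersect(unique(cohort$buckets), names(interactomes))
  gis <- lapply(interactomes[buckets], function(ci) graph_index(as_graph(ci)))
  rows <- vector("list", length(cohort$subjects) * length(buckets))
  ri <- 0L
  for (b in buckets) {
    in_b <- cohort$buckets == b
    genes_b <- cohort$genes[in_b]
    gi <- gis[[b]]
    gene_idx <- match(genes_b, gi$names)  # NA = gene absent from interactome
    for (si in seq_along(cohort$subjects)) {
      v <- cohort$scores[in_b, si]
      pos <- v > 0
      sel_idx <- integer(0)
      n_sel <- 0L
      if (any(pos)) {
        cut <- pre_percentile_cutoff(v, q)
        keep <- v > cut & pos
        n_sel <- sum(keep)
        sel_idx <- gene_idx[keep]
        sel_idx <- sel_idx[!is.na(sel_idx)]
      }
      m <- induced_metrics(gi, sel_idx)
      ri <- ri + 1L
      rows[[ri]] <- data.table(
        subject_id = cohort$subjects[si], bucket = b, n_selected = n_sel,
        n_nodes = m$n_nodes, n_edges = m$n_edges, lcc_nodes = m$lcc_nodes,
        lcc_edges = m$lcc_edges, eligible = m$lcc_nodes > min_lcc_nodes)
    }
  }
  rbindlist(rows)
}

#' Percentile rank of each subject within the cohort
#'
#' `100 x (number of subjects with value <= this subject's value) / cohort
#' size`, so the top subject sits at the 100th percentile and ties share the
#' higher rank.
#'
#' @param values numeric metric values, one per subject.
#' @return Numeric vector of ranks in \[0, 100\], same order as `values`.
#' @export
percentile_rank <- function(values) {
  n <- length(values)
  if (n < 2) stop("percentile_rank: need at least 2 subjects", call. = FALSE)
  100 * data.table::frank(values, ties.method = "max") / n
}

#' Compare a network metric between cases and controls
#'
#' One-sided Mann-Whitney U test (normal approximation with tie correction)
#' of the alternative that cases carry stochastically larger values than
#' controls — the directional hypothesis that risk networks are more
#' connected in affected subjects.
#'
#' @param values numeric metric (e.g. LCC edge count), one per subject.
#' @param status character/factor of `"case"` / `"control"` per subject.
#' @return List: `statistic` (U), `p_value`, `median_case`,
#'   `median_control`, `n_case`, `n_control`, `direction`.
#' @export
case_control_compare <- function(values, status) {
  status <- as.character(status)
  cases <- values[status == "case"]
  ctrls <- values[status == "control"]
  if (!length(cases) || !length(ctrls))
    stop("case_control_compare: both groups must be non-empty", call. = FALSE)
  wt <- stats::wilcox.test(cases, ctrls, alternative = "greater",
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_case = stats::median(cases),
       median_control = stats::median(ctrls),
       n_case = length(cases), n_control = length(ctrls),
       direction = if (stats::median(cases) >= stats::median(ctrls))
         "cases_higher" else "controls_higher")
}
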
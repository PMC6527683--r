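#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates every
#' input the pipeline consumes — tiered effect lists, LD proxies, a
#' regulatory feature catalogue, cell bucket and feature class maps, a
#' protein interactome, per-subject dosages and cell-sorted expression
#' counts — with planted, parameterized signal: activating (PEX) features
#' concentrated on designated causal genes in one signal bucket, a denser
#' planted module among those genes in the interactome, case-shifted risk
#' allele frequencies at causal-region SNPs, and expression tracking each
#' bucket's own scores.
#'
#' @param n_regions association regions per evidence tier (default 20).
#' @param snps_per_region SNPs (lead + LD proxies) per region (default 5).
#' @param n_genes size of the gene universe (default 200); regions tile it
#'   in contiguous blocks.
#' @param buckets cell bucket labels (default `c("T", "B", "M")`).
#' @param signal_bucket the bucket carrying planted regulatory signal
#'   (default `"T"`); all other buckets are background-only.
#' @param causal_gene_fraction fraction of genes designated causal
#'   (default 0.15).
#' @param pex_enrichment ratio of the PEX-feature rate on causal genes
#'   (signal bucket, GW tier) to the background rate (default 10).
#' @param feature_rate mean number of background features per
#'   (SNP, gene, bucket) combination (default 0.6).
#' @param geom_p geometric-distribution parameter for per-feature experiment
#'   counts, drawn as `1 + rgeom(geom_p)` — heavy-tailed like public
#'   regulatory catalogues (default 0.5).
#' @param ppi_nodes interactome size (default 200, the gene universe).
#'   With the default, every interactome node is a scored gene, so a score
#'   -based selection in a bucket without planted signal is exchangeable
#'   with a uniform node draw and the enrichment test is calibrated there.
#'   Values above `n_genes` add anonymous proteins; score-based selections
#'   then over-represent the dense planted module relative to whole
#'   -interactome draws and the no-signal buckets are anti-conservative.
#' @param background_edge_prob Erdos-Renyi background edge probability
#'   (default 0.05).
#' @param planted_module_size causal genes carrying the planted module
#'   (default 30).
#' @param planted_density_multiplier module edge probability as a multiple
#'   of background, capped at 1 (default 5).
#' @param n_subjects cohort size (default 250).
#' @param case_fraction fraction of subjects that are cases (default 0.8,
#'   i.e. 200 cases / 50 controls at the default cohort size).
#' @param case_dosage_shift additive risk-allele frequency shift in cases at
#'   causal-region SNPs (default 0.15).
#' @param expression_noise_sd biological coefficient of variation of the
#'   negative-binomial expression counts (default 0.3).
#' @param n_samples_per_bucket expression samples per bucket (default 8).
#' @param tiers evidence tiers to generate (default GW, SR, NR; planted
#'   signal goes to GW only).
#' @param seed integer seed; every generated table is byte-identical given
#'   the same config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_regions = 20, snps_per_region = 5, n_genes = 200,
                       buckets = c("T", "B", "M"), signal_bucket = "T",
                       causal_gene_fraction = 0.15, pex_enrichment = 10,
                       feature_rate = 0.6, geom_p = 0.5,
                       ppi_nodes = 200, background_edge_prob = 0.05,
                       planted_module_size = 30,
                       planted_density_multiplier = 5,
                       n_subjects = 250, case_fraction = 0.8,
                       case_dosage_shift = 0.15,
                       expression_noise_sd = 0.3, n_samples_per_bucket = 8,
                       tiers = c("GW", "SR", "NR"), seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("causal_gene_fraction", "case_fraction", "case_dosage_shift",
              "background_edge_prob", "geom_p"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("sim_config: ", p, " must lie in [0, 1]", call. = FALSE)
  n_causal <- round(causal_gene_fraction * n_genes)
  if (n_causal > n_genes)
    stop("sim_config: more causal genes than genes", call. = FALSE)
  if (planted_module_size > n_causal)
    stop("sim_config: planted_module_size exceeds the causal gene count",
         call. = FALSE)
  if (planted_module_size > ppi_nodes)
    stop("sim_config: planted_module_size exceeds ppi_nodes", call. = FALSE)
  if (planted_density_multiplier < 1)
    stop("sim_config: planted_density_multiplier must be >= 1", call. = FALSE)
  if (!signal_bucket %in% buckets)
    stop("sim_config: signal_bucket must be one of buckets", call. = FALSE)
  cfg$n_causal <- n_causal
  structure(cfg, class = "sim_config")
}

# Deterministic gene universe shared by all generator stages: names, the
# region block each gene belongs to, the causal set and the planted module.
sim_genes <- function(cfg) {
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  gpr <- ceiling(cfg$n_genes / cfg$n_regions)
  region_of <- ((seq_len(cfg$n_genes) - 1L) %/% gpr) + 1L
  with_seed(cfg$seed, {
    causal <- sort(sample.int(cfg$n_genes, cfg$n_causal))
    module <- sort(sample(causal, cfg$planted_module_size))
  })
  list(genes = genes, region_of = region_of,
       causal_genes = genes[causal], module_genes = genes[module])
}

sim_class_labels <- list(
  PEX = c("promoter", "enhancer", "tfbs", "protein_binding", "dhs",
          "h3k27ac", "h3k4me3"),
  R = c("h3k27me3", "h3k9me3", "repressed", "polycomb"),
  ZQI = c("quiescent", "insulator", "ctcf"))

#' Simulate effect lists, LD proxies and a regulatory feature catalogue
#'
#' Generates, for each configured tier, one lead effect per region (one in
#' five regions gets a second independent effect) with LD proxies, and a
#' feature catalogue linking every region SNP to the genes of its region in
#' every bucket. Causal genes receive activating (PEX) features at
#' `pex_enrichment` times the background rate — in the signal bucket and for
#' GW-tier SNPs only. Experiment counts are geometric (minimum 1). A few
#' cancer-line rows are included to exercise the exclusion path, and a small
#' eQTL table marks a subset of causal genes in the signal bucket.
#'
#' @param cfg a [sim_config()].
#' @return List: `effects` and `proxies` (named lists tier -> table),
#'   `catalogue` (raw, unclassified), `bucket_map`, `class_map`, `eqtl`,
#'   plus the gene universe fields of the internal layout (`genes`,
#'   `region_of`, `causal_genes`, `module_genes`).
#' @export
simulate_catalogue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gl <- sim_genes(cfg)
  with_seed(cfg$seed + 1L, {
    effects <- list()
    proxies_by_tier <- list()
    snp_meta <- list()  # snp_id, region, tier
    snp_n <- 0L
    for (tier in cfg$tiers) {
      rows <- list()
      proxies <- list()
      for (r in seq_len(cfg$n_regions)) {
        n_lead <- if (r %% 5L == 0L) 2L else 1L
        for (l in seq_len(n_lead)) {
          snp_n <- snp_n + 1L
          lead <- sprintf("rs%s%04d", tier, snp_n)
          rows[[length(rows) + 1L]] <- data.table(
            snp_id = lead, chrom = as.character((r %% 22L) + 1L),
            pos = r * 100000L + l * 1000L,
            risk_allele = sample(c("A", "C", "G", "T"), 1L),
            tier = tier, region_id = r)
          snp_meta[[length(snp_meta) + 1L]] <-
            data.table(snp_id = lead, region = r, tier = tier)
          n_px <- cfg$snps_per_region - 1L
          if (n_px > 0L) {
            px <- sprintf("rs%s%04dp%d", tier, snp_n, seq_len(n_px))
            proxies[[length(proxies) + 1L]] <- data.table(
              lead_snp = lead, proxy_snp = px,
              r2 = round(stats::runif(n_px, 0.2, 1), 3))
            snp_meta[[length(snp_meta) + 1L]] <-
              data.table(snp_id = px, region = r, tier = tier)
          }
        }
      }
      effects[[tier]] <- rbindlist(rows)
      proxies_by_tier[[tier]] <- rbindlist(proxies)
    }
    proxies <- proxies_by_tier
    snp_meta <- rbindlist(snp_meta)

    # catalogue rows: (snp, gene-in-region, bucket) combos, Poisson feature
    # counts per class, with the PEX rate inflated on causal x signal x GW
    gene_dt <- data.table(gene = gl$genes, region = gl$region_of,
                          causal = gl$genes %in% gl$causal_genes)
    combos <- merge(snp_meta, gene_dt, by = "region", allow.cartesian = TRUE)
    combos <- combos[rep(seq_len(nrow(combos)), length(cfg$buckets))]
    combos[, bucket := rep(cfg$buckets, each = nrow(combos) / length(cfg$buckets))]
    base <- cfg$feature_rate
    rates <- list(PEX = 0.35 * base, R = 0.35 * base, ZQI = 0.30 * base)
    feat_rows <- list()
    for (cl in names(rates)) {
      lam <- rep(rates[[cl]], nrow(combos))
      if (cl == "PEX")
        lam <- ifelse(combos$causal & combos$bucket == cfg$signal_bucket &
                        combos$tier == "GW",
                      rates$PEX * cfg$pex_enrichment, lam)
      k <- stats::rpois(nrow(combos), lam)
      idx <- rep(seq_len(nrow(combos)), k)
      if (!length(idx)) next
      nf <- length(idx)
      feat_rows[[cl]] <- data.table(
        snp_id = combos$snp_id[idx],
        feature_type = sample(sim_class_labels[[cl]], nf, replace = TRUE),
        cell_raw = paste0(combos$bucket[idx], "_cell_",
                          sample.int(2L, nf, replace = TRUE)),
        n_experiments = 1L + stats::rgeom(nf, cfg$geom_p),
        target_gene = combos$gene[idx])
    }
    catalogue <- rbindlist(feat_rows)
    setorder(catalogue, snp_id, target_gene, cell_raw, feature_type,
             n_experiments)
    catalogue[, feature_id := sprintf("feat%06d", .I)]
    # a few excluded cancer-line rows to exercise the bucketing filter
    n_cx <- 5L
    cancer <- data.table(
      snp_id = catalogue$snp_id[seq_len(min(n_cx, nrow(catalogue)))],
      feature_type = "enhancer", cell_raw = "cancer_line_K562",
      n_experiments = 1L,
      target_gene = catalogue$target_gene[seq_len(min(n_cx, nrow(catalogue)))])
    cancer[, feature_id := sprintf("featCX%04d", .I)]
    catalogue <- rbindlist(list(catalogue, cancer), use.names = TRUE)
    data.table::setcolorder(catalogue, c("snp_id", "feature_id",
                                         "feature_type", "cell_raw",
                                         "n_experiments", "target_gene"))

    bucket_map <- stats::setNames(
      rep(cfg$buckets, each = 2L),
      paste0(rep(cfg$buckets, each = 2L), "_cell_", 1:2))
    bucket_map <- c(bucket_map, cancer_line_K562 = "EXCLUDED")

    eq_genes <- utils::head(gl$causal_genes, 5L)
    eq_snps <- snp_meta[tier == "GW"][match(
      gene_dt[gene %in% eq_genes]$region, region)]$snp_id
    eqtl <- data.table(snp_id = eq_snps, target_gene = eq_genes,
                       bucket = cfg$signal_bucket, effect_sign = 1L)

    c(list(effects = effects, proxies = proxies, catalogue = catalogue,
           bucket_map = bucket_map, class_map = default_class_map(),
           eqtl = eqtl, snp_meta = snp_meta), gl)
  })
}

#' Simulate a protein interactome with a planted module
#'
#' Erdos-Renyi background over the gene universe plus anonymous proteins,
#' with the edge probability among the planted-module genes multiplied by
#' `planted_density_multiplier` (capped at 1). A multiplier of 1 gives a
#' pure Erdos-Renyi graph.
#'
#' @param cfg a [sim_config()].
#' @return Undirected simple [igraph::graph] whose vertices carry gene /
#'   protein names.
#' @export
simulate_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gl <- sim_genes(cfg)
  n_extra <- max(0L, cfg$ppi_nodes - cfg$n_genes)
  nodes <- c(gl$genes, if (n_extra) sprintf("p%03d", seq_len(n_extra)))
  with_seed(cfg$seed + 2L, {
    g <- igraph::sample_gnp(length(nodes), cfg$background_edge_prob,
                            directed = FALSE)
    igraph::V(g)$name <- nodes
    mod_idx <- match(gl$module_genes, nodes)
    pairs <- t(utils::combn(mod_idx, 2L))
    # regenerate module-internal pairs at the planted density
    q <- min(1, cfg$background_edge_prob * cfg$planted_density_multiplier)
    existing <- igraph::get_edge_ids(g, t(pairs))
    g <- igraph::delete_edges(g, existing[existing > 0])
    on <- stats::runif(nrow(pairs)) < q
    if (any(on))
      g <- igraph::add_edges(g, t(pairs[on, , drop = FALSE]))
    igraph::simplify(g)
  })
}

#' Simulate a genotyped cohort with expression profiles
#'
#' Control dosages are Binomial(2, f) with per-SNP risk-allele frequencies
#' drawn uniformly in \[0.2, 0.4\]; in cases the frequency is shifted up by
#' `case_dosage_shift` at SNPs of causal regions (GW tier). Expression
#' counts are negative binomial with genewise means increasing in the
#' gene's population score for the profiled bucket, with per-sample library
#' size factors, so matched score/expression bucket pairs correlate and
#' mismatched pairs do not.
#'
#' @param cfg a [sim_config()].
#' @param sim optional result of [simulate_catalogue()] (recomputed from
#'   `cfg` when omitted; both paths are deterministic given the seed).
#' @return List: `dosages` (SNP x subject matrix), `status` (named
#'   case/control vector), `counts` (gene x sample matrix),
#'   `sample_buckets` (named sample -> bucket vector), `gene_pre` (the
#'   population gene x bucket score table used to drive expression).
#' @export
simulate_cohort <- function(cfg, sim = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(sim)) sim <- simulate_catalogue(cfg)
  cat_cl <- classify_catalogue(sim$catalogue, sim$class_map, sim$bucket_map,
                               quiet = TRUE)
  region_snps <- expand_ld(sim$effects$GW, sim$proxies$GW, r2_min = 0.5)
  pre <- compute_pre(region_snps, cat_cl)
  gene_pre <- aggregate_gene_pre(pre)

  gl <- sim_genes(cfg)
  causal_regions <- unique(gl$region_of[gl$genes %in% gl$causal_genes])
  gw_snps <- sim$snp_meta[tier == "GW"]
  with_seed(cfg$seed + 3L, {
    n_case <- round(cfg$n_subjects * cfg$case_fraction)
    subjects <- sprintf("S%04d", seq_len(cfg$n_subjects))
    status <- stats::setNames(
      sample(rep(c("case", "control"),
                 c(n_case, cfg$n_subjects - n_case))), subjects)
    f <- stats::runif(nrow(gw_snps), 0.2, 0.4)
    shifted <- gw_snps$region %in% causal_regions
    D <- matrix(0, nrow(gw_snps), cfg$n_subjects,
                dimnames = list(gw_snps$snp_id, subjects))
    for (si in seq_len(cfg$n_subjects)) {
      fs <- f
      if (status[si] == "case")
        fs[shifted] <- pmin(fs[shifted] + cfg$case_dosage_shift, 0.95)
      D[, si] <- stats::rbinom(nrow(gw_snps), 2L, fs)
    }

    # expression: NB counts with means tied to the bucket's own scores
    base_mu <- 50
    size <- 1 / max(cfg$expression_noise_sd^2, 1e-8)
    sample_buckets <- stats::setNames(
      rep(cfg$buckets, each = cfg$n_samples_per_bucket),
      paste0(rep(cfg$buckets, each = cfg$n_samples_per_bucket), "_s",
             seq_len(cfg$n_samples_per_bucket)))
    counts <- matrix(0L, cfg$n_genes, length(sample_buckets),
                     dimnames = list(gl$genes, names(sample_buckets)))
    lib <- exp(stats::rnorm(length(sample_buckets), 0, 0.3))
    for (b in cfg$buckets) {
      gb <- gene_pre[bucket == b]
      v <- stats::setNames(rep(0, cfg$n_genes), gl$genes)
      v[gb$gene] <- gb$pre
      z <- v / max(stats::sd(v), 1e-12)
      mu_g <- base_mu * exp(pmin(z, 5))
      for (s in which(sample_buckets == b))
        counts[, s] <- stats::rnbinom(cfg$n_genes, mu = mu_g * lib[s],
                                      size = size)
    }
    list(dosages = D, status = status, counts = counts,
         sample_buckets = sample_buckets, gene_pre = gene_pre)
  })
}

#' Write a complete synthetic input directory
#'
#' Materializes a simulated data set as the tab-separated / YAML files the
#' readers of this package consume, plus a `manifest.json` recording the
#' configuration and seed.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param cohort also write dosages, status and expression counts
#'   (default `TRUE`).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_fixture_dir <- function(cfg, dir, cohort = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_catalogue(cfg)
  ppi <- simulate_ppi(cfg)
  paths <- c()
  for (tier in names(sim$effects)) {
    p <- file.path(dir, sprintf("effects_%s.tsv", tier))
    write_effects(sim$effects[[tier]], p)
    paths[paste0("effects_", tier)] <- p
  }
  for (tier in names(sim$proxies)) {
    p <- file.path(dir, sprintf("proxies_%s.tsv", tier))
    write_ld_proxies(sim$proxies[[tier]], p)
    paths[paste0("proxies_", tier)] <- p
  }
  write_catalogue(sim$catalogue, paths["catalogue"] <- file.path(dir, "catalogue.tsv"))
  write_eqtl(sim$eqtl, paths["eqtl"] <- file.path(dir, "eqtl.tsv"))
  write_ppi(ppi, paths["ppi"] <- file.path(dir, "ppi.tsv"))
  yaml::write_yaml(as.list(sim$bucket_map),
                   paths["bucket_map"] <- file.path(dir, "bucket_map.yaml"))
  yaml::write_yaml(as.list(sim$class_map),
                   paths["class_map"] <- file.path(dir, "class_map.yaml"))
  if (cohort) {
    ch <- simulate_cohort(cfg, sim)
    dd <- data.table(subject_id = colnames(ch$dosages), t(ch$dosages))
    write_tsv(dd, paths["dosages"] <- file.path(dir, "dosages.tsv"))
    write_tsv(data.table(subject_id = names(ch$status), status = ch$status),
              paths["status"] <- file.path(dir, "status.tsv"))
    write_tsv(data.table(gene = rownames(ch$counts), ch$counts),
              paths["counts"] <- file.path(dir, "counts.tsv"))
    write_tsv(data.table(sample = names(ch$sample_buckets),
                         bucket = unname(ch$sample_buckets)),
              paths["sample_buckets"] <- file.path(dir, "sample_buckets.tsv"))
  }
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   files = as.list(paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths["manifest"] <- file.path(dir, "manifest.json")
  invisible(paths)
}
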
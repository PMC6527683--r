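#' Read a tiered SNP effect list
#'
#' Parses a tab-separated list of independent association effects for one
#' evidence tier: `GW` (genome-wide significant), `SR` (statistically
#' replicated but sub-genome-wide) or `NR` (non-replicated). Each effect is a
#' lead SNP assigned to an association region; several independent effects may
#' share a region.
#'
#' Required columns: `snp_id`, `chrom`, `pos`, `risk_allele`, `region_id`.
#' Positions are 1-based; a `chr` prefix on `chrom` is stripped. Lines starting
#' with `#` are ignored. Gzipped files are accepted.
#'
#' @param path path to the tab-separated effect list (optionally gzipped).
#' @param tier one of `"GW"`, `"SR"`, `"NR"`.
#' @param quiet suppress the effect/region count message.
#' @return A `data.table` with columns `snp_id`, `chrom`, `pos`,
#'   `risk_allele`, `tier`, `region_id`, carrying attributes `n_effects` and
#'   `n_regions`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("snp_id\tchrom\tpos\trisk_allele\tregion_id",
#'              "rs1\t1\t100\tA\t1", "rs2\t1\t200\tG\t1", "rs3\t2\t50\tT\t5"),
#'            f)
#' eff <- read_effect_list(f, "GW")
#' attr(eff, "n_regions")  # 2
#' @export
read_effect_list <- function(path, tier = c("GW", "SR", "NR"), quiet = FALSE) {
  tier <- match.arg(tier)
  dt <- read_tsv(path)
  require_columns(dt, c("snp_id", "chrom", "pos", "risk_allele", "region_id"),
                  "effect list")
  dt <- dt[, .(snp_id = as.character(snp_id),
               chrom = sub("^chr", "", as.character(chrom)),
               pos = as.integer(pos),
               risk_allele = toupper(as.character(risk_allele)),
               tier = tier,
               region_id = as.integer(region_id))]
  if (anyNA(dt$region_id))
    stop("effect list: region_id missing or non-integer for some rows",
         call. = FALSE)
  if (anyDuplicated(dt$snp_id)) {
    dup <- unique(dt$snp_id[duplicated(dt$snp_id)])
    stop("effect list: duplicate snp_id within tier ", tier, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  n_eff <- nrow(dt)
  n_reg <- length(unique(dt$region_id))
  data.table::setattr(dt, "n_effects", n_eff)
  data.table::setattr(dt, "n_regions", n_reg)
  if (!quiet)
    message(sprintf("%s tier: %d effects in %d regions", tier, n_eff, n_reg))
  dt[]
}

#' Read an LD proxy table
#'
#' @param path tab-separated file with columns `lead_snp`, `proxy_snp`, `r2`.
#' @return `data.table` with those columns; duplicate (lead, proxy) pairs are
#'   collapsed to their maximum r-squared.
#' @export
read_ld_proxies <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, c("lead_snp", "proxy_snp", "r2"), "LD proxy table")
  dt <- dt[, .(lead_snp = as.character(lead_snp),
               proxy_snp = as.character(proxy_snp),
               r2 = as.numeric(r2))]
  if (any(dt$r2 < 0 | dt$r2 > 1, na.rm = TRUE) || anyNA(dt$r2))
    stop("LD proxy table: r2 must lie in [0, 1]", call. = FALSE)
  dt <- dt[, .(r2 = max(r2)), by = .(lead_snp, proxy_snp)]
  dt[]
}

#' Expand lead SNPs to LD sets per region
#'
#' Builds, for each association region, the set of SNPs carrying its signal:
#' every lead effect in the region plus every proxy in linkage disequilibrium
#' with a lead at `r2 >= r2_min`. Leads always count as their own proxies
#' (r-squared 1), so each region's set is non-empty at any threshold.
#' Raising `r2_min` can only shrink the sets.
#'
#' @param effects effect table from [read_effect_list()].
#' @param proxies proxy table from [read_ld_proxies()], or `NULL` for leads
#'   only.
#' @param r2_min minimum r-squared in (0, 1]; the conventional choices are
#'   0.1, 0.5 (main analysis) and 0.8.
#' @return Named list mapping region id to a character vector of SNP ids, with
#'   attribute `n_skipped_proxies` counting proxy rows whose lead is absent
#'   from `effects` (each such row is skipped with a warning).
#' @export
expand_ld <- function(effects, proxies = NULL, r2_min = 0.5) {
  stopifnot(is.numeric(r2_min), length(r2_min) == 1L, r2_min > 0, r2_min <= 1)
  eff <- as.data.table(effects)
  require_columns(eff, c("snp_id", "region_id"), "effects")
  sets <- split(eff$snp_id, eff$region_id)
  n_skip <- 0L
  if (!is.null(proxies) && nrow(proxies)) {
    px <- as.data.table(proxies)
    require_columns(px, c("lead_snp", "proxy_snp", "r2"), "proxies")
    unknown <- !(px$lead_snp %in% eff$snp_id)
    n_skip <- sum(unknown)
    if (n_skip) {
      warning(sprintf("expand_ld: skipping %d proxy row(s) with unknown lead SNP",
                      n_skip), call. = FALSE)
      px <- px[!unknown]
    }
    px <- px[r2 >= r2_min]
    if (nrow(px)) {
      px <- merge(px, eff[, .(lead_snp = snp_id, region_id)],
                  by = "lead_snp", allow.cartesian = TRUE)
      add <- split(px$proxy_snp, px$region_id)
      for (r in names(add))
        sets[[r]] <- union(sets[[r]], add[[r]])
    }
  }
  sets <- lapply(sets, function(s) sort(unique(s)))
  attr(sets, "n_skipped_proxies") <- n_skip
  sets
}

#' Default regulatory feature class map
#'
#' Maps raw assay/annotation labels to the three broad regulatory classes:
#' `PEX` (promoter/enhancer/transcription-activating evidence, positive
#' weight), `R` (repressive evidence, negative weight) and `ZQI`
#' (inert/quiescent, zero weight). Matching is case-insensitive on the whole
#' label. Labels absent from the map fall back to `ZQI` (lenient) or raise an
#' error (strict), see [load_catalogue()]. The shipped assignments follow the
#' usual reading of chromatin-state and binding annotations and are fully
#' overridable via a YAML/JSON config.
#'
#' @return Named character vector label -> class.
#' @export
default_class_map <- function() {
  c(promoter = "PEX", enhancer = "PEX", tfbs = "PEX",
    transcription_factor_binding_site = "PEX", protein_binding = "PEX",
    dhs = "PEX", dnase = "PEX", open_chromatin = "PEX",
    h3k4me1 = "PEX", h3k4me3 = "PEX", h3k27ac = "PEX", h3k9ac = "PEX",
    h3k36me3 = "PEX", transcription = "PEX", tss = "PEX", eqtl = "PEX",
    h3k27me3 = "R", h3k9me3 = "R", repressed = "R", repressor = "R",
    polycomb = "R", heterochromatin = "R",
    quiescent = "ZQI", insulator = "ZQI", ctcf = "ZQI", unknown = "ZQI")
}

#' Read a key-value config map (YAML or JSON)
#'
#' Used for the feature-class map and the cell-type bucket map.
#'
#' @param path `.yaml`/`.yml` or `.json` file of scalar key: value pairs.
#' @return Named character vector.
#' @export
read_map_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  out <- unlist(x)
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("config map must be named key: value pairs: ", path, call. = FALSE)
  out
}

valid_buckets <- c("B", "T", "M", "CNS", "Th1", "Th2", "Th17", "Treg", "L",
                   "EXCLUDED")

#' Load and classify a regulatory feature catalogue
#'
#' Reads the SNP -> feature -> target-gene evidence table (a pre-fetched
#' RegulomeDB-style export), assigns each row a regulatory class from its
#' assay label and a cell bucket from its source cell label, and drops rows
#' from excluded cells (cancer lines and anything explicitly mapped to
#' `EXCLUDED`).
#'
#' Required columns: `snp_id`, `feature_id`, `feature_type`, `cell_raw`,
#' `n_experiments`, `target_gene`.
#'
#' @param path tab-separated catalogue (optionally gzipped).
#' @param class_map named vector feature_type -> {PEX, ZQI, R}; matched
#'   case-insensitively. Defaults to [default_class_map()].
#' @param bucket_map named vector cell_raw -> bucket, buckets drawn from
#'   B, T, M, CNS, Th1, Th2, Th17, Treg, L, EXCLUDED.
#' @param strict if `TRUE`, an unmapped cell label is an error listing the
#'   offending labels; if `FALSE` (default) such rows are bucketed to
#'   `EXCLUDED` with a warning. Unmapped feature types always fall back to
#'   `ZQI` (zero weight) in lenient mode and error in strict mode.
#' @param quiet suppress the dropped-row message.
#' @return `data.table` with columns `snp_id`, `feature_id`, `feature_type`,
#'   `reg_class`, `cell_raw`, `bucket`, `n_experiments`, `target_gene`;
#'   attribute `n_dropped` records how many rows were excluded.
#' @export
load_catalogue <- function(path, class_map = default_class_map(),
                           bucket_map, strict = FALSE, quiet = FALSE) {
  dt <- read_tsv(path)
  classify_catalogue(dt, class_map = class_map, bucket_map = bucket_map,
                     strict = strict, quiet = quiet)
}

#' Classify an in-memory catalogue table
#'
#' Same contract as [load_catalogue()] but starting from a data frame, so
#' simulated catalogues take the identical code path as files on disk.
#'
#' @inheritParams load_catalogue
#' @param dt data frame with the catalogue columns.
#' @export
classify_catalogue <- function(dt, class_map = default_class_map(),
                               bucket_map, strict = FALSE, quiet = FALSE) {
  dt <- as.data.table(dt)
  require_columns(dt, c("snp_id", "feature_id", "feature_type", "cell_raw",
                        "n_experiments", "target_gene"), "catalogue")
  dt <- dt[, .(snp_id = as.character(snp_id),
               feature_id = as.character(feature_id),
               feature_type = as.character(feature_type),
               cell_raw = as.character(cell_raw),
               n_experiments = as.integer(n_experiments),
               target_gene = as.character(target_gene))]
  if (any(dt$n_experiments < 1L, na.rm = TRUE) || anyNA(dt$n_experiments))
    stop("catalogue: n_experiments must be a positive integer", call. = FALSE)

  names(class_map) <- tolower(names(class_map))
  cls <- unname(class_map[tolower(dt$feature_type)])
  if (anyNA(cls)) {
    if (strict)
      stop("catalogue: unmapped feature_type label(s): ",
           paste(unique(dt$feature_type[is.na(cls)]), collapse = ", "),
           call. = FALSE)
    cls[is.na(cls)] <- "ZQI"
  }
  bad <- setdiff(unique(cls), c("PEX", "ZQI", "R"))
  if (length(bad))
    stop("class map values must be PEX, ZQI or R; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  dt[, reg_class := cls]

  bkt <- unname(bucket_map[dt$cell_raw])
  if (anyNA(bkt)) {
    labs <- unique(dt$cell_raw[is.na(bkt)])
    if (strict)
      stop("catalogue: unmapped cell label(s): ",
           paste(labs, collapse = ", "), call. = FALSE)
    warning("catalogue: bucketing unmapped cell label(s) to EXCLUDED: ",
            paste(labs, collapse = ", "), call. = FALSE)
    bkt[is.na(bkt)] <- "EXCLUDED"
  }
  badb <- setdiff(unique(bkt), valid_buckets)
  if (length(badb))
    stop("bucket map values must be one of ",
         paste(valid_buckets, collapse = ", "), "; found: ",
         paste(badb, collapse = ", "), call. = FALSE)
  dt[, bucket := bkt]
  n_drop <- sum(dt$bucket == "EXCLUDED")
  if (n_drop && !quiet)
    message(sprintf("catalogue: dropped %d row(s) from excluded cells", n_drop))
  dt <- dt[bucket != "EXCLUDED"]
  data.table::setcolorder(dt, c("snp_id", "feature_id", "feature_type",
                                "reg_class", "cell_raw", "bucket",
                                "n_experiments", "target_gene"))
  data.table::setattr(dt, "n_dropped", n_drop)
  dt[]
}

#' Read eQTL records
#'
#' Expression-QTL evidence (SNP, target gene, cell bucket, direction of the
#' risk-allele effect on expression) that can be folded into the scoring as
#' single-experiment pseudo-features, see [compute_pre()].
#'
#' @param path tab-separated file with columns `snp_id`, `target_gene`,
#'   `bucket`, `effect_sign` (+1 or -1).
#' @return Validated `data.table`.
#' @export
read_eqtl <- function(path) {
  dt <- read_tsv(path)
  require_columns(dt, c("snp_id", "target_gene", "bucket", "effect_sign"),
                  "eQTL table")
  dt <- dt[, .(snp_id = as.character(snp_id),
               target_gene = as.character(target_gene),
               bucket = as.character(bucket),
               effect_sign = as.integer(effect_sign))]
  if (!all(dt$effect_sign %in% c(-1L, 1L)))
    stop("eQTL table: effect_sign must be +1 or -1", call. = FALSE)
  dt[]
}

#' Load a protein interactome edge list
#'
#' Two-column tab- or whitespace-separated edge list, optional header.
#' Self-loops are removed and edges deduplicated regardless of orientation.
#'
#' @param path edge list file (optionally gzipped).
#' @param header `"auto"` (default: first line treated as a header when its
#'   tokens look like column names such as `protein_a`/`node1`/`from`),
#'   `TRUE`, or `FALSE`.
#' @param quiet suppress the node/edge count message.
#' @return An undirected, simple [igraph::graph] object.
#' @export
load_ppi <- function(path, header = "auto", quiet = FALSE) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (!quiet) message("interactome: 0 nodes, 0 edges")
    return(g)
  }
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("interactome: expected two columns; offending line(s): ",
         paste(utils::head(which(nf != 2L), 5), collapse = ", "),
         call. = FALSE)
  first <- tolower(parts[[1]])
  is_header <- isTRUE(header) ||
    (identical(header, "auto") &&
       any(first %in% c("protein_a", "protein_b", "node1", "node2", "from",
                        "to", "source", "target", "gene_a", "gene_b",
                        "symbol_a", "symbol_b", "interactor_a")))
  if (is_header) parts <- parts[-1]
  m <- do.call(rbind, parts)
  g <- igraph::graph_from_edgelist(m, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!quiet)
    message(sprintf("interactome: %d nodes, %d edges",
                    igraph::vcount(g), igraph::ecount(g)))
  g
}

#' Write pipeline tables to disk
#'
#' Writers matching each reader, so every table round-trips exactly.
#'
#' @param x table (or, for `write_ppi`, an igraph object).
#' @param path output path (`.tsv`).
#' @return The path, invisibly.
#' @export
write_effects <- function(x, path) write_tsv(
  as.data.table(x)[, .(snp_id, chrom, pos, risk_allele, region_id)], path)

#' @rdname write_effects
#' @export
write_ld_proxies <- function(x, path) write_tsv(
  as.data.table(x)[, .(lead_snp, proxy_snp, r2)], path)

#' @rdname write_effects
#' @export
write_catalogue <- function(x, path) write_tsv(
  as.data.table(x)[, .(snp_id, feature_id, feature_type, cell_raw,
                       n_experiments, target_gene)], path)

#' @rdname write_effects
#' @export
write_eqtl <- function(x, path) write_tsv(
  as.data.table(x)[, .(snp_id, target_gene, bucket, effect_sign)], path)

#' @rdname write_effects
#' @export
write_ppi <- function(x, path) {
  el <- igraph::as_edgelist(x)
  dt <- data.table(protein_a = el[, 1], protein_b = el[, 2])
  write_tsv(dt, path)
}
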
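test_that("effect lists parse with correct effect and region bookkeeping", {
  toy <- data.table(snp_id = c("rs1", "rs2", "rs3"), chrom = c("1", "1", "2"),
                    pos = c(100L, 200L, 300L), risk_allele = c("A", "G", "T"),
                    region_id = c(5L, 5L, 9L))
  f <- write_toy_effects(toy)
  eff <- read_effect_list(f, "GW", quiet = TRUE)
  expect_equal(nrow(eff), 3L)
  expect_equal(attr(eff, "n_effects"), 3L)
  expect_equal(attr(eff, "n_regions"), 2L)
  expect_equal(eff$tier, rep("GW", 3))

  # header-only file
  f2 <- write_toy_effects(toy[0])
  eff2 <- read_effect_list(f2, "SR", quiet = TRUE)
  expect_equal(nrow(eff2), 0L)
  expect_equal(attr(eff2, "n_regions"), 0L)

  # chr prefix stripped, risk allele upper-cased
  toy3 <- copy(toy)[, chrom := paste0("chr", chrom)][, risk_allele := "a"]
  eff3 <- read_effect_list(write_toy_effects(toy3), "GW", quiet = TRUE)
  expect_equal(eff3$chrom, c("1", "1", "2"))
  expect_equal(eff3$risk_allele, rep("A", 3))
})

test_that("effect list validation errors name the problem", {
  toy <- data.table(snp_id = c("rs1", "rs1"), chrom = "1", pos = 1:2,
                    risk_allele = "A", region_id = 1L)
  expect_error(read_effect_list(write_toy_effects(toy), "GW", quiet = TRUE),
               "duplicate snp_id")
  bad <- data.table(snp = "rs1", chrom = "1", pos = 1L, risk_allele = "A",
                    region_id = 1L)
  expect_error(read_effect_list(write_toy_effects(bad), "GW", quiet = TRUE),
               "snp_id")
})

test_that("LD expansion thresholds proxies and keeps leads", {
  eff <- data.table(snp_id = "A", chrom = "1", pos = 1L, risk_allele = "A",
                    tier = "GW", region_id = 1L)
  px <- data.table(lead_snp = c("A", "A"), proxy_snp = c("B", "C"),
                   r2 = c(0.9, 0.4))
  expect_setequal(expand_ld(eff, px, r2_min = 0.5)[["1"]], c("A", "B"))
  expect_setequal(expand_ld(eff, px, r2_min = 0.1)[["1"]], c("A", "B", "C"))
  # no perfect proxies at the r2 = 1 boundary: leads only
  expect_equal(expand_ld(eff, px, r2_min = 1)[["1"]], "A")
  # unknown lead is skipped with a warning and counted
  px2 <- rbind(px, data.table(lead_snp = "Z", proxy_snp = "Q", r2 = 0.99))
  expect_warning(sets <- expand_ld(eff, px2, r2_min = 0.5), "unknown lead")
  expect_equal(attr(sets, "n_skipped_proxies"), 1L)
  expect_setequal(sets[["1"]], c("A", "B"))
})

test_that("LD sets are monotone decreasing in the r2 threshold", {
  for (i in 1:20) {
    set.seed(i)
    eff <- data.table(snp_id = paste0("L", 1:4), chrom = "1",
                      pos = 1:4, risk_allele = "A", tier = "GW",
                      region_id = sample.int(2, 4, replace = TRUE))
    px <- data.table(lead_snp = sample(paste0("L", 1:4), 15, replace = TRUE),
                     proxy_snp = paste0("P", 1:15), r2 = runif(15))
    px <- px[!duplicated(px[, .(lead_snp, proxy_snp)])]
    lo <- expand_ld(eff, px, r2_min = 0.1)
    hi <- expand_ld(eff, px, r2_min = 0.8)
    for (r in names(hi)) expect_true(all(hi[[r]] %in% lo[[r]]))
  }
})

test_that("catalogue classification applies class and bucket maps", {
  raw <- data.table(
    snp_id = c("s1", "s2", "s3", "s4"),
    feature_id = paste0("f", 1:4),
    feature_type = c("enhancer", "weird_assay", "h3k27me3", "enhancer"),
    cell_raw = c("T_cell_1", "T_cell_1", "B_cell_1", "cancer_line"),
    n_experiments = c(3L, 1L, 2L, 5L),
    target_gene = c("g1", "g1", "g2", "g3"))
  bmap <- c(T_cell_1 = "T", B_cell_1 = "B", cancer_line = "EXCLUDED")
  cat_cl <- classify_catalogue(raw, bucket_map = bmap, quiet = TRUE)
  expect_equal(nrow(cat_cl), 3L)                      # cancer row dropped
  expect_equal(attr(cat_cl, "n_dropped"), 1L)
  expect_equal(cat_cl[snp_id == "s1"]$reg_class, "PEX")
  expect_equal(cat_cl[snp_id == "s2"]$reg_class, "ZQI")  # lenient default
  expect_equal(cat_cl[snp_id == "s3"]$reg_class, "R")
  # strict mode surfaces unmapped labels
  expect_error(classify_catalogue(raw, bucket_map = bmap, strict = TRUE,
                                  quiet = TRUE), "weird_assay")
  raw2 <- copy(raw)[, cell_raw := "mystery_cell"][, feature_type := "enhancer"]
  expect_error(classify_catalogue(raw2, bucket_map = bmap, strict = TRUE,
                                  quiet = TRUE), "mystery_cell")
  expect_warning(classify_catalogue(raw2, bucket_map = bmap, quiet = TRUE),
                 "EXCLUDED")
})

test_that("bucketed rows partition the non-excluded input", {
  cfg <- small_sim_config()
  sim <- simulate_catalogue(cfg)
  cl <- classify_catalogue(sim$catalogue, sim$class_map, sim$bucket_map,
                           quiet = TRUE)
  n_excluded <- attr(cl, "n_dropped")
  expect_equal(nrow(cl) + n_excluded, nrow(sim$catalogue))
  expect_false(any(duplicated(cl$feature_id)))
  expect_true(all(cl$bucket != "EXCLUDED"))
})

test_that("PPI loading deduplicates, drops self-loops and detects headers", {
  f <- tempfile()
  writeLines(c("a\tb", "b\ta", "c\tc"), f)
  g <- load_ppi(f, quiet = TRUE)
  expect_equal(igraph::ecount(g), 1L)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))

  f2 <- tempfile()
  writeLines(c("protein_a\tprotein_b", "x\ty"), f2)
  g2 <- load_ppi(f2, quiet = TRUE)
  expect_equal(igraph::ecount(g2), 1L)
  expect_setequal(igraph::V(g2)$name, c("x", "y"))

  f3 <- tempfile(); writeLines(character(), f3)
  expect_equal(igraph::vcount(load_ppi(f3, quiet = TRUE)), 0L)

  f4 <- tempfile(); writeLines(c("a\tb", "a\tb\tc"), f4)
  expect_error(load_ppi(f4, quiet = TRUE), "line")
})

test_that("every table type round-trips through write + read", {
  cfg <- small_sim_config()
  sim <- simulate_catalogue(cfg)

  p <- tempfile(); write_effects(sim$effects$GW, p)
  back <- read_effect_list(p, "GW", quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(sim$effects$GW),
               ignore_attr = TRUE)

  p <- tempfile(); write_ld_proxies(sim$proxies$GW, p)
  expect_equal(as.data.frame(read_ld_proxies(p)),
               as.data.frame(sim$proxies$GW[order(lead_snp, proxy_snp)]),
               ignore_attr = TRUE)

  p <- tempfile(); write_eqtl(sim$eqtl, p)
  expect_equal(as.data.frame(read_eqtl(p)), as.data.frame(sim$eqtl),
               ignore_attr = TRUE)

  g <- simulate_ppi(cfg)
  p <- tempfile(); write_ppi(g, p)
  g2 <- load_ppi(p, quiet = TRUE)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name,
                  igraph::V(g)$name[igraph::degree(g) > 0])

  # gzip input path
  pz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(pz, "wt")
  writeLines(c("snp_id\tchrom\tpos\trisk_allele\tregion_id",
               "rs1\t1\t100\tA\t1"), con); close(con)
  expect_equal(nrow(read_effect_list(pz, "GW", quiet = TRUE)), 1L)
})

test_that("map configs round-trip through YAML and JSON", {
  m <- c(T_cell_1 = "T", B_cell_1 = "B", lung_1 = "L")
  py <- tempfile(fileext = ".yaml")
  yaml::write_yaml(as.list(m), py)
  expect_equal(read_map_config(py), m)
  pj <- tempfile(fileext = ".json")
  jsonlite::write_json(as.list(m), pj, auto_unbox = TRUE)
  expect_equal(read_map_config(pj), m)
})
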
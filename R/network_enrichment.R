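#' Restrict the interactome to one cell type
#'
#' Keeps only interactions realized by gene products expressed in the given
#' cell bucket: the induced subgraph of the global protein-interaction
#' network on the expressed gene set.
#'
#' @param ppi global interactome ([igraph::graph], from [load_ppi()]).
#' @param expressed_genes character vector of genes expressed in the bucket.
#' @param bucket bucket label, recorded on the result.
#' @return A `cell_interactome` object: list with `bucket` and `graph`.
#' @export
filter_interactome <- function(ppi, expressed_genes, bucket) {
  if (!length(expressed_genes))
    stop("filter_interactome: empty expressed gene set for bucket ", bucket,
         call. = FALSE)
  keep <- intersect(igraph::V(ppi)$name, unique(expressed_genes))
  if (!length(keep))
    stop("filter_interactome: no expressed gene of bucket ", bucket,
         " is present in the interactome", call. = FALSE)
  g <- igraph::induced_subgraph(ppi, keep)
  structure(list(bucket = bucket, graph = g), class = "cell_interactome")
}

#' @export
print.cell_interactome <- function(x, ...) {
  cat(sprintf("<cell_interactome> bucket %s: %d nodes, %d edges\n",
              x$bucket, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

as_graph <- function(x) {
  if (inherits(x, "cell_interactome")) x$graph
  else if (igraph::is_igraph(x)) x
  else stop("expected an igraph or cell_interactome object", call. = FALSE)
}

# Indexed edge representation used by the fast induced-subgraph metrics:
# integer endpoint vectors over 1..n plus the node name table.
graph_index <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  list(n = igraph::vcount(g),
       names = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
       e1 = as.integer(el[, 1]), e2 = as.integer(el[, 2]),
       degree = igraph::degree(g))
}

# Union-find with path halving; returns the component label per member node.
uf_components <- function(members, e1, e2) {
  parent <- seq_along(members)
  idx <- integer(0)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(e1)) {
    for (i in seq_along(e1)) {
      ra <- find(e1[i]); rb <- find(e2[i])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_along(members), find, integer(1))
}

# Metrics of the induced subgraph on `sel` (integer node ids of `gi`):
# edge count, and nodes/edges of the largest connected component. Ties on
# component size break by edge count, then by lexicographically smallest
# member-name set, so reports are platform-independent.
induced_metrics <- function(gi, sel, want_lcc = TRUE, want_members = FALSE) {
  k <- length(sel)
  if (k == 0L)
    return(list(n_nodes = 0L, n_edges = 0L, lcc_nodes = 0L, lcc_edges = 0L,
                lcc_members = character(0)))
  member <- integer(gi$n)
  member[sel] <- seq_len(k)
  a <- member[gi$e1]; b <- member[gi$e2]
  keep <- a > 0L & b > 0L
  ia <- a[keep]; ib <- b[keep]
  n_edges <- length(ia)
  if (!want_lcc)
    return(list(n_nodes = k, n_edges = n_edges, lcc_nodes = NA_integer_,
                lcc_edges = NA_integer_, lcc_members = character(0)))
  comp <- uf_components(seq_len(k), ia, ib)
  sizes <- tabulate(comp, nbins = k)
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    e_comp <- tabulate(comp[ia], nbins = k)  # both endpoints share a comp
    cand_e <- e_comp[cand]
    cand <- cand[cand_e == max(cand_e)]
    if (length(cand) > 1L) {
      keys <- vapply(cand, function(cc)
        paste(sort(gi$names[sel[comp == cc]]), collapse = "\r"),
        character(1))
      cand <- cand[order(keys)[1]]
    }
  }
  cc <- cand[1]
  lcc_nodes <- best_size
  lcc_edges <- sum(comp[ia] == cc)
  members <- if (want_members) sort(gi$names[sel[comp == cc]]) else character(0)
  list(n_nodes = k, n_edges = n_edges, lcc_nodes = as.integer(lcc_nodes),
       lcc_edges = as.integer(lcc_edges), lcc_members = members)
}

#' Extract the high-score subnetwork and its largest connected component
#'
#' Induces the subgraph of a cell interactome on a selected gene set (genes
#' with positive score above a percentile cutoff, see [select_high_pre()])
#' and computes its connectivity metrics: node and edge counts of the
#' subnetwork and of its largest connected component (LCC). Subnetworks whose
#' LCC has `min_lcc_nodes` nodes or fewer are flagged ineligible — very small
#' or loosely connected networks are treated as noise.
#'
#' @param interactome `cell_interactome` (or bare igraph).
#' @param selected_genes character vector of selected genes.
#' @param min_lcc_nodes eligibility threshold, strictly-greater-than
#'   (default 15).
#' @param filter_on apply the threshold to the `"lcc"` (default) or to the
#'   whole `"subnetwork"` node count.
#' @return List with `graph` (the induced subgraph), `lcc` (the LCC
#'   subgraph), and `metrics` (`n_nodes`, `n_edges`, `lcc_nodes`,
#'   `lcc_edges`, `eligible`).
#' @export
extract_subnetwork <- function(interactome, selected_genes,
                               min_lcc_nodes = 15,
                               filter_on = c("lcc", "subnetwork")) {
  filter_on <- match.arg(filter_on)
  g <- as_graph(interactome)
  gi <- graph_index(g)
  sel_names <- intersect(gi$names, unique(selected_genes))
  sel <- match(sel_names, gi$names)
  m <- induced_metrics(gi, sel, want_members = TRUE)
  sub <- igraph::induced_subgraph(g, sel_names)
  lcc <- igraph::induced_subgraph(g, m$lcc_members)
  basis <- if (filter_on == "lcc") m$lcc_nodes else m$n_nodes
  metrics <- list(n_nodes = m$n_nodes, n_edges = m$n_edges,
                  lcc_nodes = m$lcc_nodes, lcc_edges = m$lcc_edges,
                  eligible = basis > min_lcc_nodes)
  list(graph = sub, lcc = lcc, metrics = metrics)
}

#' Null distribution of connectivity for random node sets
#'
#' Draws `reps` node sets of size `k` uniformly at random (without
#' replacement) from the interactome and records, for each induced subgraph,
#' the total edge count and the node and edge counts of its largest connected
#' component. This is the size-matched random-network background against
#' which observed subnetwork connectivity is judged.
#'
#' @param interactome `cell_interactome` or igraph to sample from.
#' @param k nodes per draw; must not exceed the interactome size.
#' @param reps number of draws (the reference analysis uses 10,000).
#' @param seed integer seed for reproducibility (`NULL` = current RNG
#'   stream).
#' @param degree_matched if `TRUE`, draws preserve the degree-decile
#'   composition of `match_nodes` instead of being fully uniform — a
#'   robustness check, not the default null model.
#' @param match_nodes node names whose degree profile to match (required
#'   when `degree_matched`).
#' @return `data.table` with columns `n_edges`, `lcc_nodes`, `lcc_edges`,
#'   one row per draw.
#' @export
sample_null <- function(interactome, k, reps = 10000, seed = NULL,
                        degree_matched = FALSE, match_nodes = NULL) {
  g <- as_graph(interactome)
  gi <- graph_index(g)
  if (k > gi$n)
    stop(sprintf("sample_null: k = %d exceeds interactome size %d", k, gi$n),
         call. = FALSE)
  stopifnot(reps >= 1)
  draw_pool <- NULL
  if (degree_matched) {
    if (is.null(match_nodes))
      stop("sample_null: degree_matched requires match_nodes", call. = FALSE)
    br <- unique(stats::quantile(gi$degree, probs = seq(0, 1, 0.1), type = 7))
    bin <- cut(gi$degree, breaks = br, include.lowest = TRUE, labels = FALSE)
    sel0 <- match(intersect(match_nodes, gi$names), gi$names)
    need <- tabulate(bin[sel0], nbins = length(br) - 1L)
    draw_pool <- split(seq_len(gi$n), bin)
  }
  with_seed(seed, {
    out <- matrix(0L, nrow = reps, ncol = 3L)
    for (i in seq_len(reps)) {
      sel <- if (degree_matched) {
        unlist(lapply(seq_along(draw_pool), function(bn) {
          nb <- need[as.integer(names(draw_pool)[bn])]
          if (is.na(nb) || nb == 0L) integer(0)
          else draw_pool[[bn]][sample.int(length(draw_pool[[bn]]), nb)]
        }), use.names = FALSE)
      } else sample.int(gi$n, k)
      m <- induced_metrics(gi, sel)
      out[i, ] <- c(m$n_edges, m$lcc_nodes, m$lcc_edges)
    }
    data.table(n_edges = out[, 1], lcc_nodes = out[, 2], lcc_edges = out[, 3])
  })
}

#' Empirical p-value against a permutation null
#'
#' Add-one estimator: `(number of null values >= observed + 1) / (reps + 1)`.
#' Never returns 0; the smallest attainable value is `1 / (reps + 1)`.
#'
#' @param observed observed metric value.
#' @param null numeric vector of null metric values.
#' @return The p-value.
#' @export
empirical_p <- function(observed, null) {
  if (!length(null)) stop("empirical_p: empty null distribution",
                          call. = FALSE)
  (sum(null >= observed) + 1) / (length(null) + 1)
}

#' Connectivity enrichment test for a selected gene set
#'
#' Computes the observed subnetwork metrics of the selected genes within a
#' cell interactome and their empirical p-values against `reps` size-matched
#' random node draws (see [sample_null()]). All three metrics — total edges,
#' LCC node count, LCC edge count — are always reported.
#'
#' @inheritParams extract_subnetwork
#' @inheritParams sample_null
#' @param keep_null retain the null draws in the result (default `FALSE`).
#' @return A `network_metrics` object: observed metrics, per-metric p-values,
#'   eligibility flag, `reps`, `seed`, and optionally the null table.
#' @export
enrich_test <- function(interactome, selected_genes, reps = 10000,
                        seed = NULL, min_lcc_nodes = 15,
                        filter_on = c("lcc", "subnetwork"),
                        degree_matched = FALSE, keep_null = FALSE) {
  filter_on <- match.arg(filter_on)
  sub <- extract_subnetwork(interactome, selected_genes,
                            min_lcc_nodes = min_lcc_nodes,
                            filter_on = filter_on)
  obs <- sub$metrics
  k <- obs$n_nodes
  null <- if (k >= 1)
    sample_null(interactome, k, reps = reps, seed = seed,
                degree_matched = degree_matched,
                match_nodes = igraph::V(sub$graph)$name)
  else data.table(n_edges = integer(), lcc_nodes = integer(),
                  lcc_edges = integer())
  p <- if (k >= 1) c(
    n_edges = empirical_p(obs$n_edges, null$n_edges),
    lcc_nodes = empirical_p(obs$lcc_nodes, null$lcc_nodes),
    lcc_edges = empirical_p(obs$lcc_edges, null$lcc_edges))
  else c(n_edges = NA_real_, lcc_nodes = NA_real_, lcc_edges = NA_real_)
  structure(list(
    bucket = if (inherits(interactome, "cell_interactome"))
      interactome$bucket else NA_character_,
    n_selected = length(unique(selected_genes)),
    n_nodes = obs$n_nodes, n_edges = obs$n_edges,
    lcc_nodes = obs$lcc_nodes, lcc_edges = obs$lcc_edges,
    eligible = obs$eligible, p = p, reps = reps, seed = seed,
    null = if (keep_null) null else NULL), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> bucket %s: %d/%d selected genes in graph, %d edges\n",
    x$bucket %||% "?", x$n_nodes, x$n_selected, x$n_edges))
  cat(sprintf("  LCC: %d nodes, %d edges%s\n", x$lcc_nodes, x$lcc_edges,
              if (isTRUE(x$eligible)) "" else "  [ineligible: LCC too small]"))
  cat(sprintf("  empirical p (reps = %d): edges %.3g, LCC nodes %.3g, LCC edges %.3g\n",
              x$reps, x$p[["n_edges"]], x$p[["lcc_nodes"]],
              x$p[["lcc_edges"]]))
  invisible(x)
}

metrics_row <- function(nm) {
  data.table(bucket = nm$bucket, n_selected = nm$n_selected,
             n_nodes = nm$n_nodes, n_edges = nm$n_edges,
             lcc_nodes = nm$lcc_nodes, lcc_edges = nm$lcc_edges,
             eligible = nm$eligible,
             p_edges = nm$p[["n_edges"]],
             p_lcc_nodes = nm$p[["lcc_nodes"]],
             p_lcc_edges = nm$p[["lcc_edges"]])
}

#' Sensitivity grid over SNP tier, LD threshold and score percentile
#'
#' Reruns scoring and the connectivity enrichment test for every combination
#' of evidence tier (GW/SR/NR), LD r-squared cutoff and score percentile
#' threshold, in every cell bucket. Tiers with no data yield rows marked
#' absent rather than aborting the grid.
#'
#' @param tier_inputs named list tier -> list(effects=, proxies=); a `NULL`
#'   element marks a tier with missing data.
#' @param catalogue classified catalogue shared by all tiers.
#' @param interactomes named list bucket -> `cell_interactome`.
#' @param r2_values LD thresholds (default `c(0.1, 0.5, 0.8)`).
#' @param q_values score percentiles (default `c(10, 25, 50)`).
#' @param reps null draws per cell (default 1000 for grid work; raise to
#'   10,000 for confirmatory runs).
#' @param seed base seed; each grid cell uses a deterministic offset so rows
#'   are individually reproducible.
#' @param eqtl optional eQTL table passed to [compute_pre()].
#' @param min_lcc_nodes eligibility threshold (default 15).
#' @return `data.table` with one row per (tier, r2_min, pre_q, bucket):
#'   metrics, p-values, and `absent` flag.
#' @export
sensitivity_grid <- function(tier_inputs, catalogue, interactomes,
                             r2_values = c(0.1, 0.5, 0.8),
                             q_values = c(10, 25, 50),
                             reps = 1000, seed = 1L, eqtl = NULL,
                             min_lcc_nodes = 15) {
  rows <- list()
  cell_i <- 0L
  for (tier in names(tier_inputs)) {
    ti <- tier_inputs[[tier]]
    for (r2v in r2_values) {
      gene_pre <- NULL
      if (!is.null(ti)) {
        region_snps <- expand_ld(ti$effects, ti$proxies, r2_min = r2v)
        pre <- compute_pre(region_snps, catalogue, eqtl = eqtl)
        gene_pre <- aggregate_gene_pre(pre)
      }
      for (qv in q_values) {
        for (b in names(interactomes)) {
          cell_i <- cell_i + 1L
          if (is.null(ti)) {
            rows[[length(rows) + 1L]] <- data.table(
              tier = tier, r2_min = r2v, pre_q = qv, bucket = b,
              absent = TRUE, n_selected = NA_integer_, n_nodes = NA_integer_,
              n_edges = NA_integer_, lcc_nodes = NA_integer_,
              lcc_edges = NA_integer_, eligible = NA,
              p_edges = NA_real_, p_lcc_nodes = NA_real_,
              p_lcc_edges = NA_real_)
            next
          }
          gb <- gene_pre[bucket == b]
          sel <- select_high_pre(stats::setNames(gb$pre, gb$gene), q = qv)
          nm <- enrich_test(interactomes[[b]], sel, reps = reps,
                            seed = if (is.null(seed)) NULL else seed + cell_i,
                            min_lcc_nodes = min_lcc_nodes)
          r <- metrics_row(nm)
          rows[[length(rows) + 1L]] <- cbind(
            data.table(tier = tier, r2_min = r2v, pre_q = qv, bucket = b),
            r[, !"bucket"], data.table(absent = FALSE))
        }
      }
    }
  }
  out <- rbindlist(rows, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(out, c("tier", "r2_min", "pre_q", "bucket",
                                 "absent"))
  out[]
}
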
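# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom data.table data.table as.data.table setDT setnames rbindlist
#' @importFrom data.table setorder setorderv copy fwrite :=
#' @import stats
NULL

# data.table NSE variables, silences R CMD check
utils::globalVariables(c(
  ".", ".N", ".SD", "snp_id", "region_id", "r2", "lead_snp", "proxy_snp",
  "reg_class", "bucket", "n_experiments", "target_gene", "gene", "pre",
  "ww", "dose", "feature_type", "cell_raw", "subject_id", "value", "tier",
  "feature_id", "effect_sign", "sign_", "status", "metric", "n_edges",
  "lcc_nodes", "lcc_edges", "n_nodes", "pre_q", "r2_min", "eligible",
  "key", "n", "percentile", "causal", "region", ".I"
))

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Read a tab-separated table with header; transparently handles .gz because
# gzfile() falls back to plain text for uncompressed input.
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  # colClasses: keep everything character so labels like "T" or "NA" never
  # get coerced to logicals/NA; numeric columns are converted by each reader
  df <- utils::read.delim(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", quote = "",
                          colClasses = "character")
  setDT(df)
  df
}

write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

require_columns <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
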
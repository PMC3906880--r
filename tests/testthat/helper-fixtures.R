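# Small deterministic datasets built in code.

options(cormclust.loglevel = "warn")

# Complete toy dataset: value = gene index + time/10, two conditions x two
# replicates over the given times (deterministic, no noise).
toy_dataset <- function(n_genes = 2L, conditions = c("WT", "SM"),
                        replicates = c("r1", "r2"), times = c(0, 5, 10),
                        value_fun = function(g, cond, rep, t) g + t / 10) {
  obs <- expand.grid(condition = conditions, replicate = replicates,
                     time = times, stringsAsFactors = FALSE)
  obs <- obs[order(obs$condition, obs$replicate, obs$time), ]
  vals <- t(vapply(seq_len(n_genes), function(g)
    mapply(value_fun, g, obs$condition, obs$replicate, obs$time),
    numeric(nrow(obs))))
  expression_dataset(matrix(vals, n_genes, nrow(obs)), obs,
                     paste0("g", seq_len(n_genes)))
}

# Long-format data frame for writing fixture files.
toy_long_df <- function(ds) {
  G <- length(ds$genes); N <- nrow(ds$observations)
  data.frame(gene = rep(ds$genes, each = N),
             condition = rep(ds$observations$condition, G),
             replicate = rep(ds$observations$replicate, G),
             time = rep(ds$observations$time, G),
             value = as.vector(t(ds$values)),
             stringsAsFactors = FALSE)
}

write_long_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

# Cross-sectional dataset wrapping a plain profile matrix (one observation
# per column, single condition/replicate).
matrix_dataset <- function(P) {
  n <- ncol(P)
  obs <- data.frame(condition = "all", replicate = "r1", time = seq_len(n))
  expression_dataset(P, obs, rownames(P))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
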
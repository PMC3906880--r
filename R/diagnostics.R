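#' Model residuals and a variance-by-time summary
#'
#' Per-gene residuals r_g = y_g - X_g beta_{u_g} - Z_g bhat_g on the
#' observed entries (u_g the MAP cluster, bhat_g the BLUP), plus the
#' residual variance per cluster per time point — the standard check that
#' the residual spread is roughly constant over the time course.
#'
#' @param object a `clmm_fit`.
#' @param ds the [expression_dataset()] the model was fitted to.
#' @param ... unused.
#' @return A list with `residuals` (G x N matrix, `NA` at masked cells)
#'   and `by_time` (data frame: cluster, time, n, variance).
#' @export
residuals.clmm_fit <- function(object, ds, ...) {
  stopifnot(inherits(ds, "expression_dataset"))
  eng <- engine_prepare(ds, object$spec)
  mu <- eng$X %*% t(object$params$beta)
  Zb <- if (eng$q > 0L) object$blups$bhat %*% t(eng$Z)
        else matrix(0, eng$G, eng$N)
  lab <- object$map_labels
  R <- ds$values - t(mu)[lab, , drop = FALSE] - Zb
  R[!ds$mask] <- NA_real_
  dimnames(R) <- dimnames(ds$values)
  tt <- ds$observations$time
  ut <- sort(unique(tt))
  rows <- expand.grid(time = ut, cluster = seq_len(object$params$K))
  by_time <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    vals <- R[lab == rows$cluster[i], tt == rows$time[i]]
    vals <- vals[!is.na(vals)]
    data.frame(cluster = rows$cluster[i], time = rows$time[i],
               n = length(vals),
               variance = if (length(vals) > 1L) stats::var(vals) else NA_real_)
  }))
  list(residuals = R, by_time = by_time)
}

#' Eigen display coordinates for clustered profiles
#'
#' Eigen-decomposition of the covariance of the (column-centered) profile
#' matrix; genes are projected on the two leading eigenvectors and the
#' cluster mean profiles are projected with the same loadings, giving the
#' usual two-dimensional display of cluster location and tightness.
#' Columns with any missing cell are dropped first.
#'
#' @param profiles numeric G x n matrix (e.g. replicate-averaged).
#' @param labels optional per-gene cluster labels (used to compute cluster
#'   mean profiles when `centers` is not given).
#' @param centers optional K x n matrix of cluster profiles to project.
#' @param center_cols subtract per-column means before the decomposition
#'   (default `TRUE`).
#' @return A list with `scores` (G x 2), `center_scores` (K x 2 or `NULL`),
#'   `var_explained` (fraction of total variance captured by the two
#'   leading eigenvectors), `loadings` (n x 2), and `eigenvalues`.
#' @export
pca_scores <- function(profiles, labels = NULL, centers = NULL,
                       center_cols = TRUE) {
  profiles <- as.matrix(profiles)
  keep <- colSums(is.na(profiles)) == 0L
  profiles <- profiles[, keep, drop = FALSE]
  if (ncol(profiles) < 2L) stop("need at least two complete columns")
  if (is.null(centers) && !is.null(labels)) {
    centers <- do.call(rbind, lapply(sort(unique(labels)), function(k)
      colMeans(profiles[labels == k, , drop = FALSE])))
  } else if (!is.null(centers)) {
    centers <- as.matrix(centers)[, keep, drop = FALSE]
  }
  mu <- if (center_cols) colMeans(profiles) else rep(0, ncol(profiles))
  Xc <- sweep(profiles, 2L, mu)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  loadings <- eg$vectors[, 1:2, drop = FALSE]
  scores <- Xc %*% loadings
  center_scores <- if (!is.null(centers))
    sweep(centers, 2L, mu) %*% loadings else NULL
  list(scores = scores, center_scores = center_scores,
       var_explained = sum(eg$values[1:2]) / sum(eg$values),
       loadings = loadings, eigenvalues = eg$values)
}

#' Time of the first peak of a profile
#'
#' The time of the first interior local maximum (strictly greater than
#' both neighbours); if the profile has none, the time of its global
#' maximum.  Ties go to the earliest time.
#'
#' @param profile numeric vector (length >= 3).
#' @param times numeric vector of the same length, increasing.
#' @return The peak time, a scalar.
#' @export
first_peak_time <- function(profile, times) {
  stopifnot(length(profile) == length(times), length(profile) >= 3L)
  n <- length(profile)
  interior <- which(profile[2:(n - 1L)] > profile[1:(n - 2L)] &
                      profile[2:(n - 1L)] > profile[3:n]) + 1L
  if (length(interior)) return(times[interior[1L]])
  times[which.max(profile)]
}

#' Renumber clusters by first peak time
#'
#' Relabels the clusters of a fit 1..K in ascending order of the first
#' peak time of their fitted mean profiles, so cluster numbers follow the
#' order in which clusters peak across the time course.  Posterior
#' columns, labels, proportions and parameters are permuted consistently;
#' ties keep the original order.
#'
#' @param fit a `clmm_fit` (spline basis).
#' @param condition condition whose fitted profiles order the clusters
#'   (required for condition-blocked fits).
#' @param times evaluation grid; defaults to 25 points over the design's
#'   time range.
#' @return The relabelled `clmm_fit`, with attribute `permutation` (new
#'   index = `permutation[old index]` position, i.e. `order()` output).
#' @export
relabel_by_peak <- function(fit, condition = NULL, times = NULL) {
  stopifnot(inherits(fit, "clmm_fit"))
  spec <- fit$spec
  if (is.null(times))
    times <- seq(spec$time_range[1], spec$time_range[2], length.out = 25L)
  prof <- fitted_cluster_profile(fit$params, condition, times)
  peaks <- apply(prof, 2L, first_peak_time, times = times)
  perm <- order(peaks)                      # perm[new] = old
  inv <- match(seq_along(perm), perm)       # inv[old] = new
  fit$params$pi <- fit$params$pi[perm]
  fit$params$beta <- fit$params$beta[perm, , drop = FALSE]
  fit$params$D <- fit$params$D[perm]
  fit$params$sigma2 <- fit$params$sigma2[perm]
  fit$posterior <- fit$posterior[, perm, drop = FALSE]
  fit$map_labels[] <- inv[fit$map_labels]
  attr(fit, "permutation") <- perm
  fit
}

#' Cross-tabulate two clusterings
#'
#' Contingency table of two labelings of the same genes, with margins,
#' grand total, and the agreement fraction after the best one-to-one
#' matching of row labels to column labels (maximum-weight assignment:
#' exact by permutation search for up to 9 labels, greedy beyond).
#'
#' @param labels_a,labels_b per-gene cluster labels, same genes in the
#'   same order.
#' @return An object of class `cross_tab`: `counts` (R x C integer
#'   matrix with label dimnames), `row_labels`, `col_labels`, `total`,
#'   `row_sums`, `col_sums`, `agreement`, `matching` (column label matched
#'   to each row label).
#' @export
cross_tab <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths")
  ra <- sort(unique(labels_a)); cb <- sort(unique(labels_b))
  counts <- matrix(0L, length(ra), length(cb), dimnames = list(ra, cb))
  tab <- table(factor(labels_a, levels = ra), factor(labels_b, levels = cb))
  counts[] <- as.integer(tab)
  cross_tab_from_counts(counts)
}

# Build the cross_tab object (margins, total, matched agreement) from a
# counts matrix; also the entry point for transcribed published tables.
cross_tab_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("negative count")
  m <- best_matching(counts)
  structure(list(counts = counts,
                 row_labels = rownames(counts), col_labels = colnames(counts),
                 total = sum(counts),
                 row_sums = rowSums(counts), col_sums = colSums(counts),
                 agreement = m$weight / sum(counts),
                 matching = m$assignment),
            class = "cross_tab")
}

# Maximum-weight one-to-one matching of rows to columns: exact dynamic
# program over column subsets (rows in order, bitmask of used columns) for
# up to 16 labels; greedy (largest remaining cell first) beyond that.
best_matching <- function(counts) {
  R <- nrow(counts); C <- ncol(counts)
  if (max(R, C) <= 16L) {
    n <- max(R, C)
    pad <- matrix(0, n, n)
    pad[seq_len(R), seq_len(C)] <- counts
    nmask <- bitwShiftL(1L, n)
    dp <- rep(-Inf, nmask); dp[1L] <- 0
    choice <- integer(nmask)
    popcnt <- integer(nmask)
    for (m in seq_len(nmask - 1L))
      popcnt[m + 1L] <- popcnt[bitwShiftR(m, 1L) + 1L] + bitwAnd(m, 1L)
    for (m in 0:(nmask - 2L)) {
      if (!is.finite(dp[m + 1L])) next
      i <- popcnt[m + 1L] + 1L
      for (j in seq_len(n)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(m, bit) == 0L) {
          m2 <- bitwOr(m, bit)
          w <- dp[m + 1L] + pad[i, j]
          if (w > dp[m2 + 1L]) {
            dp[m2 + 1L] <- w
            choice[m2 + 1L] <- j
          }
        }
      }
    }
    perm <- integer(n)
    m <- nmask - 1L
    for (i in n:1) {
      j <- choice[m + 1L]
      perm[i] <- j
      m <- bitwAnd(m, bitwNot(bitwShiftL(1L, j - 1L)))
    }
    assignment <- perm[seq_len(R)]
    assignment[assignment > C] <- NA_integer_
    weight <- dp[nmask]
  } else {
    left_r <- seq_len(R); left_c <- seq_len(C)
    assignment <- rep(NA_integer_, R)
    weight <- 0
    while (length(left_r) && length(left_c)) {
      sub <- counts[left_r, left_c, drop = FALSE]
      ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
      assignment[left_r[ij[1L]]] <- left_c[ij[2L]]
      weight <- weight + sub[ij[1L], ij[2L]]
      left_r <- left_r[-ij[1L]]; left_c <- left_c[-ij[2L]]
    }
  }
  names(assignment) <- rownames(counts)
  list(assignment = assignment, weight = weight)
}

#' @export
print.cross_tab <- function(x, ...) {
  out <- cbind(x$counts, total = x$row_sums)
  out <- rbind(out, total = c(x$col_sums, x$total))
  print(out)
  cat(sprintf("agreement after one-to-one matching: %.4f (%d / %d genes)\n",
              x$agreement, round(x$agreement * x$total), x$total))
  invisible(x)
}

#' Read / write a cross-tabulation as TSV
#'
#' The TSV has row labels in the first column and column labels in the
#' header; empty cells are zeros.  `write_cross_tab` appends row/column
#' margins.
#'
#' @param path TSV file path.
#' @param x a `cross_tab`.
#' @return `read_cross_tab` returns a `cross_tab`; `write_cross_tab`
#'   returns `path` invisibly.
#' @export
read_cross_tab <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  counts <- as.matrix(tab)
  counts[is.na(counts)] <- 0
  cross_tab_from_counts(counts)
}

#' @rdname read_cross_tab
#' @export
write_cross_tab <- function(x, path) {
  stopifnot(inherits(x, "cross_tab"))
  out <- cbind(x$counts, total = x$row_sums)
  out <- rbind(out, total = c(x$col_sums, x$total))
  utils::write.table(cbind(label = rownames(out), out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen for informative genes
#'
#' Per-gene linear-model F-test of the full design against the
#' intercept-only model on the gene's observed entries (replicate
#' measurements act as independent residual draws), followed by
#' Benjamini-Hochberg adjustment.  Genes whose adjusted p-value falls
#' below `alpha` show significant systematic (covariate-explained)
#' variation and are worth clustering.
#'
#' @param ds an [expression_dataset()].
#' @param spec a [design_spec()]; needs p < n_g residual degrees of
#'   freedom per gene.
#' @param alpha adjusted-p-value cutoff.
#' @return A list with `selected` (gene identifiers with adjusted
#'   p < alpha), `p_value`, `p_adjusted` (named per gene), `statistic`
#'   (F), and `excluded` (genes with too few observations, if any, which
#'   also trigger a warning).
#' @export
select_informative_genes <- function(ds, spec, alpha = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  fd <- full_design(ds, spec)
  p <- fd$p
  G <- length(ds$genes)
  pval <- stat <- rep(NA_real_, G)
  names(pval) <- names(stat) <- ds$genes
  n_g <- rowSums(ds$mask)
  excluded <- ds$genes[n_g <= p]
  if (length(excluded))
    warning("excluded gene(s) with n_g <= p: ",
            paste(excluded, collapse = ", "))
  for (g in which(n_g > p)) {
    rows <- which(ds$mask[g, ])
    y <- ds$values[g, rows]
    X <- fd$X[rows, , drop = FALSE]
    f1 <- stats::lm.fit(X, y)
    rank1 <- f1$rank
    rss1 <- sum(f1$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    df1 <- rank1 - 1L
    df2 <- length(y) - rank1
    if (df1 < 1L || df2 < 1L) next
    Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    stat[g] <- Fstat
    pval[g] <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  padj <- stats::p.adjust(pval, method = "BH")
  sel <- ds$genes[!is.na(padj) & padj < alpha]
  list(selected = sel, p_value = pval, p_adjusted = padj,
       statistic = stat, excluded = excluded)
}
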
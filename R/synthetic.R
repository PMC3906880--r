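#' Simulation specification for replicated time-course data
#'
#' Describes a yeast-like replicated longitudinal design: sinusoidal
#' cluster mean curves (cell-cycle-style periodicity) sampled on a
#' regular time grid under several conditions, each with technical
#' replicates that share a gene-level random effect, condition-specific
#' bad time points, and missing-at-random dropout.
#'
#' Defaults emulate a two-genotype cell-cycle course: 0-120 min at 5-min
#' intervals, wild-type (WT) and mutant (SM) conditions with two
#' technical replicates each, the WT grid missing 105 min and the SM grid
#' missing 25/40/55 min, 60-min period (two cycles across the course),
#' K = 3 phase-shifted clusters over G = 300 genes, random-intercept
#' standard deviation 0.1 and residual standard deviation 0.2 (log-ratio
#' units), mutant amplitude damped to 0.6, and 5% of the remaining cells
#' masked at random.
#'
#' @param G number of genes.
#' @param K number of clusters.
#' @param cluster_sizes integer K-vector summing to `G`; defaults to
#'   (near-)equal sizes.
#' @param amplitude sinusoid amplitude (log-ratio units).
#' @param period period in minutes.
#' @param phases per-cluster phase shifts in minutes; default equally
#'   spaced across one period.
#' @param conditions named numeric vector: condition labels with their
#'   amplitude multipliers.
#' @param replicates technical replicates per condition.
#' @param times sampling grid in minutes.
#' @param random_sd per-condition random-intercept standard deviation
#'   (scalar or length K; D_k = diag(random_sd^2) over conditions).
#' @param sigma residual standard deviation (scalar or length K).
#' @param bad_timepoints named list: condition -> times to drop.
#' @param miss_frac fraction of remaining cells masked at random, in
#'   [0, 1).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(G = 300L, K = 3L, cluster_sizes = NULL,
                     amplitude = 1, period = 60,
                     phases = NULL,
                     conditions = c(WT = 1, SM = 0.6),
                     replicates = 2L,
                     times = seq(0, 120, by = 5),
                     random_sd = 0.1, sigma = 0.2,
                     bad_timepoints = list(WT = 105, SM = c(25, 40, 55)),
                     miss_frac = 0.05) {
  G <- as.integer(G); K <- as.integer(K)
  if (is.null(cluster_sizes)) {
    cluster_sizes <- rep(G %/% K, K)
    extra <- G - sum(cluster_sizes)
    if (extra > 0L) cluster_sizes[seq_len(extra)] <-
        cluster_sizes[seq_len(extra)] + 1L
  }
  if (sum(cluster_sizes) != G) stop("cluster sizes must sum to G")
  if (is.null(phases)) phases <- period * (seq_len(K) - 1L) / K
  if (length(phases) != K) stop("need one phase per cluster")
  sigma <- rep_len(sigma, K)
  random_sd <- rep_len(random_sd, K)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (any(random_sd < 0)) stop("random_sd must be non-negative")
  if (miss_frac < 0 || miss_frac >= 1) stop("miss_frac must be in [0, 1)")
  if (is.null(names(conditions)))
    stop("conditions must be a named vector of amplitude multipliers")
  if (!is.null(bad_timepoints) && length(bad_timepoints)) {
    unknown <- setdiff(names(bad_timepoints), names(conditions))
    if (length(unknown))
      stop("bad_timepoints name unknown condition(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(G = G, K = K, cluster_sizes = as.integer(cluster_sizes),
                 amplitude = amplitude, period = period, phases = phases,
                 conditions = conditions, replicates = as.integer(replicates),
                 times = as.numeric(times), random_sd = random_sd,
                 sigma = sigma, bad_timepoints = bad_timepoints,
                 miss_frac = miss_frac),
            class = "sim_spec")
}

# Cluster k's mean curve for one condition: damped/amplified sinusoid
# with the cluster's phase.
sim_template <- function(spec, k, condition, times) {
  mult <- spec$conditions[[condition]]
  mult * spec$amplitude *
    sin(2 * pi * (times - spec$phases[k]) / spec$period)
}

#' Simulate a replicated longitudinal time course
#'
#' Generates data under the CLMM: gene g in cluster k has value
#' `template_k(condition, t) + b_g[condition] + noise` at each observed
#' (condition, replicate, time), with the per-condition random intercepts
#' `b_g ~ N(0, diag(random_sd_k^2))` shared by both technical replicates
#' of the gene and independent `N(0, sigma_k^2)` noise per measurement.
#' Bad time points are removed per condition, then `miss_frac` of the
#' remaining cells are masked uniformly at random.
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed; the run is fully reproducible from it.
#' @return A list: `dataset` (an [expression_dataset()]), `labels` (true
#'   cluster per gene), `random_effects` (G x n_conditions matrix of true
#'   intercepts), `templates` (function(k, condition, times)), `spec`,
#'   `seed`.
#' @export
simulate_lwr_timecourse <- function(spec = sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  conds <- names(spec$conditions)
  grid <- do.call(rbind, lapply(conds, function(cc) {
    tt <- spec$times
    bad <- spec$bad_timepoints[[cc]]
    if (!is.null(bad)) tt <- setdiff(tt, bad)
    expand.grid(condition = cc,
                replicate = paste0("rep", seq_len(spec$replicates)),
                time = tt, stringsAsFactors = FALSE)
  }))
  grid <- grid[order(grid$condition, grid$replicate, grid$time), ]
  N <- nrow(grid)
  G <- spec$G
  labels <- rep(seq_len(spec$K), spec$cluster_sizes)
  genes <- sprintf("gene%04d", seq_len(G))
  mean_mat <- matrix(0, spec$K, N)
  for (k in seq_len(spec$K))
    for (cc in conds) {
      rows <- grid$condition == cc
      mean_mat[k, rows] <- sim_template(spec, k, cc, grid$time[rows])
    }
  b <- matrix(0, G, length(conds), dimnames = list(genes, conds))
  for (g in seq_len(G))
    b[g, ] <- stats::rnorm(length(conds), 0, spec$random_sd[labels[g]])
  condcol <- match(grid$condition, conds)
  values <- mean_mat[labels, , drop = FALSE] +
    b[, condcol, drop = FALSE] +
    matrix(stats::rnorm(G * N, 0,
                        rep(spec$sigma[labels], N)), G, N)
  dimnames(values) <- list(genes, NULL)
  mask <- matrix(TRUE, G, N)
  if (spec$miss_frac > 0) {
    n_miss <- round(spec$miss_frac * G * N)
    drop_idx <- sample.int(G * N, n_miss)
    mask[drop_idx] <- FALSE
  }
  ds <- expression_dataset(values, grid, genes, mask)
  list(dataset = ds,
       labels = structure(labels, names = genes),
       random_effects = b,
       templates = function(k, condition, times)
         sim_template(spec, k, condition, times),
       spec = spec, seed = as.integer(seed))
}

#' Simulate the two-cluster linear-covariate benchmark
#'
#' Cross-sectional benchmark with 8 genes in two clusters of four and 100
#' samples: a covariate X takes 10 levels with 10 samples each, and the
#' two clusters have distinct linear trends in X.  Gene-specific offsets
#' and measurement noise are small relative to the slope separation, so a
#' 2-component mixture of linear models recovers the partition.
#'
#' @param seed integer seed.
#' @param slopes length-2 cluster slopes in X.
#' @param offset_sd standard deviation of the gene-specific offsets.
#' @param noise_sd residual standard deviation.
#' @return A list: `dataset` (8 genes x 100 samples; the covariate is
#'   stored in the observation `time` field), `labels` (true clusters),
#'   `seed`.
#' @export
simulate_clm_benchmark <- function(seed = 1L, slopes = c(0.3, -0.3),
                                 offset_sd = 0.3, noise_sd = 0.5) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  G <- 8L
  levels_x <- 1:10
  per_level <- 10L
  x <- rep(levels_x, each = per_level)
  N <- length(x)                           # 100 samples
  labels <- rep(1:2, each = 4L)
  offsets <- stats::rnorm(G, 0, offset_sd)
  mu <- outer(slopes[labels], x - mean(levels_x)) + offsets
  values <- mu + matrix(stats::rnorm(G * N, 0, noise_sd), G, N)
  genes <- paste0("gene", seq_len(G))
  dimnames(values) <- list(genes, NULL)
  obs <- data.frame(condition = "all",
                    replicate = sprintf("s%03d", seq_len(N)),
                    time = x, stringsAsFactors = FALSE)
  ds <- expression_dataset(values, obs, genes)
  list(dataset = ds, labels = structure(labels, names = genes),
       seed = as.integer(seed))
}

#' Design specification matching [simulate_clm_benchmark()]
#'
#' Degree-1 B-spline with no interior knots on the covariate range: a
#' basis for straight lines, so the mixture of linear models fits
#' cluster-specific linear trends in X.
#'
#' @return A [design_spec()].
#' @export
clm_benchmark_design <- function() {
  design_spec(degree = 1L, n_interior_knots = 0L, time_range = c(1, 10),
              random_design = "none")
}

#' Write simulated data and truth to disk
#'
#' @param sim output of [simulate_lwr_timecourse()] or
#'   [simulate_clm_benchmark()].
#' @param data_path long-format TSV for the dataset.
#' @param truth_path TSV for the true labels (and random effects, when
#'   present).
#' @return `data_path`, invisibly.
#' @export
write_simulation <- function(sim, data_path, truth_path) {
  write_long_table(sim$dataset, data_path)
  truth <- data.frame(gene = names(sim$labels), cluster = as.integer(sim$labels),
                      stringsAsFactors = FALSE)
  if (!is.null(sim$random_effects))
    truth <- cbind(truth, as.data.frame(sim$random_effects))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(data_path)
}
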
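#' @name clmm-model
#' @title Mixture of linear mixed models for gene clustering
#'
#' @description
#' Genes are modelled as draws from a K-component mixture.  Conditional on
#' gene g belonging to cluster k (prior probability pi_k), its observed
#' expression vector follows a linear mixed model
#'
#'   y_g | u_g = k  ~  N( X_g beta_k,  Z_g D_k Z_g' + sigma2_k I )
#'
#' where X_g stacks the B-spline (or other) basis rows for the gene's
#' observed entries, beta_k is the cluster's coefficient vector (the
#' systematic, covariate-explained part of expression on which the
#' clustering is based), and the gene-level random effects b_g ~ N(0, D_k)
#' are shared by all of the gene's observations — in particular by both
#' technical replicates of a condition — with independent residual noise
#' sigma2_k.  With no random effects (q = 0) this is the mixture of linear
#' models (CLM); the model is fitted by EM treating both the cluster
#' memberships u_g and the random effects b_g as latent.
NULL

# ---- parameter container ---------------------------------------------------

new_clmm_params <- function(K, pi, beta, D, sigma2, spec = NULL,
                            conditions = NULL) {
  structure(list(K = K, pi = pi, beta = beta, D = D, sigma2 = sigma2,
                 spec = spec, conditions = conditions),
            class = "clmm_params")
}

# Symmetric PSD factor D = L L' via eigendecomposition (safe for singular D).
psd_factor <- function(D) {
  if (ncol(D) == 0L) return(D)
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  val <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(val), length(val))
}

# Project a symmetric matrix to the PSD cone by clipping eigenvalues at 0.
psd_project <- function(D) {
  if (ncol(D) == 0L) return(D)
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
}

#' Marginal log-likelihood of one gene under one cluster
#'
#' Log density of the gene's observed values under the cluster's linear
#' mixed model, with the random effects integrated out: a multivariate
#' normal with mean `X beta_k` and covariance `Z D_k Z' + sigma2_k I`.
#' Computed by dense Cholesky factorisation of the n_g x n_g covariance
#' (the EM engine itself uses a low-rank decomposition; this standalone
#' form doubles as an independent check).
#'
#' @param y numeric vector of the gene's observed values (length n_g).
#' @param design a per-gene design, i.e. one element of [build_designs()]
#'   (a list with matrices `X` and `Z`).
#' @param k cluster index.
#' @param params a `clmm_params` object (e.g. `fit$params`).
#' @return The log marginal density, a scalar.
#' @export
marginal_loglik_gene <- function(y, design, k, params) {
  X <- design$X; Z <- design$Z
  n <- length(y)
  if (nrow(X) != n || nrow(Z) != n)
    stop("design rows do not match the length of y")
  if (ncol(X) != ncol(params$beta))
    stop("design width does not match the parameter dimension")
  mu <- drop(X %*% params$beta[k, ])
  V <- params$sigma2[k] * diag(n)
  if (ncol(Z) > 0L) V <- V + Z %*% params$D[[k]] %*% t(Z)
  cV <- chol(V)
  z <- backsolve(cV, y - mu, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(cV))) + sum(z^2))
}

# ---- E step ----------------------------------------------------------------

# Low-rank per-gene likelihood and random-effect moments.
# With D_k = L L' and A = (Z_g L)'(Z_g L), S = sigma2 I_q + A:
#   det V  = sigma2^(n-q) det S
#   r'V^-1 r = (r'r - t1' S^-1 t1)/sigma2,  t1 = (Z_g L)' r
#   bhat_gk = L S^-1 t1,   C_gk = sigma2 L S^-1 L'
# All quantities use only q x q solves; per-gene designs are row subsets of
# the full-grid X and Z, so cluster means are computed once per cluster.

#' E step of the CLMM EM algorithm
#'
#' Computes posterior membership probabilities p_gk (via log-sum-exp),
#' the conditional random-effect means b_gk and covariances C_gk, and the
#' observed-data log-likelihood under the current parameters.
#'
#' @param ds an [expression_dataset()].
#' @param spec the [design_spec()] used for the fit.
#' @param params a `clmm_params` object.
#' @param hard_assign if `TRUE`, posterior rows are collapsed to 0/1 MAP
#'   indicators (classification EM) and the classification log-likelihood
#'   is reported.
#' @return A list: `posterior` (G x K), `bhat` (list over clusters of
#'   G x q matrices), `C` (list over clusters of G x q^2 matrices, rows =
#'   vectorised conditional covariances), `loglik` (scalar),
#'   `logdens` (G x K matrix of per-gene log marginal densities).
#' @export
clmm_e_step <- function(ds, spec, params, hard_assign = FALSE) {
  eng <- engine_prepare(ds, spec)
  est <- engine_e_step(eng, params, hard_assign)
  est[c("posterior", "bhat", "C", "loglik", "logdens")]
}

# Precompute everything that does not change across EM iterations.
engine_prepare <- function(ds, spec) {
  fd <- full_design(ds, spec)
  G <- length(ds$genes)
  rows <- observed_index(ds)
  n_g <- lengths(rows)
  M <- ds$mask * 1
  vals0 <- ds$values
  vals0[!ds$mask] <- 0
  q <- fd$q
  Aflat <- NULL
  if (q > 0L) {
    Aflat <- t(vapply(rows, function(r)
      as.vector(crossprod(fd$Z[r, , drop = FALSE])), numeric(q * q)))
  }
  list(ds = ds, spec = spec, X = fd$X, Z = fd$Z, p = fd$p, q = fd$q,
       conditions = fd$conditions, rows = rows, n_g = n_g, M = M,
       vals0 = vals0, Aflat = Aflat, G = G, N = nrow(ds$observations))
}

engine_e_step <- function(eng, params, hard_assign = FALSE) {
  G <- eng$G; K <- params$K; q <- eng$q
  logdens <- matrix(NA_real_, G, K)
  bhat <- vector("list", K)
  Cm <- vector("list", K)
  mu <- eng$X %*% t(params$beta)             # N x K cluster mean surfaces
  for (k in seq_len(K)) {
    s2 <- params$sigma2[k]
    if (q > 0L) {
      L <- psd_factor(params$D[[k]])
      ZL <- eng$Z %*% L
      bk <- matrix(0, G, q)
      Ck <- matrix(0, G, q * q)
      for (g in seq_len(G)) {
        r <- eng$vals0[g, eng$rows[[g]]] - mu[eng$rows[[g]], k]
        ZLg <- ZL[eng$rows[[g]], , drop = FALSE]
        A <- crossprod(ZLg)
        S <- A + diag(s2, q)
        cS <- chol(S)
        t1 <- crossprod(ZLg, r)
        w <- backsolve(cS, t1, transpose = TRUE)
        n <- eng$n_g[g]
        logdens[g, k] <- -0.5 * (n * log(2 * pi) + (n - q) * log(s2) +
                                   2 * sum(log(diag(cS))) +
                                   (sum(r * r) - sum(w * w)) / s2)
        sol <- backsolve(cS, w)              # S^-1 t1
        bk[g, ] <- L %*% sol
        Sinv <- chol2inv(cS)
        Ck[g, ] <- as.vector(s2 * L %*% Sinv %*% t(L))
      }
      bhat[[k]] <- bk
      Cm[[k]] <- Ck
    } else {
      R <- eng$vals0 - matrix(mu[, k], G, eng$N, byrow = TRUE)
      rss <- rowSums((R * eng$M)^2)
      logdens[, k] <- -0.5 * (eng$n_g * log(2 * pi * s2) + rss / s2)
      bhat[[k]] <- matrix(0, G, 0L)
      Cm[[k]] <- matrix(0, G, 0L)
    }
  }
  logjoint <- sweep(logdens, 2L, log(params$pi), "+")
  mx <- apply(logjoint, 1L, max)
  lse <- mx + log(rowSums(exp(logjoint - mx)))
  posterior <- exp(logjoint - lse)
  if (hard_assign) {
    lab <- max.col(logjoint, ties.method = "first")
    posterior <- matrix(0, G, K)
    posterior[cbind(seq_len(G), lab)] <- 1
    loglik <- sum(logjoint[cbind(seq_len(G), lab)])
  } else {
    loglik <- sum(lse)
  }
  list(posterior = posterior, bhat = bhat, C = Cm, loglik = loglik,
       logdens = logdens, logjoint = logjoint)
}

# ---- M step ----------------------------------------------------------------

#' M step of the CLMM EM algorithm
#'
#' Closed-form complete-data maximisation given the E-step quantities:
#' weighted least squares for each cluster's coefficients (with the
#' conditional random-effect means subtracted from the working response),
#' the posterior-weighted second moment for D_k, and the posterior-weighted
#' mean squared working residual (plus the conditional-variance trace
#' correction) for sigma2_k.
#'
#' @param ds an [expression_dataset()].
#' @param spec the [design_spec()] used for the fit.
#' @param e_quantities output of [clmm_e_step()].
#' @param params current `clmm_params` (supplies K, pi and the mixture
#'   options embedded in the fit).
#' @param equal_proportions keep pi fixed at 1/K.
#' @param shared_sigma2 pool the residual variance across clusters.
#' @return An updated `clmm_params` object.
#' @export
clmm_m_step <- function(ds, spec, e_quantities, params,
                        equal_proportions = FALSE, shared_sigma2 = FALSE) {
  eng <- engine_prepare(ds, spec)
  engine_m_step(eng, e_quantities, params, equal_proportions, shared_sigma2)
}

SIGMA2_FLOOR <- 1e-8

engine_m_step <- function(eng, est, params, equal_proportions = FALSE,
                          shared_sigma2 = FALSE) {
  G <- eng$G; K <- params$K; q <- eng$q; p <- eng$p
  post <- est$posterior
  beta <- matrix(0, K, p)
  sigma2 <- numeric(K)
  D <- vector("list", K)
  ss_num <- numeric(K); ss_den <- numeric(K)
  for (k in seq_len(K)) {
    pk <- post[, k]
    wk <- drop(crossprod(eng$M, pk))         # per-observation weight sums
    XtWX <- crossprod(eng$X, eng$X * wk)
    Zb <- if (q > 0L) est$bhat[[k]] %*% t(eng$Z) else matrix(0, G, eng$N)
    Ek <- (eng$vals0 - Zb) * eng$M
    XtWy <- drop(crossprod(eng$X, drop(crossprod(Ek, pk))))
    bk <- tryCatch(solve(XtWX, XtWy), error = function(e)
      stop(sprintf(
        "singular weighted design for cluster %d (near-empty cluster)", k),
        call. = FALSE))
    beta[k, ] <- bk
    muk <- drop(eng$X %*% bk)
    Rk <- (eng$vals0 - matrix(muk, G, eng$N, byrow = TRUE) - Zb) * eng$M
    e2 <- rowSums(Rk^2)
    if (q > 0L) {
      trZCZ <- rowSums(est$C[[k]] * eng$Aflat)
      sw <- sum(pk)
      Dk <- (crossprod(est$bhat[[k]], est$bhat[[k]] * pk) +
               matrix(colSums(est$C[[k]] * pk), q, q)) / sw
      D[[k]] <- psd_project(Dk)
    } else {
      trZCZ <- 0
      D[[k]] <- matrix(0, 0L, 0L)
    }
    ss_num[k] <- sum(pk * (e2 + trZCZ))
    ss_den[k] <- sum(pk * eng$n_g)
  }
  if (shared_sigma2) {
    sigma2[] <- max(sum(ss_num) / sum(ss_den), SIGMA2_FLOOR)
  } else {
    sigma2 <- pmax(ss_num / ss_den, SIGMA2_FLOOR)
  }
  pi_new <- if (equal_proportions) rep(1 / K, K) else colMeans(post)
  new_clmm_params(K, pi_new, beta, D, sigma2, params$spec, params$conditions)
}

# ---- initialisation --------------------------------------------------------

# Replicate-averaged per-gene mean profiles with missing cells imputed by
# the gene's observed mean; used only to seed the EM.
init_profiles <- function(ds) {
  av <- average_replicates(ds)
  P <- av$profiles
  gm <- rowMeans(P, na.rm = TRUE)
  gm[is.nan(gm)] <- 0
  idx <- which(is.na(P), arr.ind = TRUE)
  if (nrow(idx)) P[idx] <- gm[idx[, 1L]]
  P
}

# Parameters from hard labels: one weighted-least-squares M step with the
# random effects at zero, then D_k seeded at sigma2_k * I so the random
# effects can move away from zero in the first E step.
init_params_from_labels <- function(eng, labels, K, equal_proportions,
                                    shared_sigma2) {
  G <- eng$G; q <- eng$q
  post <- matrix(0, G, K)
  post[cbind(seq_len(G), labels)] <- 1
  est0 <- list(posterior = post,
               bhat = rep(list(matrix(0, G, q)), K),
               C = rep(list(matrix(0, G, q * q)), K))
  params0 <- new_clmm_params(K, rep(1 / K, K),
                             matrix(0, K, eng$p),
                             rep(list(diag(1, q)), K),
                             rep(1, K))
  params <- engine_m_step(eng, est0, params0, equal_proportions, shared_sigma2)
  if (q > 0L)
    params$D <- lapply(seq_len(K), function(k) diag(params$sigma2[k], q))
  params
}

# ---- driver ----------------------------------------------------------------

#' Fit a mixture of linear (mixed) models by EM
#'
#' Fits the K-component CLMM (or CLM when the design has no random
#' effects) to an expression dataset.  Initialisation runs Lloyd's K-means
#' on replicate-averaged, mean-imputed gene profiles from seeded random
#' centers, takes one M step from the resulting hard labels, then iterates
#' E and M steps until the relative log-likelihood change falls below
#' `tol`.  The best of `n_restarts` seeded restarts (by final
#' log-likelihood; ties to the lowest restart index) is returned.
#'
#' @param ds an [expression_dataset()]; every gene must have at least p
#'   observed entries, where p is the fixed-design width.
#' @param spec a [design_spec()].
#' @param K number of clusters.
#' @param n_restarts number of seeded restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer seed controlling all initialisation randomness.
#' @param equal_proportions fix the mixture proportions at 1/K.
#' @param shared_sigma2 pool the residual variance across clusters.
#' @param hard_assign run classification EM: posterior rows are collapsed
#'   to MAP indicators before each M step, and the trace records the
#'   classification log-likelihood.
#' @param init optional list with `labels` (length-G integer) or `centers`
#'   (K x p coefficient matrix) fixing the initialisation; implies a
#'   single restart.
#' @return An object of class `clmm_fit`: `params` (`clmm_params`),
#'   `posterior` (G x K), `map_labels`, `blups` (list with `bhat` G x q for
#'   each gene's MAP cluster and `cov`, the q x q conditional covariances),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `restart`, `seed`,
#'   `options`, and the `spec` and gene identifiers needed downstream.
#' @export
fit_clmm <- function(ds, spec, K, n_restarts = 10L, max_iter = 500L,
                     tol = 1e-6, seed = 1L, equal_proportions = FALSE,
                     shared_sigma2 = FALSE, hard_assign = FALSE,
                     init = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), K >= 1L)
  eng <- engine_prepare(ds, spec)
  validate_gene_support(ds, eng$p)
  if (K > eng$G) stop("K exceeds the number of genes")
  if (!is.null(init)) n_restarts <- 1L
  best <- NULL
  for (r in seq_len(n_restarts)) {
    labels0 <- NULL; centers0 <- NULL
    if (!is.null(init)) {
      labels0 <- init$labels
      centers0 <- init$centers
    } else {
      P <- init_profiles(ds)
      km <- lloyd_kmeans(P, K, init_centers = seeded_centers(P, K, seed, r),
                         max_iter = 50L)
      labels0 <- km$labels
    }
    if (!is.null(centers0)) {
      params <- new_clmm_params(K, rep(1 / K, K), centers0,
                                rep(list(diag(1, eng$q)), K), rep(1, K))
      if (eng$q > 0L)
        params$D <- rep(list(diag(1, eng$q)), K)
    } else {
      params <- init_params_from_labels(eng, labels0, K, equal_proportions,
                                        shared_sigma2)
    }
    run <- em_run(eng, params, K, max_iter, tol, equal_proportions,
                  shared_sigma2, hard_assign)
    if (is.null(run)) next
    if (is.null(best) || run$loglik > best$loglik + 1e-12) {
      best <- run
      best$restart <- r
    }
  }
  if (is.null(best))
    stop("all EM restarts degenerated; no fit obtained")
  finalize_fit(eng, best, seed, spec,
               list(n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                    equal_proportions = equal_proportions,
                    shared_sigma2 = shared_sigma2, hard_assign = hard_assign))
}

# One EM run from given parameters; returns NULL if it degenerates.
em_run <- function(eng, params, K, max_iter, tol, equal_proportions,
                   shared_sigma2, hard_assign) {
  trace <- numeric(0)
  reseeds <- 0L
  est <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    est <- engine_e_step(eng, params, hard_assign)
    empty <- which(colSums(est$posterior) < 1)
    if (length(empty)) {
      reseeds <- reseeds + 1L
      if (reseeds >= 3L) return(NULL)
      params <- reseed_clusters(eng, params, est, empty)
      est <- engine_e_step(eng, params, hard_assign)
      if (any(colSums(est$posterior) < 1)) return(NULL)
    }
    trace <- c(trace, est$loglik)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (abs(est$loglik - prev) < tol * (abs(prev) + 1e-10)) {
        converged <- TRUE
        break
      }
    }
    params <- engine_m_step(eng, est, params, equal_proportions,
                            shared_sigma2)
  }
  list(params = params, est = est, loglik = est$loglik, trace = trace,
       n_iter = length(trace), converged = converged)
}

# Re-seed emptied clusters from the genes with the lowest MAP joint log
# density (the worst-fit genes); the cluster's coefficients become that
# gene's own least-squares fit.
reseed_clusters <- function(eng, params, est, empty) {
  fitq <- apply(est$logjoint, 1L, max)
  ord <- order(fitq)
  for (i in seq_along(empty)) {
    g <- ord[i]
    k <- empty[i]
    Xg <- eng$X[eng$rows[[g]], , drop = FALSE]
    yg <- eng$vals0[g, eng$rows[[g]]]
    cf <- qr.coef(qr(Xg), yg)
    cf[is.na(cf)] <- 0
    params$beta[k, ] <- cf
  }
  params
}

finalize_fit <- function(eng, run, seed, spec, options) {
  G <- eng$G
  est <- run$est
  lab <- max.col(est$posterior, ties.method = "first")
  q <- eng$q
  bhat <- matrix(0, G, q)
  covs <- vector("list", G)
  for (g in seq_len(G)) {
    k <- lab[g]
    if (q > 0L) {
      bhat[g, ] <- est$bhat[[k]][g, ]
      covs[[g]] <- matrix(est$C[[k]][g, ], q, q)
    } else {
      covs[[g]] <- matrix(0, 0L, 0L)
    }
  }
  rownames(bhat) <- eng$ds$genes
  params <- run$params
  params$spec <- spec
  params$conditions <- eng$conditions
  structure(list(params = params,
                 posterior = structure(est$posterior,
                                       dimnames = list(eng$ds$genes, NULL)),
                 map_labels = structure(lab, names = eng$ds$genes),
                 blups = list(bhat = bhat, cov = covs),
                 loglik = run$loglik, loglik_trace = run$trace,
                 n_iter = run$n_iter, converged = run$converged,
                 restart = run$restart, seed = seed, spec = spec,
                 genes = eng$ds$genes, options = options),
            class = "clmm_fit")
}

#' @export
print.clmm_fit <- function(x, ...) {
  cat(sprintf(
    "clmm_fit: K = %d, %d genes, loglik = %.4f (%d iterations%s, restart %d)\n",
    x$params$K, length(x$genes), x$loglik, x$n_iter,
    if (x$converged) ", converged" else "", x$restart))
  cat("cluster sizes:", paste(tabulate(x$map_labels, x$params$K),
                              collapse = " "), "\n")
  invisible(x)
}

#' Best linear unbiased prediction of a gene's random effects
#'
#' Returns the conditional mean of the gene's random-effect vector given
#' its data, under its MAP cluster's parameters.
#'
#' @param fit a `clmm_fit`.
#' @param gene gene identifier or index.
#' @return Numeric q-vector.
#' @export
blup <- function(fit, gene) {
  stopifnot(inherits(fit, "clmm_fit"))
  g <- if (is.character(gene)) match(gene, fit$genes) else as.integer(gene)
  if (is.na(g) || g < 1L || g > length(fit$genes))
    stop("unknown gene: ", gene)
  fit$blups$bhat[g, ]
}

#' Classify a new gene under a fitted model
#'
#' Applies the fitted mixture as an explicit prediction rule: the
#' posterior membership probabilities of a new gene, measured on a
#' (possibly partial) set of observations, are computed from the frozen
#' parameters without refitting.
#'
#' @param params a `clmm_params` object (e.g. `fit$params`).
#' @param y numeric vector of the new gene's observed values.
#' @param design the new gene's design (list with `X` and `Z`), conformable
#'   with `params`.
#' @return A list with `posterior` (K-vector) and `map` (MAP cluster,
#'   ties to the lowest index).
#' @export
predict_new_gene <- function(params, y, design) {
  stopifnot(inherits(params, "clmm_params"))
  K <- params$K
  ll <- vapply(seq_len(K), function(k)
    marginal_loglik_gene(y, design, k, params), numeric(1))
  lj <- ll + log(params$pi)
  post <- exp(lj - max(lj))
  post <- post / sum(post)
  list(posterior = post, map = which.max(post))
}

#' Fitted cluster mean profiles
#'
#' Evaluates each cluster's fitted mean curve for one condition on a time
#' grid: the B-spline basis at the grid times multiplied by the condition's
#' block of the cluster coefficients.
#'
#' @param params a `clmm_params` (or a `clmm_fit`, whose params are used).
#' @param condition condition label; ignored unless the fit used
#'   condition blocking.
#' @param times numeric grid within the design's time range.
#' @return Numeric `length(times)` x K matrix, one column per cluster.
#' @export
fitted_cluster_profile <- function(params, condition = NULL, times) {
  if (inherits(params, "clmm_fit")) params <- params$params
  stopifnot(inherits(params, "clmm_params"))
  spec <- params$spec
  if (is.null(spec)) stop("params carry no design spec")
  if (spec$basis == "identity")
    stop("fitted profiles require a spline basis")
  B <- bspline_basis(times, spec)
  conds <- params$conditions
  if (spec$condition_blocking && length(conds) > 1L) {
    if (is.null(condition)) stop("condition required for a blocked design")
    ci <- match(condition, conds)
    if (is.na(ci)) stop("unknown condition: ", condition)
    cols <- (ci - 1L) * ncol(B) + seq_len(ncol(B))
  } else {
    cols <- seq_len(ncol(B))
  }
  prof <- B %*% t(params$beta[, cols, drop = FALSE])
  colnames(prof) <- paste0("cluster", seq_len(params$K))
  prof
}
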
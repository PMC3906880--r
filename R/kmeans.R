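#' Average technical replicates into per-gene profiles
#'
#' K-means cannot use replicated longitudinal profiles directly, so a
#' gene's replicate measurements at each (condition, time) are averaged
#' first.  Cells missing in every replicate stay missing (`NA`).
#'
#' @param ds an [expression_dataset()].
#' @return A list with `profiles` (G x n matrix, n = number of distinct
#'   (condition, time) pairs, in canonical order) and `meta` (data frame
#'   with the `condition` and `time` of each profile column).
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  obs <- ds$observations
  key <- paste(obs$condition, obs$time, sep = "\r")
  ukey <- unique(key)
  grp <- match(key, ukey)
  G <- length(ds$genes)
  vals0 <- ds$values
  vals0[!ds$mask] <- 0
  M <- ds$mask * 1
  sums <- vals0 %*% outer(grp, seq_along(ukey), "==")
  cnts <- M %*% outer(grp, seq_along(ukey), "==")
  profiles <- sums / cnts
  profiles[cnts == 0] <- NA_real_
  first <- !duplicated(key)
  meta <- data.frame(condition = obs$condition[first],
                     time = obs$time[first], stringsAsFactors = FALSE)
  dimnames(profiles) <- list(ds$genes,
                             paste(meta$condition, meta$time, sep = "_"))
  list(profiles = profiles, meta = meta)
}

# Seeded initial centers: K distinct random rows of the profile matrix.
seeded_centers <- function(profiles, K, seed, restart = 1L) {
  rs <- (as.integer(seed) * 1009L + restart * 7919L) %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(rs)
  profiles[sample.int(nrow(profiles), K), , drop = FALSE]
}

# Lloyd's algorithm from explicit initial centers or labels.
# Distance ties and an emptied cluster are handled exactly as the
# classification-EM counterpart: ties go to the lowest cluster index and an
# empty cluster is re-seeded from the gene farthest from its assigned
# center.
lloyd_kmeans <- function(profiles, K, init_centers = NULL, init_labels = NULL,
                         max_iter = 100L) {
  G <- nrow(profiles)
  n <- ncol(profiles)
  tP <- t(profiles)
  assign_step <- function(centers) {
    d2 <- vapply(seq_len(K), function(k)
      colSums((tP - centers[k, ])^2), numeric(G))
    d2 <- matrix(d2, G, K)
    list(labels = max.col(-d2, ties.method = "first"), d2 = d2)
  }
  update_step <- function(labels, d2) {
    centers <- matrix(0, K, n)
    for (k in seq_len(K)) {
      members <- labels == k
      if (!any(members)) {
        far <- which.max(d2[cbind(seq_len(G), labels)])
        centers[k, ] <- profiles[far, ]
      } else {
        centers[k, ] <- colMeans(profiles[members, , drop = FALSE])
      }
    }
    centers
  }
  if (is.null(init_centers)) {
    if (is.null(init_labels)) stop("initial centers or labels required")
    labels <- as.integer(init_labels)
    d2 <- matrix(0, G, K)
    centers <- update_step(labels, d2)
  } else {
    centers <- as.matrix(init_centers)
  }
  labels <- rep(0L, G)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    a <- assign_step(centers)
    if (identical(a$labels, labels) || iter > max_iter) {
      labels <- a$labels
      d2 <- a$d2
      break
    }
    labels <- a$labels
    centers <- update_step(labels, a$d2)
  }
  wss <- sum(a$d2[cbind(seq_len(G), labels)])
  list(labels = labels, centers = update_step(labels, a$d2),
       within_ss = wss, n_iter = iter)
}

#' Lloyd's K-means on gene profiles
#'
#' Standard K-means on a complete profile matrix (typically from
#' [average_replicates()]): iterate assignment to the nearest center
#' (Euclidean; ties to the lowest cluster index) and center recalculation
#' until the labels stabilise.  The best of `n_restarts` seeded random
#' starts by total within-cluster sum of squares is kept.
#'
#' @param profiles numeric G x n matrix with no missing values.
#' @param K number of clusters (K <= G).
#' @param n_restarts seeded restarts (ignored when `init` is given).
#' @param max_iter maximum Lloyd iterations.
#' @param seed integer seed for the random starts.
#' @param init optional list with `centers` (K x n) or `labels` (length G)
#'   fixing the initialisation; implies a single run.
#' @return An object of class `kmeans_fit`: `centers`, `labels`,
#'   `within_ss`, `n_iter`, `seed`.
#' @export
fit_kmeans <- function(profiles, K, n_restarts = 10L, max_iter = 100L,
                       seed = 1L, init = NULL) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles))
    stop("profiles contain missing cells; complete or drop them first ",
         "(see complete_profiles)")
  if (K > nrow(profiles)) stop("K exceeds the number of genes")
  best <- NULL
  if (!is.null(init)) n_restarts <- 1L
  for (r in seq_len(n_restarts)) {
    if (!is.null(init)) {
      run <- lloyd_kmeans(profiles, K, init_centers = init$centers,
                          init_labels = init$labels, max_iter = max_iter)
    } else {
      run <- lloyd_kmeans(profiles, K,
                          init_centers = seeded_centers(profiles, K, seed, r),
                          max_iter = max_iter)
    }
    if (is.null(best) || run$within_ss < best$within_ss - 1e-12) {
      best <- run
      best$restart <- r
    }
  }
  structure(list(centers = best$centers,
                 labels = structure(best$labels,
                                    names = rownames(profiles)),
                 within_ss = best$within_ss, n_iter = best$n_iter,
                 restart = best$restart, seed = seed),
            class = "kmeans_fit")
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat(sprintf("kmeans_fit: K = %d, %d genes, within-SS = %.4f\n",
              nrow(x$centers), length(x$labels), x$within_ss))
  invisible(x)
}

#' Resolve missing cells in a profile matrix
#'
#' @param profiles G x n matrix possibly containing `NA`.
#' @param method `"drop"` removes columns with any missing cell (default);
#'   `"impute"` replaces missing cells by the column mean.
#' @return A complete matrix (for `"drop"`, possibly with fewer columns).
#' @export
complete_profiles <- function(profiles, method = c("drop", "impute")) {
  method <- match.arg(method)
  if (!anyNA(profiles)) return(profiles)
  if (method == "drop") {
    keep <- colSums(is.na(profiles)) == 0L
    profiles[, keep, drop = FALSE]
  } else {
    for (j in seq_len(ncol(profiles))) {
      miss <- is.na(profiles[, j])
      if (any(miss)) profiles[miss, j] <- mean(profiles[!miss, j])
    }
    profiles
  }
}

#' K-means as a classification-EM mixture fit
#'
#' Fits the degenerate mixture model that underlies K-means — Gaussian
#' components with a common scalar covariance, equal mixture proportions,
#' and hard (classification) assignments — by running the CLMM EM engine
#' with a saturated identity design, no random effects, shared residual
#' variance, fixed proportions, and hard assignment.  With matched
#' initialisation this reproduces Lloyd's K-means exactly.
#'
#' @param profiles numeric G x n complete matrix.
#' @param K number of clusters.
#' @param n_restarts,max_iter,seed,init as in [fit_kmeans()]; `init$centers`
#'   is the K x n center matrix used as initial component means.
#' @return A `kmeans_fit` (labels, centers, within-SS) with the underlying
#'   `clmm_fit` attached as attribute `clmm`.
#' @export
kmeans_as_classification_em <- function(profiles, K, n_restarts = 10L,
                                        max_iter = 100L, seed = 1L,
                                        init = NULL) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles))
    stop("profiles contain missing cells; complete or drop them first")
  n <- ncol(profiles)
  genes <- rownames(profiles)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(profiles)))
  # one observation per profile position (distinct times, one replicate) so
  # that replicate-averaging in the default initialisation is the identity
  obs <- data.frame(condition = "all", replicate = "r1", time = seq_len(n))
  ds <- expression_dataset(profiles, obs, genes)
  spec <- design_spec(random_design = "none", basis = "identity",
                      time_range = c(0, n + 1))
  cinit <- NULL
  if (!is.null(init)) {
    cinit <- if (!is.null(init$centers)) list(centers = as.matrix(init$centers))
             else list(labels = as.integer(init$labels))
  }
  # tol near machine precision: the classification likelihood is exactly
  # stationary once the labels stop changing, so this stops at the Lloyd
  # fixed point and not before
  fit <- fit_clmm(ds, spec, K, n_restarts = n_restarts,
                  max_iter = max_iter + 2L, tol = 1e-14,
                  seed = seed, equal_proportions = TRUE, shared_sigma2 = TRUE,
                  hard_assign = TRUE, init = cinit)
  centers <- fit$params$beta
  labels <- as.integer(fit$map_labels)
  d2 <- vapply(seq_len(K), function(k)
    colSums((t(profiles) - centers[k, ])^2), numeric(nrow(profiles)))
  d2 <- matrix(d2, nrow(profiles), K)
  wss <- sum(d2[cbind(seq_len(nrow(profiles)), labels)])
  structure(list(centers = centers,
                 labels = structure(labels, names = genes),
                 within_ss = wss, n_iter = fit$n_iter,
                 restart = fit$restart, seed = seed,
                 sigma2 = fit$params$sigma2[1]),
            class = "kmeans_fit", clmm = fit)
}
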
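#' Write a fit artifact
#'
#' Serialises a `clmm_fit` or `kmeans_fit` to a JSON artifact holding the
#' design spec, parameters, labels, posteriors, log-likelihood trace, seed
#' and options — everything needed to reload the model and classify new
#' genes without refitting.
#'
#' @param fit a `clmm_fit` or `kmeans_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_artifact <- function(fit, path) {
  if (inherits(fit, "clmm_fit")) {
    obj <- list(
      model = "clmm",
      spec = unclass(fit$spec),
      params = list(K = fit$params$K, pi = fit$params$pi,
                    beta = fit$params$beta,
                    D = fit$params$D, sigma2 = fit$params$sigma2,
                    conditions = fit$params$conditions),
      genes = fit$genes,
      map_labels = as.integer(fit$map_labels),
      posterior = fit$posterior,
      blups = fit$blups$bhat,
      loglik = fit$loglik, loglik_trace = fit$loglik_trace,
      n_iter = fit$n_iter, converged = fit$converged,
      restart = fit$restart, seed = fit$seed, options = fit$options)
  } else if (inherits(fit, "kmeans_fit")) {
    obj <- list(model = "kmeans", centers = fit$centers,
                genes = names(fit$labels),
                map_labels = as.integer(fit$labels),
                within_ss = fit$within_ss, n_iter = fit$n_iter,
                seed = fit$seed)
  } else stop("unsupported fit object")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a fit artifact
#'
#' @param path JSON artifact written by [write_fit_artifact()].
#' @return For a CLMM artifact, a list of class `clmm_fit` (parameters,
#'   labels, posterior, trace); for a K-means artifact, a `kmeans_fit`.
#' @export
read_fit_artifact <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$model, "kmeans")) {
    return(structure(list(centers = as.matrix(obj$centers),
                          labels = structure(as.integer(obj$map_labels),
                                             names = obj$genes),
                          within_ss = obj$within_ss, n_iter = obj$n_iter,
                          seed = obj$seed),
                     class = "kmeans_fit"))
  }
  sp <- obj$spec
  spec <- design_spec(degree = sp$degree,
                      n_interior_knots = sp$n_interior_knots,
                      time_range = sp$time_range,
                      condition_blocking = sp$condition_blocking,
                      random_design = sp$random_design, q = sp$q,
                      basis = sp$basis)
  K <- obj$params$K
  D <- obj$params$D
  if (is.null(D) || length(D) == 0L) {
    D <- rep(list(matrix(0, 0L, 0L)), K)
  } else if (is.array(D)) {
    # K x q x q array from JSON
    D <- lapply(seq_len(K), function(k)
      matrix(D[k, , ], dim(D)[2L], dim(D)[3L]))
  } else {
    D <- lapply(D, function(m) as.matrix(m))
  }
  params <- new_clmm_params(K, obj$params$pi,
                            matrix(as.matrix(obj$params$beta), K,
                                   ncol(as.matrix(obj$params$beta))),
                            D, obj$params$sigma2, spec,
                            obj$params$conditions)
  posterior <- as.matrix(obj$posterior)
  structure(list(params = params,
                 posterior = structure(posterior,
                                       dimnames = list(obj$genes, NULL)),
                 map_labels = structure(as.integer(obj$map_labels),
                                        names = obj$genes),
                 blups = list(bhat = as.matrix(obj$blups), cov = NULL),
                 loglik = obj$loglik, loglik_trace = obj$loglik_trace,
                 n_iter = obj$n_iter, converged = obj$converged,
                 restart = obj$restart, seed = obj$seed, spec = spec,
                 genes = obj$genes, options = obj$options),
            class = "clmm_fit")
}

#' Write cluster assignments as TSV
#'
#' One row per gene: MAP cluster and the posterior probabilities.
#'
#' @param fit a `clmm_fit`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(fit, path) {
  stopifnot(inherits(fit, "clmm_fit"))
  post <- fit$posterior
  colnames(post) <- paste0("posterior_", seq_len(ncol(post)))
  out <- data.frame(gene = fit$genes, map_cluster = as.integer(fit$map_labels),
                    post, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
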
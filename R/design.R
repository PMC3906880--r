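#' Design specification for time-course mixture fits
#'
#' Describes how observation metadata is turned into per-gene fixed and
#' random design matrices.  The fixed-effect design is a B-spline basis in
#' time (default: cubic with 7 equally spaced interior knots, the standard
#' flexible-but-not-overfitted choice for a 0-120 min course sampled every
#' 5 min), optionally blocked by condition so each condition gets its own
#' coefficient vector.  The random-effect design carries the gene-level
#' random effects that technical replicates of a condition share.
#'
#' @param degree spline degree (3 = cubic).
#' @param n_interior_knots number of equally spaced interior knots on the
#'   open interval of `time_range`.
#' @param time_range numeric length-2, the closed time interval covered by
#'   the basis (boundary knots).
#' @param condition_blocking if `TRUE`, the fixed design is block diagonal
#'   over conditions: rows of one condition are zero in the other
#'   conditions' blocks, so each condition has its own curve.
#' @param random_design one of `"none"` (no random effects; the CLM case),
#'   `"per-condition-intercept"` (one shared random intercept per
#'   condition, q = number of conditions; the minimal hierarchical
#'   structure for technical replicates), or `"basis-subset"` (random
#'   coefficients on the first `q` basis columns).
#' @param q number of random-effect columns for `"basis-subset"`.
#' @param basis one of `"bspline"` or `"identity"`.  The identity basis has
#'   one indicator column per observation position (a saturated,
#'   design-free mean); it is the degenerate design under which the
#'   classification-EM fit reduces to K-means.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(degree = 3L, n_interior_knots = 7L,
                        time_range = c(0, 120), condition_blocking = FALSE,
                        random_design = c("per-condition-intercept", "none",
                                          "basis-subset"),
                        q = 1L, basis = c("bspline", "identity")) {
  random_design <- match.arg(random_design)
  basis <- match.arg(basis)
  degree <- as.integer(degree)
  n_interior_knots <- as.integer(n_interior_knots)
  stopifnot(degree >= 0L, n_interior_knots >= 0L,
            length(time_range) == 2L, time_range[1] < time_range[2],
            q >= 1L)
  structure(list(degree = degree, n_interior_knots = n_interior_knots,
                 time_range = as.numeric(time_range),
                 condition_blocking = isTRUE(condition_blocking),
                 random_design = random_design, q = as.integer(q),
                 basis = basis),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "design_spec: %s basis, degree %d, %d interior knots on [%g, %g]%s; random: %s\n",
    x$basis, x$degree, x$n_interior_knots, x$time_range[1], x$time_range[2],
    if (x$condition_blocking) ", condition-blocked" else "", x$random_design))
  invisible(x)
}

#' Write / read a design specification as a YAML config
#'
#' @param spec a [design_spec()].
#' @param path config file path.
#' @return `write_design_spec` returns `path` invisibly; `read_design_spec`
#'   returns the [design_spec()].
#' @export
write_design_spec <- function(spec, path) {
  stopifnot(inherits(spec, "design_spec"))
  yaml::write_yaml(list(degree = spec$degree, knots = spec$n_interior_knots,
                        time_min = spec$time_range[1],
                        time_max = spec$time_range[2],
                        condition_blocking = spec$condition_blocking,
                        random_design = spec$random_design, q = spec$q,
                        basis = spec$basis),
                   path)
  invisible(path)
}

#' @rdname write_design_spec
#' @export
read_design_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  design_spec(degree = cfg$degree %||% 3L,
              n_interior_knots = cfg$knots %||% 7L,
              time_range = c(cfg$time_min %||% 0, cfg$time_max %||% 120),
              condition_blocking = cfg$condition_blocking %||% FALSE,
              random_design = cfg$random_design %||% "per-condition-intercept",
              q = cfg$q %||% 1L,
              basis = cfg$basis %||% "bspline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the B-spline time basis
#'
#' Full-rank B-spline basis (including the intercept span) of the given
#' degree with `n_interior_knots` equally spaced interior knots on
#' `time_range`; boundary knots sit at the range ends.  The basis is a
#' partition of unity (each row sums to 1) and spans constants, so a flat
#' profile is exactly representable.
#'
#' @param times numeric vector of evaluation times; must lie inside
#'   `spec$time_range`.
#' @param spec a [design_spec()].
#' @return Numeric matrix, `length(times)` x
#'   `(n_interior_knots + degree + 1)`.
#' @export
bspline_basis <- function(times, spec) {
  stopifnot(inherits(spec, "design_spec"))
  times <- as.numeric(times)
  lo <- spec$time_range[1]; hi <- spec$time_range[2]
  if (any(times < lo | times > hi))
    stop(sprintf("times outside the basis range [%g, %g]", lo, hi))
  m <- spec$n_interior_knots
  knots <- if (m > 0L) lo + (hi - lo) * seq_len(m) / (m + 1L) else numeric(0)
  if (spec$degree == 0L && m == 0L)
    return(matrix(1, length(times), 1L))
  B <- splines::bs(times, knots = knots, degree = spec$degree,
                   intercept = TRUE, Boundary.knots = c(lo, hi))
  B <- unclass(B)
  attributes(B)[setdiff(names(attributes(B)), "dim")] <- NULL
  B
}

# Internal: full fixed/random design over all N observations of a dataset,
# in the dataset's canonical observation order.  Per-gene designs are row
# subsets of these.
full_design <- function(ds, spec) {
  obs <- ds$observations
  conds <- sort(unique(obs$condition))
  if (spec$basis == "identity") {
    N <- nrow(obs)
    X <- diag(N)
    colnames(X) <- paste0("obs", seq_len(N))
  } else {
    B <- bspline_basis(obs$time, spec)
    if (spec$condition_blocking && length(conds) > 1L) {
      pb <- ncol(B)
      X <- matrix(0, nrow(obs), pb * length(conds))
      for (ci in seq_along(conds)) {
        rows <- obs$condition == conds[ci]
        X[rows, (ci - 1L) * pb + seq_len(pb)] <- B[rows, ]
      }
      colnames(X) <- paste(rep(conds, each = pb), rep(seq_len(pb), length(conds)),
                           sep = ".b")
    } else {
      X <- B
      colnames(X) <- paste0("b", seq_len(ncol(B)))
    }
  }
  Z <- switch(spec$random_design,
    "none" = matrix(0, nrow(obs), 0L),
    "per-condition-intercept" = {
      Z <- sapply(conds, function(cc) as.numeric(obs$condition == cc))
      Z <- matrix(Z, nrow(obs), length(conds),
                  dimnames = list(NULL, conds))
      Z
    },
    "basis-subset" = {
      if (spec$basis == "identity")
        stop("basis-subset random design requires a spline basis")
      Bq <- bspline_basis(obs$time, spec)[, seq_len(spec$q), drop = FALSE]
      colnames(Bq) <- paste0("rb", seq_len(spec$q))
      Bq
    })
  list(X = X, Z = Z, p = ncol(X), q = ncol(Z), conditions = conds)
}

#' Build per-gene design matrices
#'
#' For each gene, stacks the fixed-effect basis rows and random-effect rows
#' corresponding to that gene's observed (unmasked) entries, in canonical
#' observation order.  Both technical replicates of a condition share
#' identical basis rows; the gene-level random effect (columns of `Z_g`)
#' is shared across all of the gene's observations, which is how
#' replication enters the model hierarchically.
#'
#' @param ds an [expression_dataset()].
#' @param spec a [design_spec()].
#' @return A list with one element per gene, each a list with `X` (n_g x p),
#'   `Z` (n_g x q) and `n` (the gene's observed entry count), plus
#'   attributes `p`, `q` and `conditions`.
#' @export
build_designs <- function(ds, spec) {
  stopifnot(inherits(ds, "expression_dataset"))
  fd <- full_design(ds, spec)
  out <- lapply(seq_along(ds$genes), function(g) {
    rows <- which(ds$mask[g, ])
    list(X = fd$X[rows, , drop = FALSE],
         Z = fd$Z[rows, , drop = FALSE],
         n = length(rows))
  })
  names(out) <- ds$genes
  attr(out, "p") <- fd$p
  attr(out, "q") <- fd$q
  attr(out, "conditions") <- fd$conditions
  out
}

# Internal: error if any gene has fewer observed entries than the fixed
# design width; names the offending genes.
validate_gene_support <- function(ds, p) {
  n_g <- rowSums(ds$mask)
  bad <- which(n_g < p)
  if (length(bad))
    stop("gene(s) with fewer observed entries than design columns (p = ", p,
         "): ", paste(ds$genes[bad], collapse = ", "))
  invisible(n_g)
}
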
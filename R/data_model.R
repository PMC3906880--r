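#' Construct an expression dataset
#'
#' Container for gene-by-observation expression values (log-ratio scale)
#' together with the observation metadata that describes the experimental
#' design: the condition (e.g. genotype), the technical replicate within
#' condition, and the measurement time in minutes.  Missing entries are
#' carried by a logical mask, never by sentinel numbers; all downstream
#' likelihoods use row deletion on masked entries (missing-at-random).
#'
#' Observations are canonicalised to (condition, replicate, time)
#' lexicographic order so that design matrices and fits are reproducible
#' regardless of input row order.
#'
#' @param values numeric G x N matrix, genes in rows.  `NA` entries are
#'   treated as missing (mask set to `FALSE`).
#' @param observations data frame with columns `condition`, `replicate`,
#'   `time`; one row per column of `values`.
#' @param genes character vector of G gene identifiers; defaults to the
#'   rownames of `values`.
#' @param mask optional logical G x N matrix, `TRUE` = observed.  Combined
#'   (AND) with non-`NA`-ness of `values`.
#' @return An object of class `expression_dataset` with elements `genes`,
#'   `observations`, `values` and `mask`.
#' @export
expression_dataset <- function(values, observations, genes = rownames(values),
                               mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  genes <- as.character(genes)
  stopifnot(nrow(values) >= 1L, ncol(values) >= 1L,
            length(genes) == nrow(values))
  if (anyDuplicated(genes)) stop("duplicated gene identifiers")
  obs <- as.data.frame(observations)
  req <- c("condition", "replicate", "time")
  miss <- setdiff(req, names(obs))
  if (length(miss))
    stop("observation metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(obs) != ncol(values))
    stop("observation metadata rows must match value columns")
  obs$condition <- as.character(obs$condition)
  obs$replicate <- as.character(obs$replicate)
  obs$time <- as.numeric(obs$time)
  if (any(obs$time < 0)) stop("observation times must be >= 0")
  key <- paste(obs$condition, obs$replicate, obs$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate, time) observation")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask) & !is.na(values)
  if (!identical(dim(mask), dim(values)))
    stop("mask dimensions must match values")
  ord <- order(obs$condition, obs$replicate, obs$time)
  obs <- obs[ord, req, drop = FALSE]
  rownames(obs) <- NULL
  values <- values[, ord, drop = FALSE]
  mask <- mask[, ord, drop = FALSE]
  values[!mask] <- NA_real_
  dimnames(values) <- list(genes, NULL)
  dimnames(mask) <- list(genes, NULL)
  structure(list(genes = genes, observations = obs,
                 values = values, mask = mask),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d observations (%d conditions, %d masked cells)\n",
    length(x$genes), nrow(x$observations),
    length(unique(x$observations$condition)), sum(!x$mask)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read a long-format expression table
#'
#' Reads delimited text with one row per (gene, condition, replicate, time)
#' measurement.  Empty or `NA` values become masked entries; a repeated
#' (gene, condition, replicate, time) cell is an error.
#'
#' @param path file path to a TSV/CSV file.
#' @param columns named character vector mapping the roles
#'   `gene`, `condition`, `replicate`, `time`, `value` to column names in
#'   the file.
#' @param sep field separator; guessed from the file extension
#'   (`.csv` = comma, otherwise tab) when `NULL`.
#' @return An [expression_dataset()].
#' @export
read_long_table <- function(path,
                            columns = c(gene = "gene", condition = "condition",
                                        replicate = "replicate", time = "time",
                                        value = "value"),
                            sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  def <- c(gene = "gene", condition = "condition", replicate = "replicate",
           time = "time", value = "value")
  def[names(columns)] <- columns
  missing_cols <- def[!def %in% names(tab)]
  if (length(missing_cols))
    stop("required column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  long <- data.frame(gene = tab[[def[["gene"]]]],
                     condition = tab[[def[["condition"]]]],
                     replicate = tab[[def[["replicate"]]]],
                     time = as.numeric(tab[[def[["time"]]]]),
                     value = as.numeric(tab[[def[["value"]]]]),
                     stringsAsFactors = FALSE)
  long_to_dataset(long)
}

# Assemble an expression_dataset from a long data frame
# (gene, condition, replicate, time, value); duplicates rejected.
long_to_dataset <- function(long) {
  okey <- paste(long$condition, long$replicate, long$time, sep = "\r")
  if (anyDuplicated(paste(long$gene, okey, sep = "\r")))
    stop("duplicate (gene, condition, replicate, time) row")
  genes <- unique(long$gene)
  ouniq <- !duplicated(okey)
  obs <- data.frame(condition = long$condition[ouniq],
                    replicate = long$replicate[ouniq],
                    time = long$time[ouniq], stringsAsFactors = FALSE)
  okeys <- okey[ouniq]
  values <- matrix(NA_real_, length(genes), length(okeys),
                   dimnames = list(genes, NULL))
  values[cbind(match(long$gene, genes), match(okey, okeys))] <- long$value
  expression_dataset(values, obs, genes)
}

#' Write a dataset as a long-format table
#'
#' Inverse of [read_long_table()]: masked cells are written with an empty
#' value field so that a read/write cycle round-trips values and mask.
#'
#' @param ds an [expression_dataset()].
#' @param path output file path (`.csv` = comma separated, else tab).
#' @return `path`, invisibly.
#' @export
write_long_table <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  G <- length(ds$genes); N <- nrow(ds$observations)
  long <- data.frame(
    gene = rep(ds$genes, each = N),
    condition = rep(ds$observations$condition, G),
    replicate = rep(ds$observations$replicate, G),
    time = rep(ds$observations$time, G),
    value = as.vector(t(ds$values)),
    stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(long, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a wide expression matrix with an observation-metadata table
#'
#' @param values_path delimited file: first column gene identifiers,
#'   remaining columns one per observation.
#' @param obs_path delimited file with columns `condition`, `replicate`,
#'   `time`, one row per observation column (in column order).
#' @param sep separator for both files; guessed from `values_path` when
#'   `NULL`.
#' @return An [expression_dataset()].
#' @export
read_wide_matrix <- function(values_path, obs_path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", values_path, ignore.case = TRUE)) "," else "\t"
  wide <- utils::read.table(values_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  obs <- utils::read.table(obs_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(wide[[1L]])
  values <- as.matrix(wide[, -1L, drop = FALSE])
  expression_dataset(values, obs, genes)
}

#' Remove bad time points
#'
#' Deletes every observation matching one of the (condition, time) pairs,
#' for all genes; used for time points lost to technical problems (sample
#' loss, poor hybridisation).
#'
#' @param ds an [expression_dataset()].
#' @param removals data frame with columns `condition` and `time` (or a
#'   named list coercible to one); each row names one bad time point.
#' @return The reduced [expression_dataset()].
#' @export
drop_bad_timepoints <- function(ds, removals) {
  stopifnot(inherits(ds, "expression_dataset"))
  removals <- as.data.frame(removals)
  if (nrow(removals) == 0L) return(ds)
  stopifnot(all(c("condition", "time") %in% names(removals)))
  removals$condition <- as.character(removals$condition)
  unknown <- setdiff(removals$condition, ds$observations$condition)
  if (length(unknown))
    stop("removal names unknown condition(s): ", paste(unknown, collapse = ", "))
  bad <- paste(ds$observations$condition, ds$observations$time, sep = "\r") %in%
    paste(removals$condition, as.numeric(removals$time), sep = "\r")
  keep <- !bad
  expression_dataset(ds$values[, keep, drop = FALSE],
                     ds$observations[keep, , drop = FALSE],
                     ds$genes, ds$mask[, keep, drop = FALSE])
}

#' Mask individual cells as missing
#'
#' Marks listed (gene, observation) cells as unobserved, e.g. measurements
#' judged to be technical outliers.  Values elsewhere are untouched.
#'
#' @param ds an [expression_dataset()].
#' @param cells two-column matrix or data frame of cell indices: gene
#'   (index or identifier) and observation index.
#' @return The dataset with the mask flipped to `FALSE` at the listed cells.
#' @export
mask_entries <- function(ds, cells) {
  stopifnot(inherits(ds, "expression_dataset"))
  cells <- as.data.frame(cells)
  if (nrow(cells) == 0L) return(ds)
  if (ncol(cells) != 2L) stop("cells must have two columns (gene, observation)")
  g <- cells[[1L]]
  if (is.character(g)) {
    g <- match(g, ds$genes)
    if (anyNA(g)) stop("unknown gene identifier in cells")
  }
  g <- as.integer(g)
  j <- as.integer(cells[[2L]])
  if (any(g < 1L | g > length(ds$genes)) ||
      any(j < 1L | j > nrow(ds$observations)))
    stop("cell index out of range")
  mask <- ds$mask
  mask[cbind(g, j)] <- FALSE
  expression_dataset(ds$values, ds$observations, ds$genes, mask)
}

# Internal: list of observed column indices per gene.
observed_index <- function(ds) {
  lapply(seq_along(ds$genes), function(g) which(ds$mask[g, ]))
}
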
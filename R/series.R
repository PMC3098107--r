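#' A single gene's expression time series
#'
#' Ordered (time, log2 level) measurements for one gene under one condition.
#'
#' @param gene_id Gene identifier (single string).
#' @param times Sampling times in hours, strictly increasing, length >= 3.
#' @param values Log2 expression levels, same length as `times`, finite.
#' @return An object of class `expression_series`.
#' @examples
#' expression_series("AT1G01010", c(0, 0.5, 1, 3, 6, 12, 24),
#'                   c(8, 8.1, 9.2, 10, 9.1, 8.2, 8.0))
#' @export
expression_series <- function(gene_id, times, values) {
  gene_id <- as.character(gene_id)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(gene_id) != 1L) stop("'gene_id' must be a single string",
                                  call. = FALSE)
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have the same length", call. = FALSE)
  }
  if (length(times) < 3L) stop("a series needs at least 3 time points",
                               call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  if (!all(is.finite(values))) stop("'values' must be finite", call. = FALSE)
  structure(list(gene_id = gene_id, times = times, values = values),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat("expression series", x$gene_id, "(", length(x$times), "time points )\n")
  m <- rbind(time_h = x$times, log2_level = signif(x$values, 4))
  print(m)
  invisible(x)
}

#' A gene-by-time expression matrix for one condition
#'
#' @param values Numeric genes x times matrix of log2 levels.
#' @param times Sampling times in hours (one per column), strictly increasing.
#' @param condition Condition label (e.g. `"control"`, `"heat"`).
#' @param gene_ids Gene identifiers; defaults to `rownames(values)`. Must be
#'   unique.
#' @param replicates Optional list of same-shape matrices holding the
#'   individual repeat measurements before averaging (used by
#'   [estimate_noise_threshold()]).
#' @return An object of class `expression_matrix` with fields `condition`,
#'   `gene_ids`, `times`, `values`, `replicates`.
#' @export
expression_matrix <- function(values, times, condition = "",
                              gene_ids = rownames(values),
                              replicates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  times <- as.numeric(times)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%0*d", nchar(nrow(values)), seq_len(nrow(values)))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("one gene id per row is required", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(times) != ncol(values)) {
    stop("one time per column is required", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  if (!is.null(replicates)) {
    if (!is.list(replicates)) stop("'replicates' must be a list of matrices",
                                   call. = FALSE)
    for (r in replicates) {
      if (!identical(dim(as.matrix(r)), dim(values))) {
        stop("replicate matrices must match the shape of 'values'",
             call. = FALSE)
      }
    }
  }
  rownames(values) <- gene_ids
  colnames(values) <- format(times, trim = TRUE)
  structure(list(condition = as.character(condition), gene_ids = gene_ids,
                 times = times, values = values, replicates = replicates),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression matrix",
      if (nzchar(x$condition)) sprintf("'%s'", x$condition) else "",
      ":", nrow(x$values), "genes x", length(x$times), "time points",
      if (!is.null(x$replicates))
        sprintf("(%d replicates)", length(x$replicates)) else "", "\n")
  cat("times (h):", paste(x$times, collapse = ", "), "\n")
  invisible(x)
}

## extract one gene as an expression_series
matrix_series <- function(m, gene_id) {
  i <- match(gene_id, m$gene_ids)
  if (is.na(i)) stop("gene '", gene_id, "' not found", call. = FALSE)
  expression_series(gene_id, m$times, m$values[i, ])
}
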
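#' Correlation-network connectivity degree
#'
#' Correlates all temporal expression profiles of one condition against each
#' other (Pearson r over the condition's time points) and connects two genes
#' when their absolute correlation exceeds `r_threshold` (strictly). The
#' degree of a gene is its number of connections. Profiles with zero variance
#' have undefined correlation; their correlations are set to 0, so such genes
#' are isolated rather than propagating `NA`.
#'
#' @param m An [expression_matrix()] with at least 2 genes and 3 time points.
#' @param r_threshold Absolute-correlation threshold in (0, 1] (default 0.98).
#' @param edges If `TRUE`, also return the edge list with correlations.
#' @return A `degree_table`: list with `gene_ids`, `degree` (named integer
#'   vector), `condition`, `r_threshold`, and optionally `edges` (data frame
#'   `gene_a`, `gene_b`, `r`).
#' @examples
#' m <- expression_matrix(rbind(a = c(0, 1, 2, 3), b = c(1, 2, 3, 4),
#'                              c = c(4, 2, 7, 1)), 1:4, "demo")
#' correlation_degree(m)$degree
#' @export
correlation_degree <- function(m, r_threshold = 0.98, edges = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (length(m$times) < 3L) {
    stop("correlation over fewer than 3 time points is degenerate",
         call. = FALSE)
  }
  if (nrow(m$values) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (!is.numeric(r_threshold) || r_threshold <= 0 || r_threshold > 1) {
    stop("'r_threshold' must be in (0, 1]", call. = FALSE)
  }
  C <- suppressWarnings(stats::cor(t(m$values)))
  C[!is.finite(C)] <- 0          # zero-variance profiles: no edges
  diag(C) <- 0
  A <- abs(C) > r_threshold
  degree <- rowSums(A)
  names(degree) <- m$gene_ids
  out <- list(gene_ids = m$gene_ids, degree = degree,
              condition = m$condition, r_threshold = r_threshold)
  if (edges) {
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    out$edges <- data.frame(gene_a = m$gene_ids[idx[, 1L]],
                            gene_b = m$gene_ids[idx[, 2L]],
                            r = C[idx])
  }
  structure(out, class = "degree_table")
}

#' @export
print.degree_table <- function(x, ...) {
  cat(sprintf("correlation degree, condition '%s' (|r| > %g): %d genes\n",
              x$condition, x$r_threshold, length(x$degree)))
  print(summary(x$degree))
  invisible(x)
}

#' Mean entropy of high- versus low-degree genes
#'
#' Ranks genes by their correlation-network degree (ties broken by gene id)
#' and averages the permutation entropy over the top and bottom `q` fraction
#' of genes, per condition -- the comparison behind the observation that
#' network hubs carry more complex temporal profiles.
#'
#' @param d A `degree_table` from [correlation_degree()], or a list of them
#'   (one per condition).
#' @param tab A [pe_table()] containing each degree table's condition and
#'   genes.
#' @param q Stratum size as a fraction of the gene count, in (0, 0.5].
#' @return Data frame with one row per condition: `condition`,
#'   `mean_pe_high`, `mean_pe_low`, `n_stratum`.
#' @export
degree_stratified_pe <- function(d, tab, q = 0.2) {
  stopifnot(inherits(tab, "pe_table"))
  if (inherits(d, "degree_table")) d <- list(d)
  if (!is.numeric(q) || q <= 0 || q > 0.5) {
    stop("'q' must be in (0, 0.5]", call. = FALSE)
  }
  rows <- lapply(d, function(dt) {
    stopifnot(inherits(dt, "degree_table"))
    cond <- dt$condition
    if (!cond %in% tab$conditions) {
      stop("condition '", cond, "' is not in the PE table", call. = FALSE)
    }
    idx <- match(dt$gene_ids, tab$gene_ids)
    if (anyNA(idx)) {
      stop("degree table and PE table gene sets are misaligned",
           call. = FALSE)
    }
    pe <- tab$pe[idx, cond]
    n <- length(dt$degree)
    k <- floor(q * n)
    if (k < 1L) stop("stratum would be empty; increase 'q' or the gene count",
                     call. = FALSE)
    ord <- order(dt$degree, dt$gene_ids)
    low <- ord[seq_len(k)]
    high <- ord[seq.int(n - k + 1L, n)]
    data.frame(condition = cond,
               mean_pe_high = mean(pe[high]),
               mean_pe_low = mean(pe[low]),
               n_stratum = as.integer(k))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
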
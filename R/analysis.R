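#' Per-gene, per-condition permutation entropy table
#'
#' Computes the permutation entropy of every gene under every condition and
#' the per-gene sum over conditions (`pe_sum`), the statistic used to rank
#' genes from low to high overall temporal complexity.
#'
#' @param matrices A list of [expression_matrix()] objects (one per
#'   condition, sharing the same gene set) or a single matrix.
#' @param d_e Noise threshold, as in [encode_window()].
#' @return A `pe_table` object: list with `gene_ids`, `conditions`, `pe`
#'   (genes x conditions matrix), `pe_sum`, and `n_windows` (per condition).
#' @examples
#' m <- expression_matrix(rbind(a = c(0, 1, 2, 3, 4, 5, 6), b = rep(0, 7)),
#'                        c(0, 0.5, 1, 3, 6, 12, 24), "control")
#' pe_table(list(m))
#' @export
pe_table <- function(matrices, d_e = 0.35) {
  d_e <- as_d_e(d_e)
  if (inherits(matrices, "expression_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  conditions <- vapply(matrices, `[[`, character(1), "condition")
  if (any(!nzchar(conditions)) && !is.null(names(matrices))) {
    conditions[!nzchar(conditions)] <- names(matrices)[!nzchar(conditions)]
  }
  if (anyDuplicated(conditions)) {
    stop("condition labels must be unique", call. = FALSE)
  }
  ref <- matrices[[1L]]$gene_ids
  pe <- matrix(NA_real_, length(ref), length(matrices),
               dimnames = list(ref, conditions))
  n_windows <- integer(length(matrices))
  for (k in seq_along(matrices)) {
    m <- matrices[[k]]
    if (!setequal(m$gene_ids, ref) || length(m$gene_ids) != length(ref)) {
      stop("condition '", conditions[k],
           "' does not share the gene set of '", conditions[1L], "'",
           call. = FALSE)
    }
    values <- m$values[match(ref, m$gene_ids), , drop = FALSE]
    codes <- encode_matrix(values, d_e)
    n_windows[k] <- ncol(codes)
    pe[, k] <- apply(codes, 1L, function(r) {
      tb <- tabulate(r, 13L)
      p <- tb[tb > 0L] / length(r)
      -sum(p * log2(p))
    })
  }
  structure(list(gene_ids = ref, conditions = conditions, pe = pe,
                 pe_sum = rowSums(pe), n_windows = n_windows, d_e = d_e),
            class = "pe_table")
}

#' @export
print.pe_table <- function(x, ...) {
  cat("permutation entropy table:", length(x$gene_ids), "genes x",
      length(x$conditions), "condition(s), d_e =", x$d_e, "\n")
  cat("conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("pe_sum summary:\n")
  print(summary(x$pe_sum))
  invisible(x)
}

#' @describeIn pe_table Flatten to a data frame (one row per gene, one column
#'   per condition plus `pe_sum`).
#' @param x A `pe_table`.
#' @param ... Unused.
#' @export
as.data.frame.pe_table <- function(x, ...) {
  data.frame(gene_id = x$gene_ids, x$pe, pe_sum = x$pe_sum,
             check.names = FALSE, row.names = NULL)
}

#' Mann-Whitney-U (Wilcoxon rank-sum) test
#'
#' Nonparametric two-sample test used throughout the package because
#' permutation entropies take only a few discrete values, so tests assuming
#' continuity or normality are inappropriate. Ties are handled by mid-ranks.
#' For small samples the exact permutation null is enumerated (all
#' `choose(m+n, m)` group assignments, valid with ties); otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exhaustive enumeration;
#'   default `NULL` enumerates when `length(x) + length(y) <= 12`.
#' @return List with `statistic` (U for the first sample), `p.value`
#'   (two-sided), and `method`.
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))
#' @export
mwu_test <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  N <- m + n
  r <- rank(c(x, y))   # mid-ranks for ties
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (is.null(exact)) exact <- N <= 12L
  if (exact) {
    sets <- utils::combn(N, m)
    u_all <- colSums(matrix(r[sets], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact permutation null"
  } else {
    ties <- table(r)
    sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = u_obs, p.value = p, method = method)
}

#' Compare permutation entropy between two conditions
#'
#' Tests whether the entropy distribution shifts between a stress and the
#' control condition using the two-sided Mann-Whitney-U test on the two PE
#' columns, and reports the difference of means and of medians
#' (stress minus control) as descriptive effect sizes.
#'
#' @param tab A [pe_table()].
#' @param stress,control Condition labels present in `tab`.
#' @return A `pe_comparison` object: list with `stress`, `control`,
#'   `delta_mean`, `delta_median`, `statistic`, `p.value`, `n`.
#' @export
compare_conditions <- function(tab, stress, control) {
  stopifnot(inherits(tab, "pe_table"))
  for (cond in c(stress, control)) {
    if (!cond %in% tab$conditions) {
      stop("condition '", cond, "' is not in the table", call. = FALSE)
    }
  }
  xs <- tab$pe[, stress]
  xc <- tab$pe[, control]
  w <- mwu_test(xs, xc)
  structure(list(stress = stress, control = control,
                 delta_mean = mean(xs) - mean(xc),
                 delta_median = stats::median(xs) - stats::median(xc),
                 statistic = w$statistic, p.value = w$p.value,
                 n = length(xs)),
            class = "pe_comparison")
}

#' @export
print.pe_comparison <- function(x, ...) {
  cat(sprintf("PE shift %s - %s (n = %d genes)\n", x$stress, x$control, x$n))
  cat(sprintf("  delta mean = %.4g, delta median = %.4g\n",
              x$delta_mean, x$delta_median))
  cat(sprintf("  MWU U = %.4g, two-sided p = %.3g\n", x$statistic, x$p.value))
  invisible(x)
}

#' Compare a gene feature between top and bottom entropy-ranked groups
#'
#' Sorts genes by `pe_sum` (ties broken lexicographically by gene id),
#' extracts the `k` highest- and `k` lowest-entropy genes, and compares a
#' per-gene numeric feature (e.g. upstream intergenic distance or
#' cis-regulatory motif count) between the two groups with the two-sided MWU
#' test. Genes with missing feature values are dropped beforehand.
#'
#' @param tab A [pe_table()].
#' @param feature Numeric vector, either named by gene id or aligned with
#'   `tab$gene_ids`.
#' @param k Group size; `2 * k` must not exceed the number of genes with a
#'   feature value.
#' @return A `pe_group_comparison`: list with `top` and `bottom` summaries
#'   (`mean`, `sd`, `median`, `n`) and the MWU `p.value`.
#' @export
top_bottom_compare <- function(tab, feature, k) {
  stopifnot(inherits(tab, "pe_table"))
  if (!is.null(names(feature))) {
    feature <- feature[match(tab$gene_ids, names(feature))]
  }
  if (length(feature) != length(tab$gene_ids)) {
    stop("'feature' must align with the table's genes", call. = FALSE)
  }
  ok <- is.finite(feature)
  feature <- feature[ok]
  pe_sum <- tab$pe_sum[ok]
  ids <- tab$gene_ids[ok]
  n <- length(ids)
  k <- as.integer(k)
  if (2L * k > n) {
    stop("2 * k exceeds the number of genes with feature values",
         call. = FALSE)
  }
  ord <- order(pe_sum, ids)
  bottom <- ord[seq_len(k)]
  top <- ord[seq.int(n - k + 1L, n)]
  summ <- function(v) list(mean = mean(v), sd = stats::sd(v),
                           median = stats::median(v), n = length(v))
  w <- mwu_test(feature[top], feature[bottom])
  structure(list(top = summ(feature[top]), bottom = summ(feature[bottom]),
                 p.value = w$p.value, statistic = w$statistic, k = k),
            class = "pe_group_comparison")
}

#' @export
print.pe_group_comparison <- function(x, ...) {
  fmt <- function(s, lab) {
    cat(sprintf("  %s %d genes: %.4g +/- %.4g (median = %.4g)\n",
                lab, s$n, s$mean, s$sd, s$median))
  }
  cat("feature by PE_sum rank group:\n")
  fmt(x$top, "top   ")
  fmt(x$bottom, "bottom")
  cat(sprintf("  MWU two-sided p = %.3g\n", x$p.value))
  invisible(x)
}

#' Category enrichment in a gene selection (Fisher's exact test, BH-FDR)
#'
#' For every category, builds the 2x2 table (selected / not selected x in
#' category / not in category) over the background gene set, tests it with
#' the two-sided Fisher's exact test, and adjusts p-values across categories
#' by Benjamini-Hochberg false-discovery-rate correction.
#'
#' @param selected Character vector of selected gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param ann Annotation: a data frame whose first two columns are gene id
#'   and category label (one row per membership, genes may repeat), as read
#'   by [read_annotation()].
#' @return Data frame sorted by FDR with columns `category`, `selected_in`,
#'   `selected_out`, `rest_in`, `rest_out`, `direction` (`"over"` /
#'   `"under"`), `p`, `fdr`. Categories with no member in the background are
#'   omitted.
#' @export
enrichment <- function(selected, background, ann) {
  selected <- unique(as.character(selected))
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  if (!all(selected %in% background)) {
    stop("'selected' must be a subset of 'background'", call. = FALSE)
  }
  ann <- as.data.frame(ann)[, 1:2]
  names(ann) <- c("gene_id", "category")
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  cats <- sort(unique(as.character(ann$category)))
  if (length(cats) == 0L) {
    return(data.frame(category = character(0), selected_in = integer(0),
                      selected_out = integer(0), rest_in = integer(0),
                      rest_out = integer(0), direction = character(0),
                      p = numeric(0), fdr = numeric(0)))
  }
  n_sel <- length(selected)
  n_bg <- length(background)
  rows <- lapply(cats, function(cc) {
    members <- unique(ann$gene_id[ann$category == cc])
    a <- sum(selected %in% members)
    b <- n_sel - a
    c2 <- length(members) - a
    d2 <- (n_bg - n_sel) - c2
    p <- stats::fisher.test(matrix(c(a, b, c2, d2), 2L))$p.value
    rate_sel <- if (n_sel > 0) a / n_sel else 0
    rate_rest <- if (n_bg > n_sel) c2 / (n_bg - n_sel) else 0
    data.frame(category = cc, selected_in = a, selected_out = b,
               rest_in = c2, rest_out = d2,
               direction = if (rate_sel >= rate_rest) "over" else "under",
               p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$fdr, out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean permutation entropy per category and condition
#'
#' Averages the PE of the genes carrying each annotation label, per
#' condition; genes with several labels contribute to each of them.
#'
#' @inheritParams enrichment
#' @param tab A [pe_table()].
#' @return Numeric category x condition matrix of mean PE values.
#' @export
mean_pe_by_category <- function(tab, ann) {
  stopifnot(inherits(tab, "pe_table"))
  ann <- as.data.frame(ann)[, 1:2]
  names(ann) <- c("gene_id", "category")
  ann <- ann[ann$gene_id %in% tab$gene_ids, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotated genes in the table", call. = FALSE)
  cats <- sort(unique(as.character(ann$category)))
  out <- matrix(NA_real_, length(cats), length(tab$conditions),
                dimnames = list(cats, tab$conditions))
  for (cc in cats) {
    idx <- tab$gene_ids %in% ann$gene_id[ann$category == cc]
    out[cc, ] <- colMeans(tab$pe[idx, , drop = FALSE])
  }
  out
}

#' Bicluster a category-by-condition mean-entropy matrix
#'
#' Independent agglomerative hierarchical clustering (average linkage) of the
#' rows and of the columns of a numeric matrix, as used to co-cluster
#' functional categories and experimental conditions by their mean entropy.
#'
#' @param mat Numeric matrix with at least 2 rows and 2 columns.
#' @param distance `"euclidean"` (default) or `"correlation"` (1 - Pearson r).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A `pe_bicluster`: list with `row_order`, `col_order` (leaf
#'   orders), `row_tree`, `col_tree` ([stats::hclust] objects), and
#'   `reordered` (the input matrix in leaf order).
#' @export
bicluster <- function(mat, distance = c("euclidean", "correlation"),
                      linkage = "average") {
  distance <- match.arg(distance)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("biclustering needs at least 2 rows and 2 columns", call. = FALSE)
  }
  dfun <- function(m) {
    if (distance == "euclidean") stats::dist(m)
    else stats::as.dist(1 - stats::cor(t(m)))
  }
  row_tree <- stats::hclust(dfun(mat), method = linkage)
  col_tree <- stats::hclust(dfun(t(mat)), method = linkage)
  structure(list(row_order = row_tree$order, col_order = col_tree$order,
                 row_tree = row_tree, col_tree = col_tree,
                 reordered = mat[row_tree$order, col_tree$order,
                                 drop = FALSE]),
            class = "pe_bicluster")
}

#' @export
print.pe_bicluster <- function(x, ...) {
  cat("bicluster of a", nrow(x$reordered), "x", ncol(x$reordered),
      "matrix (average linkage)\n")
  cat("row order:", paste(rownames(x$reordered), collapse = ", "), "\n")
  cat("column order:", paste(colnames(x$reordered), collapse = ", "), "\n")
  invisible(x)
}
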
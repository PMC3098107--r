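#' Estimate the noise threshold d_e from replicate measurements
#'
#' Pools the absolute log2 differences between repeat measurements (all
#' unordered replicate pairs, all genes, all time points, all conditions) and
#' returns their mean plus one standard deviation. On the Arabidopsis abiotic
#' stress arrays this procedure gives a mean absolute replicate difference of
#' about 0.156 with s.d. 0.19, hence the default threshold `d_e = 0.35` used
#' throughout the package.
#'
#' @param x One of: an [expression_matrix()] carrying a `replicates` list; a
#'   list of such matrices (one per condition, pooled "across all datasets");
#'   or a plain list of two or more same-shape numeric matrices (the
#'   replicates of a single condition).
#' @return A `noise_threshold` object: list with `d_e` (= `d_m + sd`), `d_m`
#'   (mean absolute replicate difference), `sd`, and `n_diffs`. It can be
#'   passed directly wherever a `d_e` argument is expected.
#' @examples
#' r1 <- matrix(rnorm(70, 8), 10)
#' r2 <- r1 + rnorm(70, sd = 0.1)
#' estimate_noise_threshold(list(r1, r2))
#' @export
estimate_noise_threshold <- function(x) {
  sets <- if (inherits(x, "expression_matrix")) {
    list(x$replicates)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                      "expression_matrix"))) {
    lapply(x, `[[`, "replicates")
  } else if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) {
    list(x)
  } else {
    stop("'x' must be expression matrices with replicates, or a list of ",
         "replicate matrices", call. = FALSE)
  }
  diffs <- numeric(0)
  for (reps in sets) {
    if (is.null(reps) || length(reps) < 2L) {
      stop("at least two replicate matrices per condition are required to ",
           "estimate the noise threshold", call. = FALSE)
    }
    for (i in seq_len(length(reps) - 1L)) {
      for (j in seq.int(i + 1L, length(reps))) {
        diffs <- c(diffs, abs(as.numeric(reps[[i]]) - as.numeric(reps[[j]])))
      }
    }
  }
  d_m <- mean(diffs)
  s <- stats::sd(diffs)
  if (is.na(s)) s <- 0
  structure(list(d_e = d_m + s, d_m = d_m, sd = s, n_diffs = length(diffs)),
            class = "noise_threshold")
}

#' @export
print.noise_threshold <- function(x, ...) {
  cat(sprintf(
    "noise threshold d_e = %.4g (mean |diff| %.4g + 1 s.d. %.4g, n = %d)\n",
    x$d_e, x$d_m, x$sd, x$n_diffs))
  invisible(x)
}

#' Drop the lowest-expressed genes
#'
#' Ranks genes by their summary expression level over the matrix's time
#' points (mean by default) and removes the `n_drop` lowest-ranked ones; ties
#' are broken lexicographically by gene id so the result is deterministic.
#' Genes expressed at or near background would trivially score `PE = 0` ("no
#' detectable change"), so analyses relating entropy to gene features are
#' restricted to genes with appreciable expression -- e.g. dropping the
#' 10,000 lowest of 21,797 array probes keeps 11,797.
#'
#' @param m An [expression_matrix()] (typically the control condition).
#' @param n_drop Number of genes to remove; a value in (0, 1) is interpreted
#'   as a fraction of the gene count.
#' @param stat Ranking statistic over time points: `"mean"` (default) or
#'   `"median"`.
#' @return List with `matrix` (the filtered [expression_matrix()], original
#'   row order preserved) and `report` (a `filter_report`: `n_input`,
#'   `n_removed`, `n_kept`, `rank_statistic`).
#' @export
filter_low_expression <- function(m, n_drop, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(m, "expression_matrix"))
  n <- nrow(m$values)
  n_drop <- as.numeric(n_drop)
  if (n_drop > 0 && n_drop < 1) n_drop <- round(n_drop * n)
  n_drop <- as.integer(n_drop)
  if (is.na(n_drop) || n_drop < 0L) stop("'n_drop' must be non-negative",
                                         call. = FALSE)
  if (n_drop >= n) {
    stop("'n_drop' (", n_drop, ") must be smaller than the number of genes (",
         n, ")", call. = FALSE)
  }
  score <- switch(stat,
                  mean = rowMeans(m$values),
                  median = apply(m$values, 1L, stats::median))
  ord <- order(score, m$gene_ids)    # ascending; lowest expression first
  drop <- ord[seq_len(n_drop)]
  keep <- setdiff(seq_len(n), drop)  # increasing: original order preserved
  reps <- if (!is.null(m$replicates)) {
    lapply(m$replicates, function(r) as.matrix(r)[keep, , drop = FALSE])
  }
  out <- expression_matrix(m$values[keep, , drop = FALSE], m$times,
                           condition = m$condition,
                           gene_ids = m$gene_ids[keep], replicates = reps)
  report <- structure(list(n_input = n, n_removed = n_drop,
                           n_kept = n - n_drop, rank_statistic = stat),
                      class = "filter_report")
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("low-expression filter (%s rank): %d genes in, %d removed, %d kept\n",
              x$rank_statistic, x$n_input, x$n_removed, x$n_kept))
  invisible(x)
}

#' Resample a series onto an even time grid by cubic-spline interpolation
#'
#' Stress time courses are usually sampled densely early and sparsely late
#' (roughly even on a log time scale). To check how entropy depends on the
#' sampling scheme, a cubic interpolating spline is fitted through the
#' observed points and evaluated at `n_points` equidistant times spanning the
#' original range (endpoints included).
#'
#' The default boundary handling is `"fmm"` (an exact cubic through the
#' endpoint runs, the [stats::spline()] default), which reproduces cubic
#' polynomials exactly; `"natural"` (zero second derivative at the ends) is
#' available as an alternative.
#'
#' @param x An [expression_series()] (length >= 4, so the cubic spline is
#'   well-posed) or an [expression_matrix()], in which case every row is
#'   resampled onto the shared even grid.
#' @param n_points Number of equidistant output points (default: as input).
#' @param method Spline boundary handling, `"fmm"` or `"natural"`.
#' @return An object of the same class as `x` on the even grid.
#' @examples
#' s <- expression_series("g", c(0, 0.5, 1, 3, 6, 12, 24),
#'                        c(0, 1, 2, 3, 4, 5, 6))
#' resample_even(s)
#' @export
resample_even <- function(x, n_points = NULL, method = c("fmm", "natural")) {
  method <- match.arg(method)
  if (inherits(x, "expression_series")) {
    if (length(x$times) < 4L) {
      stop("cubic-spline resampling needs at least 4 points", call. = FALSE)
    }
    if (is.null(n_points)) n_points <- length(x$times)
    if (n_points < 3L) stop("'n_points' must be at least 3", call. = FALSE)
    grid <- seq(min(x$times), max(x$times), length.out = n_points)
    sp <- stats::spline(x$times, x$values, xout = grid, method = method)
    return(expression_series(x$gene_id, sp$x, sp$y))
  }
  if (inherits(x, "expression_matrix")) {
    if (length(x$times) < 4L) {
      stop("cubic-spline resampling needs at least 4 points", call. = FALSE)
    }
    if (is.null(n_points)) n_points <- length(x$times)
    if (n_points < 3L) stop("'n_points' must be at least 3", call. = FALSE)
    grid <- seq(min(x$times), max(x$times), length.out = n_points)
    vals <- t(apply(x$values, 1L, function(v) {
      stats::spline(x$times, v, xout = grid, method = method)$y
    }))
    return(expression_matrix(vals, grid, condition = x$condition,
                             gene_ids = x$gene_ids))
  }
  stop("'x' must be an expression_series or expression_matrix", call. = FALSE)
}

#' Normalize a stress matrix to its control
#'
#' Subtracts, gene by gene and time point by time point, the control profile
#' from the stress profile (both on log2 scale), so the result is the log2
#' fold change trajectory relative to control. Entropy computed on the
#' normalized profiles measures the complexity of the response relative to
#' the unperturbed course.
#'
#' @param stress,control [expression_matrix()] objects with identical gene
#'   ids and times.
#' @return An [expression_matrix()] of elementwise differences, with
#'   condition label `"<stress>_minus_<control>"`.
#' @export
normalize_to_control <- function(stress, control) {
  stopifnot(inherits(stress, "expression_matrix"),
            inherits(control, "expression_matrix"))
  if (!identical(stress$gene_ids, control$gene_ids)) {
    stop("gene ids of stress and control matrices differ", call. = FALSE)
  }
  if (!isTRUE(all.equal(stress$times, control$times))) {
    stop("time grids of stress and control matrices differ", call. = FALSE)
  }
  expression_matrix(stress$values - control$values, stress$times,
                    condition = paste0(stress$condition, "_minus_",
                                       control$condition),
                    gene_ids = stress$gene_ids)
}
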
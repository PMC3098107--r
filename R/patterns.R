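#' pentropy: permutation entropy for short expression time series
#'
#' Temporal complexity of short, noisy, non-equidistant gene-expression time
#' series via a modified permutation entropy. Each overlapping window of three
#' consecutive measurements is mapped to one of the 13 weak orderings of three
#' values: consecutive differences smaller in magnitude than a noise threshold
#' `d_e` (log2 units) are treated as "unchanged", so the six strict rank
#' permutations are extended by six partially-tied classes and one all-tied
#' "no-change" class. The entropy of the resulting pattern distribution is the
#' per-gene complexity score.
#'
#' See `vignette("permutation-entropy", package = "pentropy")` for the model,
#' its assumptions, and the design choices.
#'
#' @keywords internal
"_PACKAGE"

# package-local cache (permutation index matrices etc.)
.pe_env <- new.env(parent = emptyenv())

#' The 13 three-point ordinal pattern classes
#'
#' One row per pattern class. `s1` and `s2` are the thresholded signs of the
#' consecutive differences `x2 - x1` and `x3 - x2` (0 when the magnitude is
#' below the noise threshold `d_e`); `s3` is the thresholded sign of the
#' endpoint difference `x3 - x1`, consulted only for the peak/valley classes
#' (where `s1` and `s2` are nonzero and opposite) to separate the end-below /
#' end-above / end-tied variants. `NA` marks comparisons that do not enter the
#' classification. `ranks` gives the weak rank triple (time order left to
#' right, 1 = lowest level).
#'
#' Codes 1-2 are the monotone classes, 3-6 the strict peak/valley
#' permutations, 7-12 the single-tie classes, and 13 the all-unchanged
#' ("no-change") class.
#'
#' @format A data frame with 13 rows and columns `code`, `s1`, `s2`, `s3`,
#'   `ranks`, `description`.
#' @examples
#' pe_patterns
#' @export
pe_patterns <- data.frame(
  code = 1:13,
  s1 = c( 1L, -1L,  1L,  1L, -1L, -1L,  1L, -1L,  0L,  0L,  1L, -1L, 0L),
  s2 = c( 1L, -1L, -1L, -1L,  1L,  1L, -1L,  1L,  1L, -1L,  0L,  0L, 0L),
  s3 = c( NA,  NA, -1L,  1L, -1L,  1L,  0L,  0L,  NA,  NA,  NA,  NA, NA),
  ranks = c("(1,2,3)", "(3,2,1)", "(2,3,1)", "(1,3,2)", "(3,1,2)", "(2,1,3)",
            "(1,2,1)", "(2,1,2)", "(1,1,2)", "(2,2,1)", "(1,2,2)", "(2,1,1)",
            "(1,1,1)"),
  description = c("monotone increase", "monotone decrease",
                  "peak, end below start", "peak, end above start",
                  "valley, end below start", "valley, end above start",
                  "peak, ends tied", "valley, ends tied",
                  "flat then up", "flat then down",
                  "up then flat", "down then flat",
                  "no change"),
  stringsAsFactors = FALSE
)

## thresholded sign: 0 iff |d| < d_e (a difference of exactly d_e counts as
## changed); otherwise the ordinary sign
threshold_sign <- function(d, d_e) {
  as.integer(sign(d) * (abs(d) >= d_e))
}

## vectorised classification of thresholded sign triples into codes 1..13
classify_codes <- function(s1, s2, s3) {
  code <- integer(length(s1))
  up <- s1 > 0L
  dn <- s1 < 0L
  fl <- s1 == 0L
  code[up & s2 > 0L] <- 1L
  code[dn & s2 < 0L] <- 2L
  pk <- up & s2 < 0L
  vl <- dn & s2 > 0L
  if (any(pk)) {
    code[pk] <- ifelse(s3[pk] < 0L, 3L, ifelse(s3[pk] > 0L, 4L, 7L))
  }
  if (any(vl)) {
    code[vl] <- ifelse(s3[vl] < 0L, 5L, ifelse(s3[vl] > 0L, 6L, 8L))
  }
  code[fl & s2 > 0L] <- 9L
  code[fl & s2 < 0L] <- 10L
  code[up & s2 == 0L] <- 11L
  code[dn & s2 == 0L] <- 12L
  code[fl & s2 == 0L] <- 13L
  code
}

#' Encode one three-point window as an ordinal pattern class
#'
#' Classifies the window `(x1, x2, x3)` into one of the 13 weak orderings of
#' three values (see [pe_patterns]). A consecutive difference is "unchanged"
#' when its magnitude is strictly below the noise threshold `d_e`. The
#' endpoint comparison `x3 - x1` is consulted only when the two consecutive
#' differences are changed in opposite directions (peak/valley), where it
#' splits the class into end-below, end-above, and end-tied variants;
#' threshold relations are not transitive, so it is ignored otherwise.
#'
#' @param x1,x2,x3 Expression levels (log2 scale) at three consecutive time
#'   points; must be finite.
#' @param d_e Non-negative noise threshold in log2 units (default 0.35), or a
#'   [`noise_threshold`][estimate_noise_threshold] object.
#' @return Integer pattern code in `1:13`, with attribute `signs`, the
#'   thresholded sign triple `(s1, s2, s3)` (`s3` is `NA` when not consulted).
#' @examples
#' encode_window(1, 2, 3)            # monotone increase -> 1
#' encode_window(0, 0.1, 0.2)        # all below threshold -> 13
#' encode_window(0, 1, 0.5, d_e = 0.35)  # peak, end above start -> 4
#' @seealso [encode_series()], [pe_patterns]
#' @export
encode_window <- function(x1, x2, x3, d_e = 0.35) {
  d_e <- as_d_e(d_e)
  x <- c(x1, x2, x3)
  if (length(x) != 3L || !all(is.finite(x))) {
    stop("window values must be three finite numbers", call. = FALSE)
  }
  if (!is.finite(d_e) || d_e < 0) {
    stop("'d_e' must be a single non-negative number", call. = FALSE)
  }
  s1 <- threshold_sign(x2 - x1, d_e)
  s2 <- threshold_sign(x3 - x2, d_e)
  s3 <- if (s1 != 0L && s2 != 0L && s1 != s2) {
    threshold_sign(x3 - x1, d_e)
  } else {
    NA_integer_
  }
  code <- classify_codes(s1, s2, if (is.na(s3)) 0L else s3)
  structure(code, signs = c(s1 = s1, s2 = s2, s3 = s3))
}

## encode all sliding windows of every row of a genes x times matrix;
## returns a genes x (t - 2) integer matrix of pattern codes
encode_matrix <- function(values, d_e) {
  t_len <- ncol(values)
  if (t_len < 3L) stop("need at least 3 time points", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  d <- values[, -1L, drop = FALSE] - values[, -t_len, drop = FALSE]
  s <- sign(d) * (abs(d) >= d_e)
  s1 <- s[, seq_len(t_len - 2L), drop = FALSE]
  s2 <- s[, seq_len(t_len - 2L) + 1L, drop = FALSE]
  e <- values[, seq_len(t_len - 2L) + 2L, drop = FALSE] -
    values[, seq_len(t_len - 2L), drop = FALSE]
  s3 <- sign(e) * (abs(e) >= d_e)
  codes <- classify_codes(as.vector(s1), as.vector(s2), as.vector(s3))
  matrix(codes, nrow = nrow(values), ncol = t_len - 2L,
         dimnames = list(rownames(values), NULL))
}

#' Encode a series into ordinal pattern counts
#'
#' Applies [encode_window()] to every overlapping window of three consecutive
#' points (step 1), so a series of `t` points yields `t - 2` patterns.
#'
#' @param x An [expression_series()] or a numeric vector of log2 levels in
#'   time order (length at least 3).
#' @param d_e Noise threshold, as in [encode_window()].
#' @return A `pattern_counts` object: list with `counts` (named integer
#'   vector over codes 1..13), `n_windows`, and `codes` (the window-by-window
#'   code sequence).
#' @examples
#' encode_series(c(1, 2, 3, 4, 5, 6, 7))          # all windows monotone up
#' encode_series(rep(0, 7))$counts[["13"]]        # 5 no-change windows
#' @export
encode_series <- function(x, d_e = 0.35) {
  d_e <- as_d_e(d_e)
  values <- if (inherits(x, "expression_series")) x$values else as.numeric(x)
  if (length(values) < 3L) {
    stop("a series must have at least 3 points", call. = FALSE)
  }
  codes <- as.vector(encode_matrix(matrix(values, nrow = 1L), d_e))
  pattern_counts(codes)
}

## construct a pattern_counts object from a code sequence
pattern_counts <- function(codes) {
  counts <- tabulate(codes, nbins = 13L)
  names(counts) <- as.character(1:13)
  structure(list(counts = counts, n_windows = length(codes), codes = codes),
            class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  obs <- x$counts[x$counts > 0L]
  cat("ordinal pattern counts over", x$n_windows, "windows:\n")
  print(obs)
  invisible(x)
}

#' Permutation entropy of a pattern distribution
#'
#' Shannon entropy, in bits, of the relative frequencies of the ordinal
#' patterns observed in a series' sliding windows:
#' `PE = -sum_i p_i log2 p_i`, summed over patterns actually observed
#' (equivalently, `0 * log 0 = 0`). For `w` windows the value lies in
#' `[0, log2 w]` and takes only the finitely many values generated by integer
#' partitions of `w` (see [achievable_pe_values()]); a 7-point series has
#' `w = 5` windows, hence 7 possible values with maximum `log2 5 = 2.32`.
#'
#' @param x A `pattern_counts` object from [encode_series()], or a numeric
#'   vector of non-negative counts.
#' @return Permutation entropy in bits.
#' @examples
#' permutation_entropy(c(5))            # one pattern only -> 0
#' permutation_entropy(rep(1, 5))       # five distinct patterns -> log2(5)
#' permutation_entropy(encode_series(c(0, 1, 0, 1, 0, 1, 0)))
#' @export
permutation_entropy <- function(x) {
  counts <- if (inherits(x, "pattern_counts")) x$counts else as.numeric(x)
  if (length(counts) == 0L || anyNA(counts) || any(counts < 0)) {
    stop("counts must be a non-empty vector of non-negative numbers",
         call. = FALSE)
  }
  total <- sum(counts)
  if (total < 1) stop("at least one observed window is required", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log2(p)) + 0   # "+ 0" avoids IEEE negative zero
}

## all integer partitions of n into at most max_parts parts (parts <= max_part)
integer_partitions <- function(n, max_part = n, max_parts = n) {
  if (n == 0L) return(list(integer(0)))
  if (max_parts == 0L) return(list())
  out <- list()
  for (k in seq.int(min(n, max_part), 1L)) {
    for (rest in integer_partitions(n - k, k, max_parts - 1L)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

#' The discrete set of achievable permutation entropy values
#'
#' A series with `n_windows` windows distributes them over at most 13 pattern
#' classes, so the entropy can only take the values generated by the integer
#' partitions of `n_windows` into at most 13 parts. For `n_windows = 5` (a
#' 7-point series) the partitions 5, 4-1, 3-2, 3-1-1, 2-2-1, 2-1-1-1,
#' 1-1-1-1-1 give exactly 7 distinct values between 0 and `log2 5`.
#'
#' @param n_windows Number of three-point windows (positive integer).
#' @param n_classes Number of pattern classes (default 13).
#' @return Sorted numeric vector of the distinct achievable entropies (bits).
#' @examples
#' achievable_pe_values(5)   # 7 values, min 0, max log2(5) = 2.32
#' @export
achievable_pe_values <- function(n_windows, n_classes = 13L) {
  n_windows <- as.integer(n_windows)
  if (is.na(n_windows) || n_windows < 1L) {
    stop("'n_windows' must be a positive integer", call. = FALSE)
  }
  parts <- integer_partitions(n_windows, max_parts = as.integer(n_classes))
  vals <- vapply(parts, permutation_entropy, numeric(1))
  vals <- sort(vals)
  vals[c(TRUE, diff(vals) > 1e-9)]
}

#' Pooled ordinal-pattern spectrum over many series
#'
#' Pools the sliding-window pattern counts of a collection of series into one
#' frequency spectrum over the 13 classes; `m` series of `t` points contribute
#' `m * (t - 2)` windows in total.
#'
#' @param x An [expression_matrix()], a numeric genes-by-times matrix, or a
#'   list of series (numeric vectors or [expression_series()] objects, which
#'   may differ in length).
#' @param d_e Noise threshold, as in [encode_window()].
#' @return A `pattern_counts` object with the pooled counts (the per-window
#'   code sequence is not retained).
#' @examples
#' m <- rbind(g1 = c(0, 1, 2, 3, 4, 5, 6), g2 = rep(0, 7))
#' pattern_spectrum(m)
#' @export
pattern_spectrum <- function(x, d_e = 0.35) {
  d_e <- as_d_e(d_e)
  if (inherits(x, "expression_matrix")) x <- x$values
  if (is.matrix(x)) {
    if (nrow(x) == 0L) stop("empty input", call. = FALSE)
    codes <- encode_matrix(x, d_e)
    counts <- tabulate(as.vector(codes), nbins = 13L)
    n_windows <- length(codes)
  } else if (is.list(x)) {
    if (length(x) == 0L) stop("empty input", call. = FALSE)
    counts <- integer(13L)
    n_windows <- 0L
    for (s in x) {
      pc <- encode_series(s, d_e)
      counts <- counts + pc$counts
      n_windows <- n_windows + pc$n_windows
    }
  } else {
    stop("'x' must be an expression matrix or a list of series", call. = FALSE)
  }
  names(counts) <- as.character(1:13)
  structure(list(counts = counts, n_windows = n_windows, codes = NULL),
            class = "pattern_counts")
}

## accept a plain number or a noise_threshold object wherever d_e is expected
as_d_e <- function(d_e) {
  if (inherits(d_e, "noise_threshold")) d_e <- d_e$d_e
  if (!is.numeric(d_e) || length(d_e) != 1L) {
    stop("'d_e' must be a single number (or a noise_threshold object)",
         call. = FALSE)
  }
  as.numeric(d_e)
}
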
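## ---- synthetic data with controlled ordinal-pattern composition ----------

## label "3-1-1" <-> partition c(3,1,1)
partition_label <- function(p) paste(sort(p, decreasing = TRUE),
                                     collapse = "-")
parse_partition <- function(label) {
  p <- as.integer(strsplit(label, "-", fixed = TRUE)[[1L]])
  if (anyNA(p) || any(p < 1L)) stop("bad partition label '", label, "'",
                                    call. = FALSE)
  sort(p, decreasing = TRUE)
}

#' Default mixture over window-count partitions for the control condition
#'
#' Probabilities over the 7 pattern-count multisets of 5 windows (ascending
#' entropy order), shaped after the observed control-condition PE histogram:
#' roughly half of the genes at `PE = 0`, about 10 percent at the maximum,
#' the strictly periodic 3-2 realization rarest.
#'
#' @return Named numeric vector summing to 1 (names are partition labels).
#' @export
default_pattern_mixture <- function() {
  c("5" = 0.50, "4-1" = 0.10, "3-2" = 0.02, "3-1-1" = 0.08,
    "2-2-1" = 0.12, "2-1-1-1" = 0.08, "1-1-1-1-1" = 0.10)
}

#' Specification for a simulated two-condition experiment
#'
#' Bundles and validates the parameters of [simulate_experiment()]. The
#' defaults emulate the shape of a 7-point abiotic-stress time course:
#' sampling at 0, 0.5, 1, 3, 6, 12, 24 h, noise threshold `d_e = 0.35` with
#' "changed" steps of `step_size = 1` log2 unit, replicate noise
#' `noise_sd = 0.1` (the scale of observed replicate differences), and a
#' control pattern mixture matching the observed control PE histogram (see
#' [default_pattern_mixture()]). `condition_shift` tilts the stress mixture
#' toward richer pattern multisets by reweighting each partition with
#' `exp(shift * (number_of_distinct_patterns - 1))`; the default 0.3 yields a
#' mean PE increase of about 0.4, within the range observed across real
#' stress conditions.
#'
#' @param n_genes Number of genes.
#' @param times Sampling times (hours), strictly increasing.
#' @param pattern_mixture Named probability vector over partition labels of
#'   `length(times) - 2` windows.
#' @param step_size Magnitude (log2 units) of a "changed" step; must exceed
#'   `d_e`.
#' @param noise_sd Standard deviation of additive replicate noise.
#' @param d_e Noise threshold used for construction (and the natural choice
#'   for later encoding).
#' @param condition_shift Tilt of the stress mixture (0 = no shift).
#' @param n_replicates Replicate copies of the control condition.
#' @param baseline_mean,baseline_sd Per-gene baseline expression level
#'   (log2), drawn normally.
#' @param seed Integer seed; identical specs reproduce identical data.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_genes = 2000L,
                            times = c(0, 0.5, 1, 3, 6, 12, 24),
                            pattern_mixture = default_pattern_mixture(),
                            step_size = 1.0, noise_sd = 0.1, d_e = 0.35,
                            condition_shift = 0.3, n_replicates = 2L,
                            baseline_mean = 8, baseline_sd = 2,
                            seed = 1L) {
  n_windows <- length(times) - 2L
  if (n_windows < 1L) stop("need at least 3 time points", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  if (step_size <= d_e) stop("'step_size' must exceed 'd_e'", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (is.null(names(pattern_mixture)) ||
      abs(sum(pattern_mixture) - 1) > 1e-8 || any(pattern_mixture < 0)) {
    stop("'pattern_mixture' must be a named probability vector summing to 1",
         call. = FALSE)
  }
  for (lab in names(pattern_mixture)) {
    if (sum(parse_partition(lab)) != n_windows) {
      stop("mixture label '", lab, "' is not a partition of ", n_windows,
           " windows", call. = FALSE)
    }
  }
  structure(list(n_genes = as.integer(n_genes), times = times,
                 pattern_mixture = pattern_mixture, step_size = step_size,
                 noise_sd = noise_sd, d_e = d_e,
                 condition_shift = condition_shift,
                 n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(paste0("simulation spec: %d genes, %d time points, d_e = %g, ",
                     "step = %g, noise sd = %g, shift = %g, seed = %d\n"),
              x$n_genes, length(x$times), x$d_e, x$step_size, x$noise_sd,
              x$condition_shift, x$seed))
  invisible(x)
}

## exponential tilt of the mixture toward partitions with more distinct parts
tilt_mixture <- function(mixture, shift) {
  parts <- vapply(names(mixture), function(l) length(parse_partition(l)),
                  integer(1))
  w <- mixture * exp(shift * (parts - 1L))
  w / sum(w)
}

#' Construct a series realizing a prescribed ordinal pattern sequence
#'
#' Inverse of [encode_series()]: builds a series whose overlapping
#' three-point windows encode exactly to `codes`. Points are placed left to
#' right; each new point is chosen from the interval that the requested
#' pattern's thresholded-sign constraints admit ("changed" steps move by
#' about `step_size`, "unchanged" steps jitter uniformly within
#' `(-d_e/2, d_e/2)`, bounded intervals take their midpoint). Consecutive
#' windows share two points, so the requested sequence must chain: the first
#' thresholded sign of each pattern must equal the second sign of its
#' predecessor, and bounded intervals must stay non-empty. Infeasible
#' requests raise an error naming the first offending window.
#'
#' @param codes Integer vector of pattern codes in `1:13` (see
#'   [pe_patterns]), one per window; the series has `length(codes) + 2`
#'   points.
#' @param step_size Magnitude of a changed step (log2 units), > `d_e`.
#' @param d_e Noise threshold the series is built against.
#' @param start Level of the first point (log2), e.g. a baseline expression.
#' @return Numeric vector of expression levels of length `length(codes) + 2`.
#' @examples
#' x <- series_from_patterns(c(3, 5, 4, 2, 6))
#' encode_series(x)$codes   # 3 5 4 2 6
#' @export
series_from_patterns <- function(codes, step_size = 1.0, d_e = 0.35,
                                 start = 0) {
  codes <- as.integer(codes)
  if (length(codes) < 1L || anyNA(codes) || any(codes < 1L | codes > 13L)) {
    stop("'codes' must be pattern codes in 1..13", call. = FALSE)
  }
  if (step_size <= d_e) stop("'step_size' must exceed 'd_e'", call. = FALSE)
  s1 <- pe_patterns$s1; s2 <- pe_patterns$s2; s3 <- pe_patterns$s3
  if (length(codes) > 1L) {
    bad <- which(s1[codes[-1L]] != s2[codes[-length(codes)]])
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf(paste0("infeasible transition at window %d: pattern %d ",
                          "requires a first step sign of %d but pattern %d ",
                          "ends with sign %d"),
                   i + 1L, codes[i + 1L], s1[codes[i + 1L]], codes[i],
                   s2[codes[i]]), call. = FALSE)
    }
  }
  eps <- d_e * 1e-6   # margin pulling strict "< d_e" bounds inside
  x <- numeric(length(codes) + 2L)
  x[1L] <- start
  x[2L] <- start + switch(as.character(s1[codes[1L]]),
                          "1" = step_size,
                          "-1" = -step_size,
                          "0" = stats::runif(1, -d_e / 2, d_e / 2))
  for (i in seq_along(codes)) {
    a <- x[i]; b <- x[i + 1L]
    cc <- codes[i]
    lo <- -Inf; hi <- Inf
    # consecutive constraint (x3 vs b)
    if (s2[cc] > 0L) lo <- max(lo, b + d_e)
    if (s2[cc] < 0L) hi <- min(hi, b - d_e)
    if (s2[cc] == 0L) { lo <- max(lo, b - d_e + eps); hi <- min(hi, b + d_e - eps) }
    # endpoint constraint (x3 vs a), peak/valley classes only
    if (!is.na(s3[cc])) {
      if (s3[cc] > 0L) lo <- max(lo, a + d_e)
      if (s3[cc] < 0L) hi <- min(hi, a - d_e)
      if (s3[cc] == 0L) { lo <- max(lo, a - d_e + eps); hi <- min(hi, a + d_e - eps) }
    }
    if (lo > hi) {
      stop(sprintf(paste0("infeasible window %d (pattern %d): the admissible ",
                          "interval for the new point is empty"),
                   i, cc), call. = FALSE)
    }
    x[i + 2L] <- if (is.infinite(lo) && is.infinite(hi)) {
      stop("internal error: unconstrained point")   # s2 always constrains
    } else if (is.infinite(hi)) {
      lo - d_e + step_size                 # plain changed step upward
    } else if (is.infinite(lo)) {
      hi + d_e - step_size                 # plain changed step downward
    } else if (s2[cc] == 0L || (!is.na(s3[cc]) && s3[cc] == 0L)) {
      anchor <- if (s2[cc] == 0L) b else a # tie class: jitter about the tied point
      cand <- anchor + stats::runif(1, -d_e / 2, d_e / 2)
      if (cand < lo || cand > hi) (lo + hi) / 2 else cand
    } else {
      (lo + hi) / 2                        # bounded strict interval: midpoint
    }
  }
  got <- as.vector(encode_matrix(matrix(x, nrow = 1L), d_e))
  if (!identical(got, codes)) {
    stop("internal error: constructed series does not realize the requested ",
         "patterns", call. = FALSE)
  }
  x
}

## permutations of 1..n as a matrix (cached)
perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.pe_env$perms[[key]])) return(.pe_env$perms[[key]])
  pm <- if (n == 1L) matrix(1L, 1L, 1L) else {
    sub <- perm_matrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, ifelse(sub >= k, sub + 1L, sub))
    }))
  }
  if (is.null(.pe_env$perms)) .pe_env$perms <- list()
  .pe_env$perms[[key]] <- pm
  pm
}

## all orderings of a code multiset whose consecutive signs chain
chainable_orderings <- function(codes) {
  n <- length(codes)
  pm <- perm_matrix(n)
  seqs <- matrix(codes[pm], nrow(pm), n)
  if (n == 1L) return(seqs)
  s1 <- pe_patterns$s1; s2 <- pe_patterns$s2
  a <- matrix(s1[seqs[, -1L]], nrow(seqs))
  b <- matrix(s2[seqs[, -n]], nrow(seqs))
  ok <- rowSums(a == b) == (n - 1L)
  unique(seqs[ok, , drop = FALSE])
}

## codes whose pattern chains with itself (monotone up/down, no-change)
SELF_CHAIN_CODES <- c(1L, 2L, 13L)

## sample a realizable code sequence with the given count multiset and
## construct the series; retries code assignments until construction works
sample_partition_series <- function(partition, step_size, d_e, start,
                                    max_tries = 100L) {
  k <- length(partition)
  for (try in seq_len(max_tries)) {
    codes <- if (k == 1L) sample(SELF_CHAIN_CODES, 1L) else sample(13L, k)
    multiset <- rep(codes, times = partition)
    ords <- chainable_orderings(multiset)
    if (nrow(ords) == 0L) next
    for (r in sample(nrow(ords), min(nrow(ords), 10L))) {
      seq_codes <- ords[r, ]
      values <- tryCatch(series_from_patterns(seq_codes, step_size, d_e,
                                              start),
                         error = function(e) NULL)
      if (!is.null(values)) {
        return(list(codes = seq_codes, values = values))
      }
    }
  }
  stop("could not realize a pattern sequence for partition ",
       partition_label(partition), call. = FALSE)
}

#' Draw a random realizable ordinal pattern sequence
#'
#' Samples pattern codes window by window, each uniformly among the classes
#' whose first thresholded sign chains with the predecessor's second sign,
#' and accepts the sequence once [series_from_patterns()] can realize it
#' (bounded-interval chains can still be geometrically infeasible and are
#' resampled).
#'
#' @param n_windows Number of windows.
#' @param d_e,step_size As in [series_from_patterns()].
#' @param max_tries Resampling budget.
#' @return Integer vector of pattern codes, realizable by
#'   [series_from_patterns()] with the same `step_size` and `d_e`.
#' @export
random_pattern_sequence <- function(n_windows = 5L, d_e = 0.35,
                                    step_size = 1.0, max_tries = 100L) {
  s1 <- pe_patterns$s1; s2 <- pe_patterns$s2
  for (try in seq_len(max_tries)) {
    codes <- integer(n_windows)
    codes[1L] <- sample(13L, 1L)
    if (n_windows > 1L) {
      for (i in seq.int(2L, n_windows)) {
        pool <- which(s1 == s2[codes[i - 1L]])
        codes[i] <- pool[sample.int(length(pool), 1L)]
      }
    }
    ok <- tryCatch({
      series_from_patterns(codes, step_size, d_e)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(codes)
  }
  stop("failed to draw a realizable pattern sequence", call. = FALSE)
}

#' Simulate a control/stress expression experiment
#'
#' Generates a control and a stress [expression_matrix()] whose per-gene
#' ordinal-pattern count multisets are drawn from the spec's
#' `pattern_mixture` (control) and its tilted version (stress; see
#' [simulation_spec()]). Each gene receives a normal baseline level, the
#' noiseless profile realizing the sampled multiset, and additive normal
#' replicate noise: the control matrix is the average of `n_replicates`
#' noisy copies (kept in `$replicates`), the stress matrix a single noisy
#' realization. Fully reproducible from the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A `pe_simulation`: list with `control`, `stress`
#'   ([expression_matrix()] objects) and `truth`, a data frame with the
#'   sampled partition labels and the noiseless entropies per gene.
#' @examples
#' sim <- simulate_experiment(simulation_spec(n_genes = 50, seed = 7))
#' head(sim$truth)
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  t_len <- length(spec$times)
  labels <- names(spec$pattern_mixture)
  stress_mixture <- tilt_mixture(spec$pattern_mixture, spec$condition_shift)
  ctrl_lab <- sample(labels, n, replace = TRUE, prob = spec$pattern_mixture)
  strs_lab <- sample(labels, n, replace = TRUE, prob = stress_mixture)
  gene_ids <- sprintf("G%05d", seq_len(n))
  baseline <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
  ctrl_base <- matrix(NA_real_, n, t_len)
  strs_base <- matrix(NA_real_, n, t_len)
  ctrl_pe <- strs_pe <- numeric(n)
  for (g in seq_len(n)) {
    sc <- sample_partition_series(parse_partition(ctrl_lab[g]),
                                  spec$step_size, spec$d_e, baseline[g])
    ss <- sample_partition_series(parse_partition(strs_lab[g]),
                                  spec$step_size, spec$d_e, baseline[g])
    ctrl_base[g, ] <- sc$values
    strs_base[g, ] <- ss$values
    ctrl_pe[g] <- permutation_entropy(tabulate(sc$codes, 13L))
    strs_pe[g] <- permutation_entropy(tabulate(ss$codes, 13L))
  }
  noise <- function(base) {
    base + matrix(stats::rnorm(length(base), sd = spec$noise_sd),
                  nrow(base), ncol(base))
  }
  reps <- lapply(seq_len(spec$n_replicates), function(i) noise(ctrl_base))
  ctrl_values <- Reduce(`+`, reps) / length(reps)
  control <- expression_matrix(ctrl_values, spec$times, "control",
                               gene_ids = gene_ids, replicates = reps)
  stress <- expression_matrix(noise(strs_base), spec$times, "stress",
                              gene_ids = gene_ids)
  truth <- data.frame(gene_id = gene_ids,
                      control_partition = ctrl_lab,
                      stress_partition = strs_lab,
                      control_pe = ctrl_pe, stress_pe = strs_pe)
  structure(list(control = control, stress = stress, truth = truth,
                 spec = spec),
            class = "pe_simulation")
}

#' @export
print.pe_simulation <- function(x, ...) {
  cat("simulated experiment:", x$spec$n_genes, "genes,",
      length(x$spec$times), "time points\n")
  cat(sprintf("noiseless mean PE: control %.3f, stress %.3f\n",
              mean(x$truth$control_pe), mean(x$truth$stress_pe)))
  invisible(x)
}

#' Simulate replicate measurements with prescribed noise moments
#'
#' Produces one condition measured in two replicates whose pooled absolute
#' log2 differences have, in expectation, the requested mean and standard
#' deviation -- the two moments that define the noise threshold
#' `d_e = mean + sd`. Difference magnitudes are gamma-distributed (shape and
#' scale solved from the two moments) with random sign and split evenly
#' between the two replicates.
#'
#' @param n_genes Number of genes.
#' @param times Sampling times.
#' @param mean_abs,sd_abs Target mean and s.d. of the pooled absolute
#'   replicate differences (defaults 0.156 and 0.19, the values observed on
#'   the stress arrays).
#' @param baseline_mean,baseline_sd Baseline expression level distribution.
#' @param seed Optional integer seed.
#' @return An [expression_matrix()] with two entries in `$replicates`,
#'   suitable for [estimate_noise_threshold()].
#' @export
simulate_replicate_noise <- function(n_genes = 2000L,
                                     times = c(0, 0.5, 1, 3, 6, 12, 24),
                                     mean_abs = 0.156, sd_abs = 0.19,
                                     baseline_mean = 8, baseline_sd = 2,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_genes <- as.integer(n_genes)
  t_len <- length(times)
  base <- matrix(stats::rnorm(n_genes * t_len, baseline_mean, baseline_sd),
                 n_genes, t_len)
  if (mean_abs <= 0) {
    delta <- matrix(0, n_genes, t_len)
  } else {
    shape <- (mean_abs / sd_abs)^2
    mag <- stats::rgamma(n_genes * t_len, shape = shape,
                         scale = sd_abs^2 / mean_abs)
    delta <- matrix(mag * sample(c(-1, 1), n_genes * t_len, replace = TRUE),
                    n_genes, t_len)
  }
  r1 <- base + delta / 2
  r2 <- base - delta / 2
  expression_matrix((r1 + r2) / 2, times, "replicated",
                    gene_ids = sprintf("G%05d", seq_len(n_genes)),
                    replicates = list(r1, r2))
}
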
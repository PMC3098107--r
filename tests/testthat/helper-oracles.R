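# Independent brute-force oracles used to check the implementation.

# Shannon entropy via natural logs on the raw probability vector
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(2)
}

# Mann-Whitney U through the pair-counting definition (not rank sums)
oracle_u_pairs <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# exhaustive two-sided permutation p-value for the MWU test, ties included
oracle_mwu_p <- function(x, y) {
  pool <- c(x, y)
  m <- length(x)
  mu <- m * length(y) / 2
  u_obs <- oracle_u_pairs(x, y)
  sets <- utils::combn(length(pool), m)
  u_all <- apply(sets, 2, function(idx) {
    oracle_u_pairs(pool[idx], pool[-idx])
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# two-sided Fisher p by summing hypergeometric probabilities over all tables
# with the observed margins
oracle_fisher_p <- function(a, b, c2, d2) {
  m1 <- a + b          # selected
  k1 <- a + c2         # in category
  n_tot <- a + b + c2 + d2
  p_obs <- stats::dhyper(a, k1, n_tot - k1, m1)
  support <- max(0, m1 + k1 - n_tot):min(m1, k1)
  probs <- stats::dhyper(support, k1, n_tot - k1, m1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive all-pairs correlation degree
oracle_degree <- function(values, r_threshold) {
  n <- nrow(values)
  deg <- integer(n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    r <- suppressWarnings(stats::cor(values[i, ], values[j, ]))
    if (is.finite(r) && abs(r) > r_threshold) {
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
    }
  }
  deg
}

# naive average-linkage agglomeration; returns sorted merge heights
oracle_average_linkage_heights <- function(mat) {
  clusters <- as.list(seq_len(nrow(mat)))
  d <- as.matrix(stats::dist(mat))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# a tiny expression matrix with named rows
make_matrix <- function(values, condition = "test",
                        times = seq_len(ncol(values))) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  expression_matrix(values, times, condition = condition)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "pentropy", mustWork = TRUE)
}
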
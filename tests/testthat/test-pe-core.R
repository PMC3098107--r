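test_that("the thresholded codec realizes exactly the 13 weak orderings", {
  d_e <- 0.35
  # grid with sub-threshold (0.1) and supra-threshold (>= 0.4) spacings covers
  # every achievable configuration of thresholded comparisons
  vals <- c(0, 0.1, 0.5, 0.6, 1.0, 1.5)
  grid <- expand.grid(x1 = vals, x2 = vals, x3 = vals)
  codes <- mapply(function(a, b, c) as.integer(encode_window(a, b, c, d_e)),
                  grid$x1, grid$x2, grid$x3)
  expect_setequal(unique(codes), 1:13)
  # single-valued: the same thresholded-sign configuration never yields two codes
  signs <- mapply(function(a, b, c) {
    s <- attr(encode_window(a, b, c, d_e), "signs")
    paste(ifelse(is.na(s), ".", s), collapse = ",")
  }, grid$x1, grid$x2, grid$x3)
  expect_true(all(tapply(codes, signs, function(x) length(unique(x))) == 1L))
})

test_that("encode_window agrees with the documented pattern table", {
  # one hand-built window per class (d_e = 0.35)
  windows <- list(
    `1` = c(0, 1, 2),       `2` = c(2, 1, 0),
    `3` = c(0, 1, -1),      `4` = c(0, 1, 0.5),
    `5` = c(1, 0, 0.5),     `6` = c(0, -1, 0.5),
    `7` = c(0, 1, 0),       `8` = c(0, -1, 0.1),
    `9` = c(0, 0.1, 1),     `10` = c(0, 0.1, -1),
    `11` = c(0, 1, 1.1),    `12` = c(0, -1, -1.1),
    `13` = c(0, 0.1, 0.2))
  for (k in names(windows)) {
    w <- windows[[k]]
    code <- encode_window(w[1], w[2], w[3], d_e = 0.35)
    expect_identical(as.integer(code), as.integer(k))
    s <- attr(code, "signs")
    expect_identical(unname(s[["s1"]]), pe_patterns$s1[as.integer(k)])
    expect_identical(unname(s[["s2"]]), pe_patterns$s2[as.integer(k)])
  }
  expect_error(encode_window(0, NA, 1), "finite")
  # a difference of exactly d_e counts as changed
  expect_identical(as.integer(encode_window(0, 0.35, 0.7, d_e = 0.35)), 1L)
})

test_that("encoding is shift invariant and jointly scale covariant", {
  set.seed(42)
  for (i in 1:200) {
    x <- rnorm(3, sd = 2)
    d_e <- runif(1, 0.05, 0.6)
    base <- as.integer(encode_window(x[1], x[2], x[3], d_e))
    shift <- rnorm(1, sd = 10)
    expect_identical(
      as.integer(encode_window(x[1] + shift, x[2] + shift, x[3] + shift, d_e)),
      base)
    k <- runif(1, 0.1, 5)
    expect_identical(
      as.integer(encode_window(k * x[1], k * x[2], k * x[3], k * d_e)),
      base)
  }
})

test_that("time reversal permutes patterns bijectively and preserves PE", {
  d_e <- 0.35
  vals <- c(0, 0.1, 0.5, 1.0, 1.5)
  grid <- expand.grid(x1 = vals, x2 = vals, x3 = vals)
  fwd <- mapply(function(a, b, c) as.integer(encode_window(a, b, c, d_e)),
                grid$x1, grid$x2, grid$x3)
  rev_ <- mapply(function(a, b, c) as.integer(encode_window(c, b, a, d_e)),
                 grid$x1, grid$x2, grid$x3)
  mirror <- tapply(rev_, fwd, unique)
  expect_true(all(lengths(mirror) == 1L))            # well-defined map
  expect_setequal(unlist(mirror), 1:13)              # bijection
  set.seed(7)
  for (i in 1:50) {
    x <- cumsum(rnorm(7))
    expect_equal(permutation_entropy(encode_series(rev(x), d_e)),
                 permutation_entropy(encode_series(x, d_e)))
  }
})

test_that("permutation entropy matches the worked extreme and midway cases", {
  expect_identical(permutation_entropy(c(5)), 0)
  expect_equal(permutation_entropy(rep(1, 5)), log2(5), tolerance = 1e-12)
  expect_equal(round(permutation_entropy(rep(1, 5)), 2), 2.32)
  expect_equal(permutation_entropy(c(4, 1)), 0.7219281, tolerance = 1e-6)
  expect_error(permutation_entropy(numeric(0)), "non-empty")
  expect_error(permutation_entropy(c(0, 0)), "observed")
})

test_that("permutation entropy equals an independent Shannon computation", {
  set.seed(11)
  for (i in 1:100) {
    counts <- rpois(sample(2:13, 1), lambda = 3)
    if (sum(counts) == 0) counts[1] <- 1
    expect_equal(permutation_entropy(counts), oracle_entropy(counts),
                 tolerance = 1e-12)
  }
})

test_that("the achievable PE spectrum is the partition-generated set", {
  v5 <- achievable_pe_values(5)
  expect_length(v5, 7L)
  expect_identical(v5[1], 0)
  expect_equal(max(v5), log2(5), tolerance = 1e-12)
  expect_identical(achievable_pe_values(1), 0)
  # independent oracle for 4 windows: enumerate all 13^4 window labellings
  labellings <- expand.grid(rep(list(1:13), 4))
  ent <- apply(labellings, 1, function(r) oracle_entropy(tabulate(r, 13)))
  expect_equal(achievable_pe_values(4), sort(unique(round(ent, 12))),
               tolerance = 1e-9)
  expect_length(achievable_pe_values(4), 5L)
})

test_that("encode_series slides one window at a time", {
  up <- encode_series(c(5, 6, 7, 8, 9, 10, 11))
  expect_identical(unname(up$counts[1]), 5L)
  expect_identical(up$n_windows, 5L)
  flat <- encode_series(rep(3, 7))
  expect_identical(unname(flat$counts[13]), 5L)
  expect_error(encode_series(c(1, 2)), "at least 3")
  # five distinct strict patterns in succession
  x <- c(8, 9, 7, 8, 7.5, 6.5, 8.5)
  expect_identical(encode_series(x)$codes, c(3L, 5L, 4L, 2L, 6L))
  expect_equal(permutation_entropy(encode_series(x)), log2(5))
})

test_that("every series PE lies in the achievable discrete set", {
  set.seed(13)
  achievable <- achievable_pe_values(5)
  for (i in 1:200) {
    x <- cumsum(rnorm(7, sd = 0.8))
    pe <- permutation_entropy(encode_series(x))
    expect_true(min(abs(pe - achievable)) < 1e-9)
    expect_true(pe >= 0 && pe <= log2(5) + 1e-12)
  }
})

test_that("pattern spectrum pools counts across series", {
  expect_identical(unname(pattern_spectrum(list(rep(0, 7)))$counts[13]), 5L)
  series <- list(c(5, 6, 7, 8, 9, 10, 11), rep(1, 7),
                 c(8, 9, 7, 8, 7.5, 6.5, 8.5))
  pooled <- pattern_spectrum(series)
  indiv <- Reduce(`+`, lapply(series, function(s) encode_series(s)$counts))
  expect_identical(pooled$counts, indiv)
  expect_identical(pooled$n_windows, 15L)
  expect_error(pattern_spectrum(list()), "empty")
  # matrix and list inputs agree
  m <- do.call(rbind, series)
  expect_identical(pattern_spectrum(m)$counts, pooled$counts)
})
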
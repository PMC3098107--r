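times7 <- c(0, 0.5, 1, 3, 6, 12, 24)

test_that("the PE table reproduces designed entropies and sums", {
  flat <- make_matrix(matrix(2, 5, 7), "c1", times7)
  tab <- pe_table(list(flat))
  expect_true(all(tab$pe == 0))
  expect_true(all(tab$pe_sum == 0))
  # ten identical conditions: pe_sum is 10x the single-condition PE
  set.seed(61)
  vals <- matrix(cumsum(rnorm(70, sd = 0.8)), 10, 7)
  rownames(vals) <- sprintf("g%02d", 1:10)
  mats <- lapply(1:10, function(k) {
    expression_matrix(vals, times7, condition = paste0("c", k))
  })
  tab <- pe_table(mats)
  expect_equal(tab$pe_sum, 10 * tab$pe[, 1], ignore_attr = TRUE)
  # designed pattern multisets from the generator are recovered exactly
  sim <- simulate_experiment(simulation_spec(n_genes = 60, noise_sd = 0,
                                             seed = 62))
  tab <- pe_table(list(sim$control), 0.35)
  expect_equal(unname(tab$pe[, "control"]), sim$truth$control_pe,
               tolerance = 1e-12)
  bad <- make_matrix(matrix(1, 3, 7), "other", times7)
  expect_error(pe_table(list(flat, bad)), "gene set")
})

test_that("the MWU test matches the exhaustive permutation null", {
  cases <- list(
    list(x = c(1, 2, 3), y = c(4, 5, 6)),
    list(x = c(1, 1, 2, 2), y = c(1, 2, 2, 3)),          # heavy ties
    list(x = c(0, 0, 0, 2.32), y = c(0, 0.72, 0.72, 1.52, 2.32)),
    list(x = rep(1, 5), y = rep(1, 5)),                  # all tied
    list(x = c(5, 7), y = c(1, 2, 3, 4, 6, 8, 9, 10)))   # m != n
  for (cs in cases) {
    got <- mwu_test(cs$x, cs$y)
    expect_match(got$method, "exact")
    expect_equal(got$statistic, oracle_u_pairs(cs$x, cs$y))
    expect_equal(got$p.value, oracle_mwu_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("the approximate MWU agrees with wilcox.test on large samples", {
  set.seed(71)
  for (i in 1:5) {
    x <- sample(seq(0, 2.32, length.out = 7), 300, replace = TRUE)
    y <- sample(seq(0, 2.32, length.out = 7), 250, replace = TRUE)
    got <- mwu_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("condition comparison reports shift and significance", {
  set.seed(81)
  vals <- matrix(cumsum(rnorm(140, sd = 0.8)), 20, 7)
  rownames(vals) <- sprintf("g%02d", 1:20)
  m1 <- expression_matrix(vals, times7, condition = "control")
  m2 <- expression_matrix(vals, times7, condition = "stress")
  tab <- pe_table(list(m1, m2))
  cmp <- compare_conditions(tab, "stress", "control")
  expect_equal(cmp$delta_mean, 0)
  expect_equal(cmp$delta_median, 0)
  expect_gt(cmp$p.value, 0.9)
  expect_error(compare_conditions(tab, "heat", "control"), "heat")
})

test_that("top/bottom comparison splits by pe_sum with deterministic ties", {
  set.seed(91)
  sim <- simulate_experiment(simulation_spec(n_genes = 200, seed = 91))
  tab <- pe_table(list(sim$control, sim$stress))
  # identical feature: identical summaries, p ~ 1
  f <- rep(3.5, 200)
  names(f) <- tab$gene_ids
  cmp <- top_bottom_compare(tab, f, 50)
  expect_equal(cmp$top$mean, cmp$bottom$mean)
  expect_equal(cmp$top$median, cmp$bottom$median)
  expect_gt(cmp$p.value, 0.9)
  # the ranking statistic itself separates strictly
  cmp <- top_bottom_compare(tab, setNames(tab$pe_sum, tab$gene_ids), 50)
  expect_gt(cmp$top$mean, cmp$bottom$mean)
  expect_error(top_bottom_compare(tab, f, 150), "2 \\* k")
})

test_that("a feature coupled to pe_sum is detected in the group contrast", {
  set.seed(101)
  sim <- simulate_experiment(simulation_spec(n_genes = 4000, seed = 101))
  tab <- pe_table(list(sim$control, sim$stress))
  feature <- 1000 + 400 * tab$pe_sum + rnorm(4000, sd = 600)
  names(feature) <- tab$gene_ids
  cmp <- top_bottom_compare(tab, feature, 500)
  expect_gt(cmp$top$median, cmp$bottom$median)
  expect_lt(cmp$p.value, 0.01)
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  # a printed 2x2 table: selected 8 in / 2 out, rest 1 in / 5 out
  selected <- sprintf("s%02d", 1:10)
  rest <- sprintf("r%02d", 1:6)
  background <- c(selected, rest)
  ann <- data.frame(gene_id = c(selected[1:8], rest[1]), category = "cat")
  res <- enrichment(selected, background, ann)
  expect_identical(res$selected_in, 8L)
  expect_identical(res$rest_in, 1L)
  expect_equal(res$p, oracle_fisher_p(8, 2, 1, 5), tolerance = 1e-9)
  expect_identical(res$direction, "over")
  expect_equal(res$fdr, res$p)   # single category: BH leaves p unchanged
})

test_that("enrichment handles degenerate selections and categories", {
  bg <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene_id = c(bg[1:5], "not_in_bg"),
                    category = c(rep("a", 5), "ghost"))
  # categories with no background member are excluded
  res <- enrichment(bg[1:4], bg, ann)
  expect_identical(res$category, "a")
  # selected = background: everything has p = 1
  res <- enrichment(bg, bg, ann)
  expect_true(all(res$p == 1))
  expect_error(enrichment(c("zz"), bg, ann), "subset")
  expect_error(enrichment(character(0), character(0), ann), "empty")
})

test_that("BH correction is monotone and bounded", {
  set.seed(111)
  bg <- sprintf("g%03d", 1:200)
  ann <- data.frame(gene_id = sample(bg, 400, replace = TRUE),
                    category = sample(letters[1:10], 400, replace = TRUE))
  res <- enrichment(sample(bg, 50), bg, ann)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  byp <- res[order(res$p), ]
  expect_true(all(diff(byp$fdr) >= -1e-12))
  expect_equal(byp$fdr, p.adjust(byp$p, "BH"), tolerance = 1e-12)
})

test_that("category means recombine to the global mean", {
  set.seed(121)
  sim <- simulate_experiment(simulation_spec(n_genes = 100, seed = 121))
  tab <- pe_table(list(sim$control, sim$stress))
  # one category holding every gene reproduces the per-condition mean
  ann_all <- data.frame(gene_id = tab$gene_ids, category = "all")
  m <- mean_pe_by_category(tab, ann_all)
  expect_equal(m["all", ], colMeans(tab$pe), tolerance = 1e-12)
  # random disjoint categories: size-weighted rows give the global mean
  grp <- sample(c("a", "b", "c"), 100, replace = TRUE)
  ann <- data.frame(gene_id = tab$gene_ids, category = grp)
  m <- mean_pe_by_category(tab, ann)
  w <- as.vector(table(grp)[rownames(m)])
  expect_equal(colSums(m * w) / sum(w), colMeans(tab$pe), tolerance = 1e-12)
  expect_error(mean_pe_by_category(tab, data.frame(gene_id = "zz",
                                                   category = "x")),
               "no annotated")
})

test_that("designed extreme categories give rows 0 and log2(5)", {
  flat <- matrix(2, 4, 7)
  rownames(flat) <- sprintf("lo%d", 1:4)
  busy <- t(vapply(1:4, function(i) series_from_patterns(c(3, 5, 4, 2, 6),
                                                         start = 8),
                   numeric(7)))
  rownames(busy) <- sprintf("hi%d", 1:4)
  m <- make_matrix(rbind(flat, busy), "c", times7)
  tab <- pe_table(list(m))
  ann <- data.frame(gene_id = m$gene_ids,
                    category = rep(c("low", "high"), each = 4))
  cm <- mean_pe_by_category(tab, ann)
  expect_equal(unname(cm["low", 1]), 0)
  expect_equal(unname(cm["high", 1]), log2(5), tolerance = 1e-12)
})

test_that("biclustering reproduces an independent average-linkage oracle", {
  set.seed(131)
  mat <- rbind(a1 = c(0, 0.1, 0, 0.2), a2 = c(0.1, 0, 0.1, 0.1),
               b1 = c(2, 2.2, 2.1, 2), b2 = c(2.1, 2, 2.2, 2.1))
  colnames(mat) <- paste0("c", 1:4)
  bc <- bicluster(mat)
  expect_equal(sort(bc$row_tree$height),
               oracle_average_linkage_heights(mat), tolerance = 1e-12)
  # well-separated blocks end up contiguous in leaf order
  lab <- substr(rownames(mat)[bc$row_order], 1, 1)
  expect_true(identical(lab, c("a", "a", "b", "b")) ||
                identical(lab, c("b", "b", "a", "a")))
  # identical rows merge first at height 0
  mat2 <- rbind(x = c(1, 2, 3), y = c(1, 2, 3), z = c(9, 1, 4))
  bc2 <- bicluster(mat2[, 1:3])
  expect_equal(bc2$row_tree$height[1], 0)
  expect_setequal(abs(bc2$row_tree$merge[1, ]), c(1, 2))
  expect_error(bicluster(mat[1, , drop = FALSE]), "at least 2")
})

test_that("bicluster topology is invariant to row permutation", {
  set.seed(141)
  mat <- matrix(rnorm(30), 6, 5,
                dimnames = list(letters[1:6], paste0("c", 1:5)))
  bc1 <- bicluster(mat)
  perm <- sample(6)
  bc2 <- bicluster(mat[perm, ])
  expect_equal(sort(bc1$row_tree$height), sort(bc2$row_tree$height),
               tolerance = 1e-12)
  expect_identical(rownames(bc1$reordered)[bc1$row_order == bc1$row_order],
                   rownames(bc1$reordered))
  expect_setequal(rownames(bc2$reordered), rownames(mat))
})
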
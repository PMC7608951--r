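# log2cpm matrix for the early/late comparison with n replicates each
two_cond <- function(vals_early, vals_late) {
  n <- ncol(vals_early)
  toy_log2cpm(cbind(vals_early, vals_late),
              conditions = rep("control", 2 * n),
              cycle_labels = rep(c("C12", "C14L"), each = n))
}

test_that("zygotic identification applies strict FC and p cuts", {
  set.seed(5)
  # identical means -> excluded
  m <- matrix(rnorm(6, 5, 0.01), 1)
  x <- two_cond(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
  res <- identify_zygotic(x, late = "control:C14L", early = "control:C12")
  expect_false(res$zygotic)
  # fold change exactly at the threshold -> excluded (strict >)
  e <- matrix(rep(5, 6), 1)
  l <- e + log2(1.5)
  res2 <- identify_zygotic(two_cond(e[, 1:3, drop = FALSE],
                                    l[, 4:6, drop = FALSE]))
  expect_equal(res2$fold_change, 1.5)
  expect_false(res2$zygotic)
  # replicate requirements are enforced
  solo <- toy_log2cpm(matrix(1:3 + 0, 1), rep("control", 3),
                      c("C12", "C14L", "C14L"))
  expect_error(identify_zygotic(solo), "fewer than 2 replicates")
  expect_error(identify_zygotic(x, late = "control:C99"), "not present")
})

test_that("planted up-regulated genes are recovered with no false positives", {
  set.seed(17)
  n_up <- 20; n_null <- 200; reps <- 3
  base <- matrix(rnorm((n_up + n_null) * reps, 6, 0.1), ncol = reps)
  late <- base + rnorm(length(base), 0, 0.1)
  late[seq_len(n_up), ] <- late[seq_len(n_up), ] + 2  # planted Delta = 2 log2
  vals <- cbind(base, late)
  rownames(vals) <- c(sprintf("up%02d", seq_len(n_up)),
                      sprintf("null%03d", seq_len(n_null)))
  x <- toy_log2cpm(vals, rep("control", 2 * reps),
                   rep(c("C12", "C14L"), each = reps))
  res <- identify_zygotic(x)
  expect_true(all(res$zygotic[seq_len(n_up)]))
  expect_equal(sum(res$zygotic[-seq_len(n_up)]), 0)
})

test_that("prior-list intersection is exact and order-stable", {
  expect_identical(intersect_with_prior(c("c", "a", "b"), c("b", "c", "z")),
                   c("c", "b"))
  expect_identical(intersect_with_prior(c("a", "b"), c("x", "y")),
                   character(0))
  expect_identical(intersect_with_prior(c("a", "b"), c("a", "b", "c")),
                   c("a", "b"))
})

test_that("arrest-response grouping follows the three-way rule", {
  conds <- c(rep("control", 2), rep("arrested", 8))
  labs <- c("C12", "C12", rep(c("15", "30", "50", "70"), each = 2))
  mk <- function(...) {
    profs <- rbind(...)
    vals <- profs[, c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5), drop = FALSE]
    rownames(vals) <- rownames(profs)
    toy_log2cpm(vals, conds, labs)
  }
  # columns: baseline, 15', 30', 50', 70'
  x <- mk(rise  = c(1, 2, 3, 4, 5),     # monotone increase -> group 1
          dip   = c(3, 2.5, 1, 1, 2),   # dip at 30/50, rise at 70 -> group 2
          fall  = c(5, 4, 3, 2, 1))     # monotone decrease -> group 3
  g <- categorize_groups(x, c("rise", "dip", "fall"))
  expect_equal(g$genes$group, c(1L, 2L, 3L))
  expect_equal(unname(g$counts), c(1L, 1L, 1L))
  # partition invariant
  expect_equal(sum(g$counts), 3L)
  # non-group-1 genes are exactly the initial-decrease genes
  expect_equal(sum(!g$genes$initial_decrease), sum(g$genes$group == 1L))
  # gene order does not change labels
  g2 <- categorize_groups(x, c("fall", "rise", "dip"))
  expect_equal(g2$genes$group[match(g$genes$gene_id, g2$genes$gene_id)],
               g$genes$group)
  expect_error(categorize_groups(x, character(0)), "no genes")
  # missing arrest condition is reported
  x2 <- toy_log2cpm(matrix(1:4 + 0, 1), c("control", "control",
                                          "arrested", "arrested"),
                    c("C12", "C12", "15", "15"))
  expect_error(categorize_groups(x2, rownames(x2$values)), "missing condition")
})

test_that("grouping is invariant to unrelated genes in the matrix", {
  conds <- c(rep("control", 2), rep("arrested", 8))
  labs <- c("C12", "C12", rep(c("15", "30", "50", "70"), each = 2))
  profs <- rbind(rise = c(1, 2, 3, 4, 5), junk1 = c(9, 1, 9, 1, 9),
                 junk2 = c(0, 0, 5, 0, 0))
  vals <- profs[, c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)]
  rownames(vals) <- rownames(profs)
  x <- toy_log2cpm(vals, conds, labs)
  g <- categorize_groups(x, "rise")
  expect_equal(g$genes$group, 1L)
  expect_equal(nrow(g$genes), 1L)
})

test_that("maternal selection keeps only genes decreasing in controls", {
  vals <- rbind(down = c(5, 5, 2, 2), up = c(2, 2, 5, 5),
                flat = c(3, 3, 3, 3))
  x <- toy_log2cpm(vals, rep("control", 4), rep(c("C12", "C14L"), each = 2))
  expect_identical(select_maternal(c("down", "up", "flat"), x), "down")
  # with a positive margin a flat gene is excluded even under tiny noise
  expect_identical(select_maternal(c("down", "flat"), x, margin = 0.5),
                   "down")
  expect_identical(select_maternal("absent", x), character(0))
})

test_that("feature enrichment matches a hypergeometric oracle", {
  a <- paste0("a", 1:10); b <- paste0("b", 1:10)
  # perfectly separated table [[10,0],[0,10]]
  fe <- feature_enrichment(a, b, feature_members = a)
  expect_equal(unname(fe$table), matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  # oracle: enumerate the hypergeometric tail probabilities directly
  p_oracle <- sum(stats::dhyper(0:10, 10, 10, 10)[
    stats::dhyper(0:10, 10, 10, 10) <= stats::dhyper(10, 10, 10, 10) + 1e-12])
  expect_equal(fe$p_value, p_oracle, tolerance = 1e-10)
  # even split: odds ratio 1, p = 1
  even <- feature_enrichment(a, b, feature_members = c(a[1:5], b[1:5]))
  expect_equal(even$odds_ratio, 1, tolerance = 1e-8)
  expect_equal(even$p_value, 1)
  # swapping the sets inverts the odds ratio
  f <- c(a[1:8], b[1:2])
  fe1 <- feature_enrichment(a, b, f)
  fe2 <- feature_enrichment(b, a, f)
  expect_equal(fe1$odds_ratio, 1 / fe2$odds_ratio, tolerance = 1e-6)
  expect_error(feature_enrichment(a, c(a[1], b), f), "disjoint")
  expect_error(feature_enrichment(character(0), b, f), "non-empty")
})

test_that("gene lists read back from one-column files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("gA", "gB", "gC"), path)
  expect_identical(read_gene_list(path), c("gA", "gB", "gC"))
})
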
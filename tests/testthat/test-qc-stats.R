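test_that("cell filtering applies the gene filter first, then cell rules", {
  # genes g1..g5 + one mitochondrial gene; thresholds: gene in >= 2 cells,
  # >= 3 qualifying genes per cell, mito <= 7%
  counts <- rbind(
    g1 = c(A = 20, B = 99, C = 20),
    g2 = c(30, 0, 30),
    g3 = c(25, 0, 25),
    g4 = c(23, 0, 20),
    g5 = c(0, 0, 20),          # present in one cell only -> dropped first
    `mt-x` = c(2, 1, 10))      # mito totals: A 2/100, B 1/100, C 10/125
  th <- qc_thresholds(min_genes_per_cell = 3, max_mito_fraction = 0.07,
                      min_cells_per_gene = 2)
  f <- filter_cells(counts, th)
  expect_equal(colnames(f$counts), "A")
  expect_equal(f$report$dropped_genes, "g5")
  expect_setequal(f$report$dropped_cells$cell_id, c("B", "C"))
  expect_equal(f$report$dropped_cells$reason[
    f$report$dropped_cells$cell_id == "B"], "too_few_genes")
  expect_equal(f$report$dropped_cells$reason[
    f$report$dropped_cells$cell_id == "C"], "high_mito_fraction")
  # g5 is absent from the output and from the per-cell gene tally
  expect_false("g5" %in% rownames(f$counts))
  expect_equal(unname(f$report$genes_expressed["C"]), 5)
  expect_equal(unname(f$report$mito_fraction["C"]), 0.08)
})

test_that("filtering is idempotent when the table is stable", {
  counts <- matrix(5, nrow = 6, ncol = 4,
                   dimnames = list(c(paste0("g", 1:5), "mt-x"),
                                   paste0("c", 1:4)))
  th <- qc_thresholds(min_genes_per_cell = 3, max_mito_fraction = 0.5,
                      min_cells_per_gene = 2)
  f1 <- filter_cells(counts, th)
  expect_equal(f1$counts, counts)  # all cells identical and passing
  f2 <- filter_cells(f1$counts, th)
  expect_equal(f2$counts, f1$counts)
})

test_that("gene-then-cell order changes the survivor set on a crafted table", {
  # cell B expresses 3 genes, but one of them (g3) fails the gene filter, so
  # under the documented order B drops below the 3-gene threshold
  counts <- rbind(
    g1 = c(A = 10, B = 10, C = 10),
    g2 = c(10, 10, 10),
    g3 = c(0, 10, 0),
    g4 = c(10, 0, 10))
  th <- qc_thresholds(min_genes_per_cell = 3, max_mito_fraction = 1,
                      min_cells_per_gene = 2)
  f <- filter_cells(counts, th)
  expect_setequal(colnames(f$counts), c("A", "C"))
  # a cell-first tally (all genes) would have kept B as well
  expect_true(all(colSums(counts > 0) >= 3))
  expect_error(filter_cells(counts[0, , drop = FALSE], th), "empty")
})

test_that("delta-delta-Ct identities hold", {
  ref <- c(15, 15, 15)
  ctrl <- list(target_ct = c(20, 20, 20), reference_ct = ref)
  same <- ddct_knockdown(ctrl, ctrl)
  expect_equal(same$knockdown_pct, 0)
  expect_equal(same$relative_expression, 1)
  two <- ddct_knockdown(list(target_ct = c(22, 22, 22), reference_ct = ref),
                        ctrl)
  expect_equal(two$dd_ct, 2)
  expect_equal(two$knockdown_pct, 75)
  # ddCt solving 2^-x = 0.2 gives 80% knockdown
  x <- ddct_knockdown(list(target_ct = 20 + 2.3219281, reference_ct = 15),
                      ctrl)
  expect_equal(x$knockdown_pct, 80, tolerance = 1e-6)
  # knockdown is strictly increasing in ddCt, and
  # relative_expression == 1 - knockdown/100 at every point
  dd <- seq(-2, 6, by = 0.5)
  kd <- vapply(dd, function(d) {
    r <- ddct_knockdown(list(target_ct = 20 + d, reference_ct = 15), ctrl)
    expect_equal(r$relative_expression, 1 - r$knockdown_pct / 100)
    r$knockdown_pct
  }, numeric(1))
  expect_true(all(diff(kd) > 0))
  expect_error(ddct_knockdown(list(target_ct = 1), ctrl), "reference_ct")
})

test_that("qPCR plate tables round-trip into measurements", {
  tab <- data.frame(
    sample = rep(c("ctrl", "test"), each = 6),
    role = rep(rep(c("target", "reference"), each = 3), 2),
    ct = c(20, 20, 20, 15, 15, 15, 22, 22, 22, 15, 15, 15))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_qpcr_table(path)
  expect_setequal(names(m), c("ctrl", "test"))
  expect_equal(ddct_knockdown(m$test, m$ctrl)$knockdown_pct, 75)
})

test_that("Welch's t matches the closed-form oracle to 1e-8", {
  r <- compare_two(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- compare_two(c(0, 0, 1, 1), c(10, 10, 11, 11))
  expect_lt(r$p_value, 0.001)
  set.seed(77)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1), sample(0:3, 1))
    b <- rnorm(sample(3:9, 1))
    r <- compare_two(a, b)
    o <- welch_oracle(a, b)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-8)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-8)
    expect_equal(r$df, o$df, tolerance = 1e-8)
  }
  # degenerate constant groups
  expect_equal(compare_two(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(compare_two(c(2, 2), c(3, 3))$p_value, 0)
})

test_that("multi-group comparison routes on the Bartlett gate", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- compare_many(g)
  expect_equal(r$p_value, 1)
  expect_true(all(r$pairwise$p_adj > 0.99))
  # equal variances, shifted means: classic ANOVA + Tukey, oracle-checked
  set.seed(21)
  g <- lapply(c(0, 1, 4), function(m) rnorm(8, m))
  names(g) <- c("a", "b", "c")
  r <- compare_many(g)
  expect_equal(r$route, "anova_tukey")
  o <- anova_oracle(g)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-8)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-8)
  expect_equal(r$pairwise$adjustment, rep("tukey", 3))
  # an inflated-variance group trips Bartlett into the Welch path
  set.seed(22)
  g$c <- rnorm(8, 4, 30)
  r <- compare_many(g)
  expect_equal(r$route, "welch_dunnett_t3")
  expect_lt(r$bartlett_p, 0.05)
  ow <- oneway.test(c(g$a, g$b, g$c) ~ rep(c("a", "b", "c"), each = 8),
                    var.equal = FALSE)
  expect_equal(r$statistic, unname(ow$statistic), tolerance = 1e-8)
  # adjusted p never below raw p
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw - 1e-12))
  # constant group: Bartlett undefined, warn and use the Welch path
  g$c <- c(5, 5, 5, 5, 5, 5, 5, 5)
  expect_warning(r <- compare_many(g), "constant")
  expect_equal(r$route, "welch_dunnett_t3")
})

test_that("Kruskal-Wallis/Dunn matches closed forms; BH keeps monotone order", {
  r <- kruskal_dunn(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  o <- kw_oracle(list(1:3, 4:6, 7:9))
  expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-10)
  # Dunn z for the no-tie 1..9 layout: sigma = sqrt(5), mean ranks 2/5/8
  expect_equal(r$pairwise$statistic,
               c(-3, -6, -3) / sqrt(5), tolerance = 1e-8)
  expect_equal(r$pairwise$p_raw,
               2 * pnorm(-abs(c(-3, -6, -3) / sqrt(5))), tolerance = 1e-10)
  expect_equal(r$pairwise$p_adj, p.adjust(r$pairwise$p_raw, "BH"))
  # identical observations: H = 0, p = 1
  r0 <- kruskal_dunn(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # two-group case with ties agrees with the tie-corrected oracle
  g <- list(a = c(1, 2, 2, 3, 5), b = c(2, 4, 4, 6))
  r2 <- kruskal_dunn(g)
  o2 <- kw_oracle(g)
  expect_equal(r2$statistic, o2$statistic, tolerance = 1e-8)
  expect_equal(r2$p_value, o2$p_value, tolerance = 1e-8)
  # BH preserves the ordering of the raw p-values
  set.seed(9)
  g3 <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 3), d = rnorm(6))
  r3 <- kruskal_dunn(g3)
  ord <- order(r3$pairwise$p_raw)
  expect_true(all(diff(r3$pairwise$p_adj[ord]) >= -1e-12))
  expect_true(all(r3$pairwise$p_adj >= r3$pairwise$p_raw - 1e-12))
})
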
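sig <- site_signature(study_endo, study_exo)

test_that("single reads are assigned by exact full-length site matching", {
  set.seed(31)
  r_endo <- planted_read(study_endo)
  ac <- count_allele_reads(c(r1 = r_endo), sig)
  expect_identical(ac$n_endo, 1L)
  expect_identical(ac$n_exo, 0L)
  # reverse complement of the exogenous site also counts
  ac <- count_allele_reads(c(r1 = planted_read(reverse_complement(study_exo))), sig)
  expect_identical(c(ac$n_endo, ac$n_exo), c(0L, 1L))
  # a single base error inside the site defeats the exact match
  broken <- r_endo
  pos <- 20 + 10  # inside the planted site
  substr(broken, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                      substr(broken, pos, pos))[1]
  ac <- count_allele_reads(c(r1 = broken), sig)
  expect_identical(c(ac$n_endo, ac$n_exo), c(0L, 0L))
  # an N inside the window also never matches
  substr(broken, pos, pos) <- "N"
  ac <- count_allele_reads(c(r1 = broken), sig)
  expect_identical(ac$n_site_reads, 0L)
})

test_that("a planted 60/40 endo/exo read set is counted exactly", {
  set.seed(1)
  reads <- c(vapply(1:60, function(i) planted_read(study_endo), ""),
             vapply(1:40, function(i) planted_read(study_exo), ""))
  names(reads) <- sprintf("r%03d", 1:100)
  ac <- count_allele_reads(reads, sig)
  expect_identical(c(ac$n_endo, ac$n_exo), c(60L, 40L))
  orc <- naive_count_oracle(reads, sig)
  expect_identical(ac$n_endo, as.integer(orc$n_endo))
  expect_identical(ac$n_exo, as.integer(orc$n_exo))
})

test_that("counter equals the naive substring oracle and is RC-invariant", {
  sim <- simulate_site_reads(3, 40, 0.3, sig, read_length = 60,
                             error_rate = 0.02, seed = 99)
  reads <- unlist(unname(sim$reads))
  ac <- count_allele_reads(reads, sig)
  orc <- naive_count_oracle(reads, sig)
  expect_identical(ac$n_endo, as.integer(orc$n_endo))
  expect_identical(ac$n_exo, as.integer(orc$n_exo))
  # reverse-complementing every read leaves counts unchanged
  ac_rc <- count_allele_reads(stats::setNames(reverse_complement(reads),
                                              names(reads)), sig)
  expect_identical(ac[c("n_endo", "n_exo")], ac_rc[c("n_endo", "n_exo")])
  # planting one extra site-bearing read adds exactly one endo fragment
  extra <- c(reads, extra_read = planted_read(study_endo, 5, 5))
  ac2 <- count_allele_reads(extra, sig)
  expect_identical(ac2$n_endo, ac$n_endo + 1L)
  expect_identical(ac2$n_exo, ac$n_exo)
})

test_that("mates collapse to fragments; dual-allele fragments are discarded", {
  set.seed(8)
  reads <- c(planted_read(study_endo), planted_read(study_endo))
  names(reads) <- c("frag1", "frag1")  # two mates of the same fragment
  ac <- count_allele_reads(reads, sig)
  expect_identical(ac$n_endo, 1L)
  expect_identical(ac$n_fragments, 1L)
  # one mate endogenous, the other exogenous: contradictory, count neither
  reads <- c(planted_read(study_endo), planted_read(study_exo))
  names(reads) <- c("frag1", "frag1")
  expect_warning(ac <- count_allele_reads(reads, sig), "both alleles")
  expect_identical(c(ac$n_endo, ac$n_exo, ac$n_ambiguous), c(0L, 0L, 1L))
  # reads shorter than the site are silently ignored
  ac <- count_allele_reads(c(r1 = "ACGT"), sig)
  expect_identical(ac$n_site_reads, 0L)
})

test_that("FASTQ round-trip preserves reads and mate ids", {
  set.seed(12)
  reads <- stats::setNames(c(planted_read(study_endo), planted_read(study_exo)),
                           c("a/1", "a/2"))
  fq <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(unname(back), unname(reads))
  expect_equal(names(back), c("a", "a"))  # mate suffix stripped
  expect_warning(count_allele_reads(fq, sig), "both alleles")
})

test_that("pooled allele fractions exclude siteless cells and sum to 100", {
  counts <- data.frame(n_endo = c(3, 0, 1), n_exo = c(1, 0, 3))
  fr <- pooled_allele_fraction(counts)
  expect_equal(fr$pct_endo, 50)
  expect_equal(fr$pct_exo, 50)
  expect_identical(fr$n_cells_used, 2L)
  fr <- pooled_allele_fraction(data.frame(n_endo = 0, n_exo = 5))
  expect_equal(c(fr$pct_endo, fr$pct_exo), c(0, 100))
  expect_error(pooled_allele_fraction(data.frame(n_endo = 0, n_exo = 0)),
               "undefined")
  # invariant to cell order and to appending zero-count cells
  set.seed(2)
  tab <- data.frame(n_endo = rpois(8, 4), n_exo = rpois(8, 2))
  tab$n_endo[1] <- tab$n_endo[1] + 1  # ensure nonzero
  f1 <- pooled_allele_fraction(tab)
  f2 <- pooled_allele_fraction(tab[sample(nrow(tab)), ])
  f3 <- pooled_allele_fraction(rbind(tab, data.frame(n_endo = 0, n_exo = 0)))
  expect_equal(f1$pct_endo, f2$pct_endo)
  expect_equal(f1$pct_endo, f3$pct_endo)
})

test_that("depth normalization is counts-per-million", {
  expect_equal(normalize_expression(5, 5e5), 10)
  expect_equal(normalize_expression(0, 1e6), 0)
  expect_equal(normalize_expression(123, 2e6), 61.5)
  expect_error(normalize_expression(1, 0), "positive")
  expect_error(normalize_expression(-1, 10), "nonnegative")
})

test_that("allele allocation conserves total expression exactly", {
  al <- allocate_allele_expression(200, 25, 75)
  expect_equal(al$endo_expression, 50)
  expect_equal(al$exo_expression, 150)
  al <- allocate_allele_expression(0, 40, 60)
  expect_equal(c(al$endo_expression, al$exo_expression), c(0, 0))
  al <- allocate_allele_expression(10, 0, 100)
  expect_equal(c(al$endo_expression, al$exo_expression), c(0, 10))
  set.seed(4)
  expr <- runif(50, 0, 1000)
  pct <- runif(1, 0, 100)
  al <- allocate_allele_expression(expr, pct, 100 - pct)
  expect_identical(al$endo_expression + al$exo_expression, expr)  # exact
  expect_error(allocate_allele_expression(1, 60, 60), "sum to 100")
  expect_error(allocate_allele_expression(-1, 50, 50), "nonnegative")
})

test_that("knockdown efficiency is one minus the treated/control mean ratio", {
  expect_equal(knockdown_efficiency(c(10, 20), c(100, 100)), 85)
  expect_equal(knockdown_efficiency(c(0, 0), c(50, 150)), 100)
  expect_equal(as.numeric(knockdown_efficiency(c(100, 100), c(100, 100))), 0)
  kd <- knockdown_efficiency(c(200, 200), c(100, 100))
  expect_true(kd < 0)
  expect_match(attr(kd, "flagged"), "exceeds")
  expect_error(knockdown_efficiency(c(1, 2), c(0, 0)), "zero")
  expect_error(knockdown_efficiency(numeric(0), c(1)), "non-empty")
})

test_that("group estimates combine fractions, allocation, and knockdown", {
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:6),
    group = rep(c("ctrl", "treated"), each = 3),
    n_endo = c(5, 4, 6, 1, 1, 0),
    n_exo = c(0, 0, 0, 3, 3, 4),
    tmc1_expression = c(100, 110, 90, 200, 180, 220))
  est <- group_allele_estimates(cells, control_group = "ctrl")
  g <- est$groups
  expect_equal(g$pct_endo[g$group == "ctrl"], 100)
  expect_equal(g$pct_exo[g$group == "treated"], 100 * 10 / 12)
  # allocation conserves per-cell totals
  pc <- est$per_cell
  expect_equal(pc$endo_expression + pc$exo_expression, pc$tmc1_expression)
  # treated endo mean = 200 * (2/12); control mean = 100
  expect_equal(g$knockdown_efficiency[g$group == "treated"],
               100 * (1 - 200 * (2 / 12) / 100))
  expect_equal(est$pooled_knockdown_efficiency,
               g$knockdown_efficiency[g$group == "treated"])
  expect_error(group_allele_estimates(cells, control_group = "nope"),
               "not present")
})
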
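# Seeded generators for every input the pipeline consumes: site-spanning
# reads with a known endogenous/exogenous mixture, per-cell expression tables
# with group effect sizes, and qPCR Ct triplicates. Each generator is a pure
# function of its arguments including `seed`, and returns a truth ledger so
# downstream estimates can be checked against ground truth.

nb_draw <- function(n, mu, dispersion) {
  # negative binomial parameterized by mean and dispersion (var = mu + mu^2*d);
  # dispersion <= 0 is the deterministic limit
  if (dispersion <= 0) rep(round(mu), n) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

apply_sequencing_error <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  len <- nchar(reads)
  for (i in seq_along(reads)) {
    hit <- which(stats::runif(len[i]) < error_rate)
    for (p in hit) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  reads
}

#' Simulate site-spanning reads with a known allele mixture
#'
#' Each read is a random flank, the allele's site sequence (endogenous or
#' exogenous, drawn Bernoulli(`exo_fraction`)) in a uniformly random strand
#' orientation, and a random flank, followed by per-base uniform substitution
#' error. Deterministic under `seed`.
#'
#' @param n_cells Number of cells.
#' @param reads_per_cell Site-spanning reads per cell.
#' @param exo_fraction True exogenous-allele proportion in \[0,1\].
#' @param signature A [site_signature()].
#' @param read_length Read length (must exceed the site length by >= 2).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param cell_prefix Prefix for generated cell ids.
#' @return List: `reads` (named list per cell of named read vectors),
#'   `truth` (data.frame `cell_id`, `read_id`, `allele`, `orientation`),
#'   `truth_by_cell` (data.frame `cell_id`, `n_endo_true`, `n_exo_true`),
#'   `exo_fraction` (the truth), `seed`.
#' @export
simulate_site_reads <- function(n_cells, reads_per_cell, exo_fraction,
                                signature, read_length = 100L,
                                error_rate = 0.005, seed = 1L,
                                cell_prefix = "cell") {
  stopifnot(inherits(signature, "site_signature"),
            n_cells >= 1, reads_per_cell >= 1,
            exo_fraction >= 0, exo_fraction <= 1,
            error_rate >= 0, error_rate < 1)
  site_len <- nchar(signature$endo)
  if (read_length < site_len + 2L) {
    stop("read_length must be at least site length + 2", call. = FALSE)
  }
  set.seed(seed)
  cells <- sprintf("%s%03d", cell_prefix, seq_len(n_cells))
  all_reads <- vector("list", n_cells)
  names(all_reads) <- cells
  truth <- vector("list", n_cells)
  flank_total <- read_length - site_len
  for (ci in seq_len(n_cells)) {
    n <- reads_per_cell
    allele <- ifelse(stats::runif(n) < exo_fraction, "exo", "endo")
    orient <- ifelse(stats::runif(n) < 0.5, "fwd", "rc")
    left_len <- sample.int(flank_total + 1L, n, replace = TRUE) - 1L
    site_seq <- ifelse(allele == "endo",
                       ifelse(orient == "fwd", signature$endo,
                              signature$endo_rc),
                       ifelse(orient == "fwd", signature$exo,
                              signature$exo_rc))
    # one random pool per cell; flanks are substrings at random offsets
    pool_left <- random_dna(n * flank_total + 1L)
    pool_right <- random_dna(n * flank_total + 1L)
    off_l <- sample.int(n * flank_total + 1L - flank_total, n, replace = TRUE)
    off_r <- sample.int(n * flank_total + 1L - flank_total, n, replace = TRUE)
    left <- substr(rep(pool_left, n), off_l, off_l + left_len - 1L)
    right <- substr(rep(pool_right, n), off_r,
                    off_r + (flank_total - left_len) - 1L)
    reads <- apply_sequencing_error(paste0(left, site_seq, right), error_rate)
    ids <- sprintf("%s_read%05d", cells[ci], seq_len(n))
    names(reads) <- ids
    all_reads[[ci]] <- reads
    truth[[ci]] <- data.frame(cell_id = cells[ci], read_id = ids,
                              allele = allele, orientation = orient,
                              stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  by_cell <- data.frame(
    cell_id = cells,
    n_endo_true = as.integer(tapply(truth$allele == "endo", truth$cell_id,
                                    sum)[cells]),
    n_exo_true = as.integer(tapply(truth$allele == "exo", truth$cell_id,
                                   sum)[cells]),
    stringsAsFactors = FALSE)
  list(reads = all_reads, truth = truth, truth_by_cell = by_cell,
       exo_fraction = exo_fraction, seed = seed)
}

#' Simulate a per-cell expression count table with group effect sizes
#'
#' Per-cell total expression of the gene of interest is drawn (in CPM units)
#' from a negative binomial with group mean `control_mean_cpm * fold_change`
#' and the given dispersion, then split into endogenous/exogenous components
#' by the group's true exogenous fraction. Sequencing depth is lognormal;
#' the gene's raw count is the CPM scaled to that depth, and filler plus
#' mitochondrial pseudo-genes are added so that QC filters are exercisable
#' and row sums approximate the drawn depth.
#'
#' @param groups data.frame with columns `group`, `n_cells`, `fold_change`,
#'   `exo_fraction`.
#' @param seed Integer seed.
#' @param control_mean_cpm Mean expression (CPM) at fold change 1.
#' @param dispersion Negative-binomial dispersion (var = mu + mu^2 * d).
#' @param gene Gene id of the gene of interest.
#' @param n_filler_genes Number of filler genes.
#' @param n_mito_genes Number of mitochondrial pseudo-genes (ids `mt-...`).
#' @param mito_fraction Expected mitochondrial share of reads per cell.
#' @param depth_meanlog,depth_sdlog Lognormal parameters of per-cell depth.
#' @return List: `counts` (genes x cells integer matrix), `cells`
#'   (data.frame `cell_id`, `group`, `total_mapped_reads`, `tmc1_raw`,
#'   `tmc1_cpm`), `truth` (per-cell true total/endo/exo CPM and per-group
#'   true means), `seed`.
#' @export
simulate_expression_table <- function(groups, seed = 1L,
                                      control_mean_cpm = 300,
                                      dispersion = 0.2,
                                      gene = "Tmc1",
                                      n_filler_genes = 4000L,
                                      n_mito_genes = 13L,
                                      mito_fraction = 0.03,
                                      depth_meanlog = log(5e5),
                                      depth_sdlog = 0.3) {
  need <- c("group", "n_cells", "fold_change", "exo_fraction")
  stopifnot(is.data.frame(groups), all(need %in% names(groups)),
            all(groups$n_cells >= 1), all(groups$fold_change > 0),
            all(groups$exo_fraction >= 0 & groups$exo_fraction <= 1))
  set.seed(seed)
  cells <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    mu <- control_mean_cpm * g$fold_change
    total_cpm <- nb_draw(g$n_cells, mu, dispersion)
    cells[[gi]] <- data.frame(
      cell_id = sprintf("%s_c%03d", g$group, seq_len(g$n_cells)),
      group = g$group,
      true_total_cpm = total_cpm,
      true_endo_cpm = total_cpm * (1 - g$exo_fraction),
      true_exo_cpm = total_cpm * g$exo_fraction,
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  n <- nrow(cells)
  depth <- stats::rlnorm(n, depth_meanlog, depth_sdlog)
  tmc1_raw <- as.integer(round(cells$true_total_cpm * depth / 1e6))

  filler_ids <- sprintf("gene%04d", seq_len(n_filler_genes))
  mito_ids <- sprintf("mt-g%02d", seq_len(n_mito_genes))
  filler_mu <- depth * (1 - mito_fraction) / n_filler_genes
  filler <- matrix(stats::rpois(n_filler_genes * n,
                                rep(filler_mu, each = n_filler_genes)),
                   nrow = n_filler_genes, ncol = n,
                   dimnames = list(filler_ids, cells$cell_id))
  mito_mu <- depth * mito_fraction / n_mito_genes
  mito <- matrix(stats::rpois(n_mito_genes * n,
                              rep(mito_mu, each = n_mito_genes)),
                 nrow = n_mito_genes, ncol = n,
                 dimnames = list(mito_ids, cells$cell_id))
  counts <- rbind(matrix(tmc1_raw, nrow = 1,
                         dimnames = list(gene, cells$cell_id)),
                  filler, mito)
  total_mapped <- colSums(counts)
  cells$total_mapped_reads <- as.numeric(total_mapped)
  cells$tmc1_raw <- tmc1_raw
  cells$tmc1_cpm <- normalize_expression(tmc1_raw, cells$total_mapped_reads)

  group_truth <- data.frame(
    group = groups$group,
    true_mean_cpm = control_mean_cpm * groups$fold_change,
    true_fold_change = groups$fold_change,
    true_exo_fraction = groups$exo_fraction,
    stringsAsFactors = FALSE)
  list(counts = counts,
       cells = cells[, c("cell_id", "group", "total_mapped_reads",
                         "tmc1_raw", "tmc1_cpm")],
       truth = list(per_cell = cells[, c("cell_id", "group", "true_total_cpm",
                                         "true_endo_cpm", "true_exo_cpm")],
                    per_group = group_truth),
       seed = seed)
}

#' Simulate per-cell endogenous and exogenous expression components
#'
#' Draws the two allele components independently from negative binomials
#' with the given mean CPMs (a mean of 0 yields exact zeros). Used to build
#' treated/control groups with a known residual endogenous expression.
#'
#' @param n_cells Number of cells.
#' @param endo_mean_cpm,exo_mean_cpm Component means in CPM (>= 0).
#' @param dispersion Negative-binomial dispersion.
#' @param seed Integer seed.
#' @return data.frame: `cell_id`, `endo_cpm`, `exo_cpm`, `total_cpm`.
#' @export
simulate_allele_expression <- function(n_cells, endo_mean_cpm, exo_mean_cpm,
                                       dispersion = 0.2, seed = 1L) {
  stopifnot(n_cells >= 1, endo_mean_cpm >= 0, exo_mean_cpm >= 0)
  set.seed(seed)
  endo <- if (endo_mean_cpm == 0) rep(0, n_cells) else
    nb_draw(n_cells, endo_mean_cpm, dispersion)
  exo <- if (exo_mean_cpm == 0) rep(0, n_cells) else
    nb_draw(n_cells, exo_mean_cpm, dispersion)
  data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)),
             endo_cpm = endo, exo_cpm = exo, total_cpm = endo + exo,
             stringsAsFactors = FALSE)
}

#' Simulate a qPCR test/control measurement pair
#'
#' The control sample has fixed target and reference Cts; the test sample's
#' target Ct is shifted by `-log2(true_residual_expression)` cycles (so its
#' relative expression is the residual) plus Gaussian per-replicate noise.
#'
#' @param true_residual_expression True residual expression of the test
#'   sample relative to control, in (0, 1].
#' @param ct_noise_sd Per-replicate Gaussian noise SD, in cycles.
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per sample (default 3).
#' @param control_target_ct,reference_ct Baseline cycle values.
#' @return List with elements `test` and `control`, each usable with
#'   [ddct_knockdown()], plus `true_residual_expression` and
#'   `true_knockdown_pct`.
#' @export
simulate_qpcr <- function(true_residual_expression, ct_noise_sd = 0,
                          seed = 1L, n_replicates = 3L,
                          control_target_ct = 20, reference_ct = 15) {
  if (true_residual_expression <= 0 || true_residual_expression > 1) {
    stop("true_residual_expression must be in (0, 1]", call. = FALSE)
  }
  stopifnot(ct_noise_sd >= 0)
  set.seed(seed)
  shift <- -log2(true_residual_expression)
  test_ct <- control_target_ct + shift +
    stats::rnorm(n_replicates, 0, ct_noise_sd)
  list(test = list(sample = "test",
                   target_ct = test_ct,
                   reference_ct = rep(reference_ct, n_replicates)),
       control = list(sample = "control",
                      target_ct = rep(control_target_ct, n_replicates),
                      reference_ct = rep(reference_ct, n_replicates)),
       true_residual_expression = true_residual_expression,
       true_knockdown_pct = 100 * (1 - true_residual_expression))
}

#' Built-in presets mirroring the four study groups
#'
#' Loads the shipped group presets (site pair, per-group exogenous
#' fractions, expression fold changes, cell numbers, and the implied
#' knockdown efficiency) from the package's extdata.
#'
#' @return Named list: `signature` (a [site_signature()]), `groups`
#'   (data.frame), `knockdown_efficiency`, `control_mean_cpm`.
#' @export
study_presets <- function() {
  path <- system.file("extdata", "study_groups.json", package = "rnairescue",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(signature = site_signature(raw$signature$endo, raw$signature$exo),
       groups = as.data.frame(raw$groups, stringsAsFactors = FALSE),
       knockdown_efficiency = raw$knockdown_efficiency,
       control_mean_cpm = raw$control_mean_cpm)
}
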
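# Orchestration: design -> simulate -> quantify, with file-based inputs and
# machine-readable JSON reports. These functions are the programmatic
# equivalents of the shell entry point in inst/scripts/rnairescue-cli.R.

provenance <- function(seed = NULL, config = list()) {
  list(package = "rnairescue",
       version = as.character(utils::packageVersion("rnairescue")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       config = config)
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a cell-by-gene count table
#'
#' Delimited text with cells in rows and a header row of gene ids (first
#' column = cell ids), or MatrixMarket triplet format with companion
#' row/column id files. Returned in genes-by-cells orientation.
#'
#' @param path Path to the table (`.mtx` triggers MatrixMarket mode).
#' @param sep Field separator for delimited text.
#' @param genes_file,cells_file For MTX input: one id per line for rows
#'   (genes) and columns (cells) of the matrix.
#' @return Numeric matrix, genes in rows, cells in columns.
#' @export
read_count_table <- function(path, sep = "\t", genes_file = NULL,
                             cells_file = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("the Matrix package is required for MTX input", call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_file)
    colnames(m) <- readLines(cells_file)
    return(m)
  }
  x <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  t(as.matrix(x))  # file is cells x genes; internal orientation genes x cells
}

#' Read a cell manifest
#'
#' Delimited text with columns `cell_id`, `group`, `fastq` (one or more
#' paths separated by `;`, resolved relative to the manifest's directory
#' when not absolute).
#'
#' @param path Manifest path.
#' @return data.frame with columns `cell_id`, `group`, `fastq`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "group", "fastq") %in% names(m)))
  if (!nrow(m)) stop("empty manifest", call. = FALSE)
  base <- dirname(path)
  m$fastq <- vapply(m$fastq, function(f) {
    parts <- strsplit(f, ";", fixed = TRUE)[[1]]
    paste(ifelse(grepl("^/", parts), parts, file.path(base, parts)),
          collapse = ";")
  }, character(1L))
  m
}

#' Produce a knockdown-resistance design report
#'
#' Two modes: given `site_a`/`site_b`, verifies a provided engineered pair
#' (frame inference, synonymy proof, substitution census); given `cds` plus
#' a site interval, recodes the site to its synonymous maximum-divergence
#' form. Coordinates are 0-based half-open.
#'
#' @param site_a,site_b Original and engineered site sequences (pair mode).
#' @param cds Coding sequence, as a string or a FASTA path (design mode).
#' @param site_start,site_length,frame_offset,orientation Site interval and
#'   frame for design mode (see [coding_context()]).
#' @param min_total_mismatches,min_seed_mismatches,seed_interval Resistance
#'   thresholds passed to [verify_resistance()].
#' @param out Optional path for the JSON design report.
#' @return The design report, invisibly when `out` is given.
#' @export
run_design <- function(site_a = NULL, site_b = NULL, cds = NULL,
                       site_start = 0L, site_length = 21L,
                       frame_offset = 0L, orientation = "sense",
                       min_total_mismatches = 6L, min_seed_mismatches = 1L,
                       seed_interval = NULL, out = NULL) {
  if (!is.null(site_a) && !is.null(site_b)) {
    rec <- recoded_site_pair(site_a, site_b)
    fr <- rec$frame
  } else if (!is.null(cds)) {
    if (length(cds) == 1L && file.exists(cds)) {
      seqs <- Biostrings::readDNAStringSet(cds)
      if (!length(seqs)) stop("no sequence in FASTA", call. = FALSE)
      cds <- as.character(seqs[[1]])
    }
    rec <- recode_site(coding_context(cds, site_start, site_length,
                                      frame_offset, orientation))
    fr <- infer_matching_frame(rec$original, rec$engineered)
  } else {
    stop("provide either site_a/site_b or a cds", call. = FALSE)
  }
  res <- verify_resistance(rec, min_total_mismatches, min_seed_mismatches,
                           seed_interval)
  report <- list(
    original = rec$original,
    engineered = rec$engineered,
    n_substitutions = rec$n_substitutions,
    substitution_positions = rec$substitution_positions,
    synonymy_verified = rec$synonymy_verified,
    frame = list(orientation = fr$orientation,
                 frame_offset = fr$frame_offset,
                 synonymous = fr$synonymous,
                 peptide_a = fr$peptide_a,
                 peptide_b = fr$peptide_b,
                 codon_position_of_diffs = fr$codon_position_of_diffs),
    resistance = res,
    provenance = provenance())
  if (!is.null(out)) {
    write_report(report, out)
    return(invisible(report))
  }
  report
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes, for every cell of every preset group: gzipped FASTQ of
#' site-spanning reads (allele mixture = the group's true exogenous
#' fraction), a cell-by-gene count table, a manifest, and a truth ledger
#' JSON. Deterministic under `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param preset Presets as returned by [study_presets()].
#' @param reads_per_cell Site-spanning reads per cell.
#' @param read_length Read length.
#' @param error_rate Per-base substitution error rate.
#' @param dispersion Negative-binomial dispersion of expression.
#' @param n_filler_genes Filler genes in the count table.
#' @return Paths of the written files (list), invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, preset = study_presets(),
                         reads_per_cell = 200L, read_length = 100L,
                         error_rate = 0.005, dispersion = 0.2,
                         n_filler_genes = 4000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expr <- simulate_expression_table(preset$groups, seed = seed,
                                    control_mean_cpm = preset$control_mean_cpm,
                                    dispersion = dispersion,
                                    n_filler_genes = n_filler_genes)
  fastq_dir <- file.path(out_dir, "fastq")
  dir.create(fastq_dir, showWarnings = FALSE)
  manifest <- list()
  read_truth <- list()
  for (gi in seq_len(nrow(preset$groups))) {
    g <- preset$groups[gi, ]
    sim <- simulate_site_reads(g$n_cells, reads_per_cell, g$exo_fraction,
                               preset$signature, read_length = read_length,
                               error_rate = error_rate,
                               seed = seed * 100L + gi,
                               cell_prefix = paste0(g$group, "_c"))
    for (cid in names(sim$reads)) {
      fq <- file.path(fastq_dir, paste0(cid, ".fastq.gz"))
      write_fastq(sim$reads[[cid]], fq)
    }
    manifest[[gi]] <- data.frame(
      cell_id = names(sim$reads), group = g$group,
      fastq = file.path("fastq", paste0(names(sim$reads), ".fastq.gz")),
      stringsAsFactors = FALSE)
    read_truth[[gi]] <- sim$truth_by_cell
  }
  manifest <- do.call(rbind, manifest)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts_path <- file.path(out_dir, "counts.tsv")
  # external format: cells in rows, genes in the header
  utils::write.table(t(expr$counts), counts_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  truth <- list(per_cell_expression = expr$truth$per_cell,
                per_group = expr$truth$per_group,
                site_reads_by_cell = do.call(rbind, read_truth),
                knockdown_efficiency = preset$knockdown_efficiency,
                provenance = provenance(seed = seed,
                                        config = list(
                                          reads_per_cell = reads_per_cell,
                                          read_length = read_length,
                                          error_rate = error_rate,
                                          dispersion = dispersion)))
  truth_path <- file.path(out_dir, "truth.json")
  write_report(truth, truth_path)
  invisible(list(manifest = manifest_path, counts = counts_path,
                 truth = truth_path, fastq_dir = fastq_dir))
}

#' Quantify allele-resolved expression across groups
#'
#' End-to-end quantification: per-cell exact-match allele counting from
#' FASTQ, optional QC filtering of the count table, depth normalization of
#' the gene of interest, group-pooled allele fractions applied per cell,
#' knockdown efficiency against the control group, and a Kruskal-Wallis /
#' Dunn / Benjamini-Hochberg comparison of per-cell expression across
#' groups. Cells present in the manifest but absent from the count table are
#' reported and excluded.
#'
#' @param manifest Manifest path or data.frame (see [read_manifest()]).
#' @param counts Count table path or genes-by-cells matrix.
#' @param signature A [site_signature()].
#' @param control_group Name of the fully endogenous control group (or
#'   `NULL` to skip knockdown estimation).
#' @param gene Gene id of the gene of interest.
#' @param thresholds A [qc_thresholds()], or `NULL` to skip QC filtering.
#' @param out_dir Optional output directory for `per_cell.tsv` and
#'   `summary.json`.
#' @return List: `per_cell`, `groups`, `pooled_knockdown_efficiency`,
#'   `expression_test` (Kruskal-Wallis/Dunn), `qc_report`,
#'   `missing_cells`.
#' @export
run_quantify <- function(manifest, counts, signature,
                         control_group = NULL, gene = "Tmc1",
                         thresholds = NULL, out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!nrow(manifest)) stop("empty manifest", call. = FALSE)
  if (is.character(counts)) counts <- read_count_table(counts)
  qc_report <- NULL
  if (!is.null(thresholds)) {
    f <- filter_cells(counts, thresholds)
    counts <- f$counts
    qc_report <- f$report
  }
  if (!gene %in% rownames(counts)) {
    stop("gene '", gene, "' absent from the count table", call. = FALSE)
  }
  missing <- setdiff(manifest$cell_id, colnames(counts))
  manifest <- manifest[manifest$cell_id %in% colnames(counts), , drop = FALSE]
  if (!nrow(manifest)) {
    stop("no manifest cell is present in the count table", call. = FALSE)
  }
  depth <- colSums(counts)[manifest$cell_id]
  raw <- counts[gene, manifest$cell_id]
  per_cell <- data.frame(cell_id = manifest$cell_id,
                         group = manifest$group,
                         total_mapped_reads = as.numeric(depth),
                         tmc1_raw = as.numeric(raw),
                         tmc1_expression = normalize_expression(
                           as.numeric(raw), as.numeric(depth)),
                         n_endo = NA_integer_, n_exo = NA_integer_,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per_cell))) {
    paths <- strsplit(manifest$fastq[i], ";", fixed = TRUE)[[1]]
    ac <- count_allele_reads(read_fastq(paths), signature)
    per_cell$n_endo[i] <- ac$n_endo
    per_cell$n_exo[i] <- ac$n_exo
  }
  est <- group_allele_estimates(per_cell, control_group = control_group)
  groups <- split(est$per_cell$tmc1_expression, est$per_cell$group)
  test <- if (length(groups) >= 2) kruskal_dunn(groups) else NULL
  result <- list(per_cell = est$per_cell,
                 groups = est$groups,
                 pooled_knockdown_efficiency = est$pooled_knockdown_efficiency,
                 expression_test = test,
                 qc_report = qc_report,
                 missing_cells = missing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(est$per_cell, file.path(out_dir, "per_cell.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(
      groups = est$groups,
      pooled_knockdown_efficiency = est$pooled_knockdown_efficiency,
      expression_test = if (is.null(test)) NULL else
        list(method = test$method, statistic = test$statistic,
             p_value = test$p_value, pairwise = test$pairwise),
      missing_cells = missing,
      provenance = provenance())
    write_report(summary, file.path(out_dir, "summary.json"))
  }
  result
}
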
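# Allele-resolved quantification of endogenous vs. exogenous transcripts.
#
# Transcripts from the animal's own gene and from the delivered replacement
# construct are identical except at the recoded RNAi-binding site, so a read
# is assigned to an allele iff it contains the full-length site sequence (or
# its reverse complement) as an exact substring. Fragments are deduplicated
# by read id, pooled per experimental group into allele fractions, and the
# fractions are applied to depth-normalized per-cell expression.

#' Define the endogenous/exogenous site pair used for allele assignment
#'
#' @param endo_site,exo_site Equal-length site sequences that differ in at
#'   least one position.
#' @return A `site_signature` list carrying both sites and their reverse
#'   complements.
#' @examples
#' site_signature("GACGATCATGTACAGGACCGG", "CACTATCATATATAGTACTGG")
#' @export
site_signature <- function(endo_site, exo_site) {
  endo_site <- as_dna(endo_site, "endo_site")
  exo_site <- as_dna(exo_site, "exo_site")
  if (nchar(endo_site) != nchar(exo_site)) {
    stop("endogenous and exogenous sites must have equal length",
         call. = FALSE)
  }
  if (hamming(endo_site, exo_site) < 1L) {
    stop("sites must differ in at least one position", call. = FALSE)
  }
  structure(list(endo = endo_site,
                 exo = exo_site,
                 endo_rc = reverse_complement(endo_site),
                 exo_rc = reverse_complement(exo_site)),
            class = "site_signature")
}

#' Read a FASTQ file into a named vector of read sequences
#'
#' Names are read ids truncated at the first whitespace; a trailing `/1` or
#' `/2` mate suffix is stripped so that mates of a fragment share an id.
#' Gzipped input is handled transparently.
#'
#' @param paths One or more FASTQ paths (all reads are concatenated).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(paths) {
  reads <- lapply(paths, function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    ids <- sub("\\s.*$", "", names(x))
    ids <- sub("/[12]$", "", ids)
    stats::setNames(as.character(x), ids)
  })
  do.call(c, reads)
}

#' Write reads to a FASTQ file
#'
#' Emits constant placeholder base qualities (`I`, Phred 40); the matching
#' stage is quality-blind. Paths ending in `.gz` are gzip-compressed.
#'
#' @param reads Named character vector (names become read ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  rec <- rbind(paste0("@", ids), reads, "+",
               vapply(nchar(reads), function(n) strrep("I", n), character(1L)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rec), con)
  invisible(path)
}

#' Count reads matching the endogenous or exogenous site exactly
#'
#' A fragment is assigned to an allele iff any of its reads contains the
#' full-length site, or the reverse complement of the site, as an exact
#' substring. Mates sharing a read id are collapsed to one fragment. A
#' fragment matching both alleles is counted for neither (with a warning);
#' reads shorter than the site simply cannot match. Reads containing `N`
#' inside the would-be match window never match (exactness is literal).
#'
#' @param reads Named character vector of read sequences (names = read ids;
#'   unnamed reads are treated as distinct fragments), a data.frame with
#'   columns `read_id` and `seq`, or a character vector of FASTQ path(s).
#' @param signature A [site_signature()].
#' @return List: `n_endo`, `n_exo`, `n_site_reads` (= their sum),
#'   `n_ambiguous`, `n_fragments`.
#' @export
count_allele_reads <- function(reads, signature) {
  stopifnot(inherits(signature, "site_signature"))
  if (is.data.frame(reads)) {
    reads <- stats::setNames(as.character(reads$seq), as.character(reads$read_id))
  } else if (is.character(reads) && length(reads) &&
             all(file.exists(reads)) && is.null(names(reads))) {
    reads <- read_fastq(reads)
  }
  if (!length(reads)) {
    return(list(n_endo = 0L, n_exo = 0L, n_site_reads = 0L,
                n_ambiguous = 0L, n_fragments = 0L))
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  reads <- toupper(reads)
  endo_hit <- grepl(signature$endo, reads, fixed = TRUE) |
    grepl(signature$endo_rc, reads, fixed = TRUE)
  exo_hit <- grepl(signature$exo, reads, fixed = TRUE) |
    grepl(signature$exo_rc, reads, fixed = TRUE)
  # collapse mates: a fragment matches an allele if either mate does
  frag_endo <- tapply(endo_hit, ids, any)
  frag_exo <- tapply(exo_hit, ids, any)
  both <- frag_endo & frag_exo
  if (any(both)) {
    warning(sum(both), " fragment(s) matched both alleles; counted as neither")
  }
  list(n_endo = as.integer(sum(frag_endo & !both)),
       n_exo = as.integer(sum(frag_exo & !both)),
       n_site_reads = as.integer(sum(frag_endo & !both) + sum(frag_exo & !both)),
       n_ambiguous = as.integer(sum(both)),
       n_fragments = length(frag_endo))
}

#' Pool allele counts across cells into group-level fractions
#'
#' Cells with no site-spanning reads are excluded; percentages are computed
#' from the summed counts of the remaining cells (pooled, not a mean of
#' per-cell percentages) and sum to 100.
#'
#' @param counts data.frame with columns `n_endo` and `n_exo`, one row per
#'   cell (extra columns ignored).
#' @return List: `pct_endo`, `pct_exo`, `n_cells_used`.
#' @export
pooled_allele_fraction <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("n_endo", "n_exo") %in% names(counts)))
  if (nrow(counts) < 1L) stop("at least one cell required", call. = FALSE)
  if (any(counts$n_endo < 0) || any(counts$n_exo < 0)) {
    stop("allele counts must be nonnegative", call. = FALSE)
  }
  keep <- (counts$n_endo + counts$n_exo) > 0
  if (!any(keep)) {
    stop("no cell has site-spanning reads; allele fractions undefined",
         call. = FALSE)
  }
  tot_endo <- sum(counts$n_endo[keep])
  tot <- tot_endo + sum(counts$n_exo[keep])
  list(pct_endo = 100 * tot_endo / tot,
       pct_exo = 100 * (tot - tot_endo) / tot,
       n_cells_used = sum(keep))
}

#' Depth-normalize a per-cell gene count (counts per million)
#'
#' @param raw_count Raw read count for the gene.
#' @param total_mapped_reads Total mapped reads of the cell (> 0).
#' @return CPM value(s).
#' @examples
#' normalize_expression(5, 5e5) # 10
#' @export
normalize_expression <- function(raw_count, total_mapped_reads) {
  if (any(total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be positive", call. = FALSE)
  }
  if (any(raw_count < 0)) stop("raw_count must be nonnegative", call. = FALSE)
  raw_count / total_mapped_reads * 1e6
}

#' Split per-cell expression into allele components by group fractions
#'
#' Multiplies a cell's expression by the group-level allele percentages. The
#' two components sum to the input expression exactly (the exogenous share is
#' computed as the remainder).
#'
#' @param tmc1_expression Per-cell depth-normalized expression (>= 0).
#' @param pct_endo,pct_exo Group allele percentages summing to 100.
#' @return List: `endo_expression`, `exo_expression` (same length as input).
#' @export
allocate_allele_expression <- function(tmc1_expression, pct_endo, pct_exo) {
  if (abs(pct_endo + pct_exo - 100) > 1e-8) {
    stop("allele percentages must sum to 100", call. = FALSE)
  }
  if (any(tmc1_expression < 0)) {
    stop("expression must be nonnegative", call. = FALSE)
  }
  endo <- tmc1_expression * pct_endo / 100
  list(endo_expression = endo, exo_expression = tmc1_expression - endo)
}

#' Estimate RNAi knockdown efficiency of the endogenous allele
#'
#' Computes `100 * (1 - mean(treated endogenous expression) / mean(control
#' total expression))`, treating the (untreated) control group as fully
#' endogenous. A negative value — treated endogenous expression exceeding the
#' control — is returned but flagged via the `"flagged"` attribute.
#'
#' @param treated_endo_expression Per-cell endogenous expression of the
#'   treated group.
#' @param control_expression Per-cell total expression of the control group.
#' @return Knockdown percentage.
#' @export
knockdown_efficiency <- function(treated_endo_expression, control_expression) {
  if (!length(treated_endo_expression) || !length(control_expression)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mc <- mean(control_expression)
  if (mc == 0) stop("control mean expression is zero", call. = FALSE)
  kd <- 100 * (1 - mean(treated_endo_expression) / mc)
  if (kd < 0) attr(kd, "flagged") <- "treated endogenous exceeds control"
  kd
}

#' Group-level allele estimates from per-cell records
#'
#' Combines per-cell allele counts and expression into the group summary:
#' pooled allele fractions, per-cell allele expression (fractions applied to
#' every cell of the group), and — when a control group is named — knockdown
#' efficiency of each non-control group and pooled across them.
#'
#' @param cells data.frame with columns `cell_id`, `group`, `n_endo`,
#'   `n_exo`, `tmc1_expression` (depth-normalized).
#' @param control_group Name of the fully endogenous control group, or
#'   `NULL` to skip knockdown estimation.
#' @return List: `per_cell` (input augmented with `endo_expression`,
#'   `exo_expression`) and `groups` (data.frame of `group`, `pct_endo`,
#'   `pct_exo`, `n_cells_used`, `n_cells`, `mean_expression`,
#'   `knockdown_efficiency`), plus `pooled_knockdown_efficiency`.
#' @export
group_allele_estimates <- function(cells, control_group = NULL) {
  need <- c("cell_id", "group", "n_endo", "n_exo", "tmc1_expression")
  stopifnot(is.data.frame(cells), all(need %in% names(cells)))
  cells$endo_expression <- NA_real_
  cells$exo_expression <- NA_real_
  groups <- unique(as.character(cells$group))
  summ <- data.frame(group = groups, pct_endo = NA_real_, pct_exo = NA_real_,
                     n_cells_used = NA_integer_, n_cells = NA_integer_,
                     mean_expression = NA_real_,
                     knockdown_efficiency = NA_real_,
                     stringsAsFactors = FALSE)
  for (g in groups) {
    i <- cells$group == g
    summ$n_cells[summ$group == g] <- sum(i)
    summ$mean_expression[summ$group == g] <- mean(cells$tmc1_expression[i])
    fr <- tryCatch(pooled_allele_fraction(cells[i, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(fr)) next
    alloc <- allocate_allele_expression(cells$tmc1_expression[i],
                                        fr$pct_endo, fr$pct_exo)
    cells$endo_expression[i] <- alloc$endo_expression
    cells$exo_expression[i] <- alloc$exo_expression
    summ[summ$group == g, c("pct_endo", "pct_exo", "n_cells_used")] <-
      list(fr$pct_endo, fr$pct_exo, fr$n_cells_used)
  }
  pooled_kd <- NA_real_
  if (!is.null(control_group)) {
    if (!control_group %in% groups) {
      stop("control group '", control_group, "' not present", call. = FALSE)
    }
    ctrl <- cells$tmc1_expression[cells$group == control_group]
    for (g in setdiff(groups, control_group)) {
      te <- cells$endo_expression[cells$group == g]
      if (all(is.na(te))) next
      summ$knockdown_efficiency[summ$group == g] <-
        as.numeric(knockdown_efficiency(te[!is.na(te)], ctrl))
    }
    treated <- cells$group != control_group & !is.na(cells$endo_expression)
    if (any(treated)) {
      pooled_kd <- as.numeric(
        knockdown_efficiency(cells$endo_expression[treated], ctrl))
    }
  }
  list(per_cell = cells, groups = summ,
       pooled_knockdown_efficiency = pooled_kd)
}
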
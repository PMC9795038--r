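# Cell-quality filters, delta-delta-Ct qPCR knockdown, and the statistical
# battery used to compare expression between experimental groups.

#' Quality-control thresholds for single-cell count tables
#'
#' Defaults follow the full-length single-cell protocol this package targets:
#' a cell must express at least 3000 qualifying genes with mitochondrial
#' reads at most 7% of its total; a gene qualifies when present in at least
#' 3 cells.
#'
#' @param min_genes_per_cell Minimum qualifying genes expressed per cell.
#' @param max_mito_fraction Maximum mitochondrial read proportion, in (0,1].
#' @param min_cells_per_gene Minimum cells a gene must be detected in.
#' @param mito_pattern Regular expression identifying mitochondrial gene ids
#'   (matched case-insensitively against rownames).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 3000L,
                          max_mito_fraction = 0.07,
                          min_cells_per_gene = 3L,
                          mito_pattern = "^mt-") {
  stopifnot(min_genes_per_cell >= 1, min_cells_per_gene >= 1,
            max_mito_fraction > 0, max_mito_fraction <= 1)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 mito_pattern = mito_pattern),
            class = "qc_thresholds")
}

#' Filter a count table by gene prevalence and cell quality
#'
#' The gene filter is applied first: genes detected (count > 0) in fewer than
#' `min_cells_per_gene` cells are dropped, and only the surviving genes count
#' toward each cell's genes-expressed tally. Cells are then dropped when they
#' express fewer than `min_genes_per_cell` surviving genes or exceed
#' `max_mito_fraction` mitochondrial reads; the mitochondrial fraction is a
#' read-level quantity and is computed on the unfiltered table.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene ids), cells
#'   in columns (colnames = cell ids); nonnegative counts.
#' @param thresholds A [qc_thresholds()].
#' @return List: `counts` (filtered matrix), `report` (list with
#'   `dropped_genes`, `dropped_cells` data.frame of id/reason, and per-cell
#'   metrics `genes_expressed`, `mito_fraction`).
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  counts <- as.matrix(counts)
  if (!nrow(counts) || !ncol(counts)) stop("empty count table", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table needs gene rownames and cell colnames", call. = FALSE)
  }
  mito <- grepl(thresholds$mito_pattern, rownames(counts), ignore.case = TRUE)
  total_reads <- colSums(counts)
  mito_fraction <- ifelse(total_reads > 0,
                          colSums(counts[mito, , drop = FALSE]) / total_reads,
                          0)
  gene_keep <- rowSums(counts > 0) >= thresholds$min_cells_per_gene
  kept <- counts[gene_keep, , drop = FALSE]
  genes_expressed <- colSums(kept > 0)
  low_genes <- genes_expressed < thresholds$min_genes_per_cell
  high_mito <- mito_fraction > thresholds$max_mito_fraction
  cell_keep <- !low_genes & !high_mito

  reason <- character(0)
  dropped <- colnames(counts)[!cell_keep]
  if (length(dropped)) {
    reason <- vapply(which(!cell_keep), function(i) {
      paste(c(if (low_genes[i]) "too_few_genes",
              if (high_mito[i]) "high_mito_fraction"), collapse = ";")
    }, character(1L))
  }
  list(counts = kept[, cell_keep, drop = FALSE],
       report = list(
         dropped_genes = rownames(counts)[!gene_keep],
         dropped_cells = data.frame(cell_id = dropped, reason = reason,
                                    stringsAsFactors = FALSE),
         genes_expressed = genes_expressed,
         mito_fraction = mito_fraction,
         thresholds = thresholds))
}

#' Relative expression and knockdown by the delta-delta-Ct method
#'
#' Ct triplicates are aggregated by arithmetic mean; per sample
#' `dCt = mean(target Ct) - mean(reference Ct)`, then
#' `ddCt = dCt_test - dCt_control`, relative expression `2^(-ddCt)`, and
#' knockdown `100 * (1 - 2^(-ddCt))`. Per-replicate spread (sd of the target
#' Cts) is reported alongside.
#'
#' @param test,control Lists with numeric elements `target_ct` and
#'   `reference_ct` (cycle values, each a non-empty positive vector),
#'   optionally a `sample` label.
#' @return List: `d_ct_test`, `d_ct_control`, `dd_ct`,
#'   `relative_expression`, `knockdown_pct`, `target_ct_sd_test`,
#'   `target_ct_sd_control`.
#' @examples
#' ddct_knockdown(
#'   test = list(target_ct = c(22, 22, 22), reference_ct = c(15, 15, 15)),
#'   control = list(target_ct = c(20, 20, 20), reference_ct = c(15, 15, 15))
#' )$knockdown_pct # 75
#' @export
ddct_knockdown <- function(test, control) {
  check <- function(m, what) {
    if (!is.list(m) || !all(c("target_ct", "reference_ct") %in% names(m))) {
      stop(what, " must list target_ct and reference_ct", call. = FALSE)
    }
    if (!length(m$target_ct) || !length(m$reference_ct) ||
        any(m$target_ct <= 0) || any(m$reference_ct <= 0)) {
      stop(what, " Ct values must be non-empty and positive", call. = FALSE)
    }
  }
  check(test, "test")
  check(control, "control")
  d_test <- mean(test$target_ct) - mean(test$reference_ct)
  d_ctrl <- mean(control$target_ct) - mean(control$reference_ct)
  dd <- d_test - d_ctrl
  rel <- 2^(-dd)
  list(d_ct_test = d_test, d_ct_control = d_ctrl, dd_ct = dd,
       relative_expression = rel,
       knockdown_pct = 100 * (1 - rel),
       target_ct_sd_test = stats::sd(test$target_ct),
       target_ct_sd_control = stats::sd(control$target_ct))
}

#' Read a qPCR plate table into measurement objects
#'
#' Expects delimited text with columns `sample`, `role` (`target` or
#' `reference`) and `ct`, one row per replicate well.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default tab).
#' @return Named list of measurement lists usable with [ddct_knockdown()].
#' @export
read_qpcr_table <- function(path, sep = "\t") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "role", "ct") %in% names(x)))
  lapply(split(x, x$sample), function(s) {
    list(sample = s$sample[1],
         target_ct = s$ct[s$role == "target"],
         reference_ct = s$ct[s$role == "reference"])
  })
}

stat_result <- function(method, statistic, p_value, pairwise = NULL,
                        route = NULL, alpha = NULL, details = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value), pairwise = pairwise,
                   route = route, alpha = alpha), details),
            class = "stat_result")
}

welch_df <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
}

#' Compare two groups with Welch's t test
#'
#' Two-sided Welch t test with Welch-Satterthwaite degrees of freedom. When
#' both groups are constant the test is degenerate: equal means give
#' statistic 0 and p = 1, unequal means give p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A `stat_result` with `statistic`, `p_value`, `df`, `estimate`
#'   (difference in means).
#' @export
compare_two <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- mean(a) == mean(b)
    return(stat_result("Welch two-sample t test",
                       statistic = if (same) 0 else Inf,
                       p_value = if (same) 1 else 0,
                       details = list(df = NA_real_,
                                      estimate = mean(a) - mean(b))))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  stat_result("Welch two-sample t test", tt$statistic, tt$p.value,
              details = list(df = unname(tt$parameter),
                             estimate = unname(diff(rev(tt$estimate)))))
}

# pairwise Welch t with Sidak family adjustment: a conservative stand-in for
# Dunnett's T3 studentized-maximum-modulus reference distribution
dunnett_t3 <- function(groups) {
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(comparison = character(m), statistic = numeric(m),
                    df = numeric(m), p_raw = numeric(m), p_adj = numeric(m),
                    adjustment = "sidak", stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- groups[[i1]]; b <- groups[[i2]]
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    t <- if (se == 0) ifelse(mean(a) == mean(b), 0, Inf) else
      (mean(a) - mean(b)) / se
    df <- if (se == 0) NA_real_ else welch_df(a, b)
    p <- if (is.na(df)) ifelse(t == 0, 1, 0) else 2 * stats::pt(-abs(t), df)
    out$comparison[j] <- paste(names(groups)[i1], names(groups)[i2], sep = "-")
    out$statistic[j] <- t
    out$df[j] <- df
    out$p_raw[j] <- p
    out$p_adj[j] <- 1 - (1 - p)^m
  }
  out
}

#' Compare three or more groups, routing on variance homogeneity
#'
#' Runs Bartlett's test at `alpha`; with homogeneous variances, one-way ANOVA
#' with Tukey's HSD post hoc; with significantly different SDs (or any
#' constant group, for which Bartlett is undefined), Welch's ANOVA with a
#' Dunnett-T3-style post hoc (pairwise Welch t, Sidak-adjusted). The route
#' taken is recorded in the result.
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each n >= 2).
#' @param alpha Significance level of the Bartlett gate (default 0.05).
#' @return A `stat_result`; `route` is `"anova_tukey"` or
#'   `"welch_dunnett_t3"`, `pairwise` the post hoc table.
#' @export
compare_many <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 3,
            all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups))
  constant <- vapply(groups, function(g) stats::var(g) == 0, logical(1L))
  if (any(constant)) {
    warning("constant group(s): Bartlett's test undefined; ",
            "routing to the Welch path")
    bartlett_p <- NA_real_
    welch_route <- TRUE
  } else {
    bartlett_p <- stats::bartlett.test(values, labels)$p.value
    welch_route <- bartlett_p < alpha
  }
  if (welch_route) {
    if (all(constant) && length(unique(vapply(groups, mean, 1))) == 1L) {
      # fully degenerate: identical constant groups
      return(stat_result("Welch one-way ANOVA", 0, 1,
                         pairwise = dunnett_t3(groups),
                         route = "welch_dunnett_t3", alpha = alpha,
                         details = list(bartlett_p = bartlett_p)))
    }
    ow <- stats::oneway.test(values ~ labels, var.equal = FALSE)
    stat_result("Welch one-way ANOVA", ow$statistic, ow$p.value,
                pairwise = dunnett_t3(groups),
                route = "welch_dunnett_t3", alpha = alpha,
                details = list(df = unname(ow$parameter),
                               bartlett_p = bartlett_p))
  } else {
    fit <- stats::aov(values ~ labels)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$labels
    pw <- data.frame(comparison = rownames(tk),
                     statistic = tk[, "diff"],
                     p_raw = tk[, "p adj"], p_adj = tk[, "p adj"],
                     adjustment = "tukey", row.names = NULL,
                     stringsAsFactors = FALSE)
    stat_result("one-way ANOVA", an[["F value"]][1], an[["Pr(>F)"]][1],
                pairwise = pw, route = "anova_tukey", alpha = alpha,
                details = list(df = unname(an[["Df"]]),
                               bartlett_p = bartlett_p))
  }
}

#' Kruskal-Wallis test with Dunn's post hoc and Benjamini-Hochberg adjustment
#'
#' Omnibus H is the tie-corrected Kruskal-Wallis statistic with a chi-squared
#' p-value. Dunn's z for each pair uses the tie-corrected pooled variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`; raw two-sided
#' normal p-values are adjusted by Benjamini-Hochberg across all pairs.
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @return A `stat_result` with the H `statistic`, omnibus `p_value`, and a
#'   `pairwise` Dunn table.
#' @export
kruskal_dunn <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups))
  if (length(unique(values)) == 1L) {
    pw <- dunn_table(values, labels)
    return(stat_result("Kruskal-Wallis rank sum test", 0, 1, pairwise = pw,
                       details = list(df = length(groups) - 1L)))
  }
  kw <- stats::kruskal.test(values, labels)
  stat_result("Kruskal-Wallis rank sum test", kw$statistic, kw$p.value,
              pairwise = dunn_table(values, labels),
              details = list(df = unname(kw$parameter)))
}

dunn_table <- function(values, labels) {
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  lev <- levels(labels)
  pairs <- utils::combn(length(lev), 2)
  m <- ncol(pairs)
  out <- data.frame(comparison = character(m), statistic = numeric(m),
                    p_raw = numeric(m), p_adj = numeric(m),
                    adjustment = "BH", stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(base_var * (1 / n[[i1]] + 1 / n[[i2]]))
    z <- if (se == 0) 0 else (mean_rank[[i1]] - mean_rank[[i2]]) / se
    out$comparison[j] <- paste(lev[i1], lev[i2], sep = "-")
    out$statistic[j] <- z
    out$p_raw[j] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out
}
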
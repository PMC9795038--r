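# Independent oracles the implementation is checked against. These
# deliberately use different algorithms (naive scans, exhaustive enumeration,
# closed forms) than the package code.

study_endo <- "GACGATCATGTACAGGACCGG"
study_exo <- "CACTATCATATATAGTACTGG"

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive O(n*m) substring scan over every window of every read, both
# orientations, fragment-collapsed by read id
naive_count_oracle <- function(reads, sig) {
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  pats_endo <- c(sig$endo, sig$endo_rc)
  pats_exo <- c(sig$exo, sig$exo_rc)
  scan <- function(read, pats) {
    L <- nchar(read)
    m <- nchar(pats[1])
    if (L < m) return(FALSE)
    for (s in 1:(L - m + 1)) {
      w <- substr(read, s, s + m - 1)
      if (w == pats[1] || w == pats[2]) return(TRUE)
    }
    FALSE
  }
  endo_hit <- vapply(reads, scan, logical(1), pats = pats_endo)
  exo_hit <- vapply(reads, scan, logical(1), pats = pats_exo)
  fe <- tapply(endo_hit, ids, any)
  fx <- tapply(exo_hit, ids, any)
  both <- fe & fx
  list(n_endo = sum(fe & !both), n_exo = sum(fx & !both),
       n_ambiguous = sum(both))
}

# exhaustive maximization over all synonymous codon assignments of a site
# read in sense frame 0 (site length a multiple of 3)
brute_force_max_recode <- function(site) {
  stopifnot(nchar(site) %% 3 == 0)
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(site, seq(1, nchar(site), 3), seq(3, nchar(site), 3))
  options <- lapply(codons, function(cd) {
    if (gc[[cd]] == "*") return(cd)  # stops preserved
    names(gc)[gc == gc[[cd]]]
  })
  grid <- expand.grid(options, stringsAsFactors = FALSE)
  mism <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  best <- 0L
  for (r in seq_len(nrow(grid))) {
    tot <- sum(mapply(mism, unlist(grid[r, ]), codons))
    if (tot > best) best <- tot
  }
  best
}

# closed-form Welch t
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# closed-form tie-corrected Kruskal-Wallis H and chi-squared p
kw_oracle <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(splits, function(ri) length(ri) *
                 (mean(ri) - (N + 1) / 2)^2, numeric(1)))
  ties <- table(values)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(statistic = H,
       p_value = pchisq(H, df = length(groups) - 1, lower.tail = FALSE))
}

# one-way ANOVA F from the sums-of-squares definition
anova_oracle <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  N <- length(values)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - mean(values))^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f,
       p_value = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# build a read embedding a site with given flanks
planted_read <- function(site, left = 20, right = 20) {
  paste0(random_seq(left), site, random_seq(right))
}
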
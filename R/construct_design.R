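# Design of knockdown-resistant, synonymously recoded RNAi target sites.
#
# The engineering problem: an RNAi guide silences every transcript carrying
# its binding site, so a replacement cDNA must carry a site that encodes the
# same peptide while diverging from the guide's target as much as the genetic
# code allows. The functions here infer the coding frame/strand shared by a
# site pair, recode a site to the synonymous maximum-divergence sequence, and
# verify that an engineered site clears resistance thresholds.

#' Describe a target site inside a coding sequence
#'
#' Coordinates are 0-based, half-open: the site occupies
#' `[site_start, site_start + site_length)` of `cds`. `frame_offset` is the
#' offset of the first complete codon of the reading frame, in the declared
#' `orientation` ("antisense" means the frame reads on the reverse complement
#' of `cds`).
#'
#' @param cds Coding sequence (character scalar).
#' @param site_start 0-based start of the site within `cds`.
#' @param site_length Site length in nt (default 21, the guide-site length).
#' @param frame_offset Integer in `{0,1,2}`.
#' @param orientation `"sense"` or `"antisense"`.
#' @return A `coding_context` list.
#' @export
coding_context <- function(cds, site_start, site_length = 21L,
                           frame_offset = 0L,
                           orientation = c("sense", "antisense")) {
  cds <- as_dna(cds, "cds")
  orientation <- match.arg(orientation)
  site_start <- as.integer(site_start)
  site_length <- as.integer(site_length)
  stopifnot(frame_offset %in% 0:2, site_length >= 1L)
  if (site_start < 0L || site_start + site_length > nchar(cds)) {
    stop("site interval [", site_start, ", ", site_start + site_length,
         ") lies outside the coding sequence", call. = FALSE)
  }
  structure(list(cds = cds, site_start = site_start,
                 site_length = site_length,
                 frame_offset = as.integer(frame_offset),
                 orientation = orientation),
            class = "coding_context")
}

#' Infer the reading frame and strand under which two sites are synonymous
#'
#' Exhaustively searches the 3 frame offsets x 2 orientations (applied
#' jointly to both sites) and returns the first candidate under which the two
#' sites translate to identical peptides over fully covered codons, with
#' every differing base inside a fully covered codon; if none
#' exists, the candidate maximizing the number of matching amino acids is
#' returned with `synonymous = FALSE`. Sense frames are searched before
#' antisense, offset 0 before 1 before 2.
#'
#' @param site_a,site_b Equal-length DNA sequences (length >= 3).
#' @return A `frame_result` list: `orientation`, `frame_offset`,
#'   `synonymous`, `diff_positions` (1-based, in the returned orientation),
#'   `codon_position_of_diffs` (1/2/3, `NA` for bases preceding the frame),
#'   `peptide_a`, `peptide_b`, `n_matching_aa`.
#' @examples
#' infer_matching_frame("GACGATCATGTACAGGACCGG", "CACTATCATATATAGTACTGG")
#' @export
infer_matching_frame <- function(site_a, site_b) {
  site_a <- as_dna(site_a, "site_a")
  site_b <- as_dna(site_b, "site_b")
  if (nchar(site_a) != nchar(site_b) || nchar(site_a) < 3L) {
    stop("sites must be equal-length and at least 3 nt", call. = FALSE)
  }
  best <- NULL
  for (orientation in c("sense", "antisense")) {
    a <- if (orientation == "sense") site_a else reverse_complement(site_a)
    b <- if (orientation == "sense") site_b else reverse_complement(site_b)
    for (f in 0:2) {
      if (nchar(a) - f < 3L) next
      pep_a <- translate_frame(a, f)
      pep_b <- translate_frame(b, f)
      n_match <- sum(strsplit(pep_a, "")[[1]] == strsplit(pep_b, "")[[1]])
      d <- diff_positions(a, b)
      # synonymy is only proven when every differing base is inside a fully
      # covered codon of this frame (equal peptides alone would leave edge
      # differences unaccounted for)
      covered_end <- f + 3L * nchar(pep_a)
      all_covered <- all(d > f & d <= covered_end)
      cand <- structure(list(
        orientation = orientation,
        frame_offset = f,
        synonymous = identical(pep_a, pep_b) && all_covered,
        diff_positions = d,
        codon_position_of_diffs = ifelse(d > f, ((d - f - 1L) %% 3L) + 1L,
                                         NA_integer_),
        peptide_a = pep_a,
        peptide_b = pep_b,
        n_matching_aa = n_match
      ), class = "frame_result")
      if (cand$synonymous) return(cand)
      if (is.null(best) || n_match > best$n_matching_aa) best <- cand
    }
  }
  best
}

#' Recode a target site to its synonymous maximum-divergence form
#'
#' For every codon lying entirely inside the site interval (in the declared
#' frame and orientation), the synonymous codon with the greatest number of
#' nucleotide mismatches to the original codon is chosen; ties are broken by
#' the lexicographically smallest codon, making the result deterministic.
#' Codons only partially covered by the site, and stop codons, are left
#' unchanged (stop codons are additionally flagged). Since codons are
#' recoded independently, the per-codon greedy choice attains the global
#' synonymous maximum.
#'
#' @param ctx A [coding_context()].
#' @return A `recoded_site` list: `original` and `engineered` site sequences
#'   (in the input orientation of `cds`), `n_substitutions`,
#'   `substitution_positions` (1-based within the site), `synonymy_verified`,
#'   `per_codon_mismatches`, `stop_codons_preserved`, and the frame context.
#' @examples
#' # a single leucine codon admits two synonymous mismatches (CTG -> TTA)
#' recode_site(coding_context("CTG", 0, 3))$engineered
#' @export
recode_site <- function(ctx) {
  stopifnot(inherits(ctx, "coding_context"))
  L <- nchar(ctx$cds)
  # work on the oriented strand; map the site interval across if antisense
  if (ctx$orientation == "antisense") {
    cds_o <- reverse_complement(ctx$cds)
    site_start <- L - (ctx$site_start + ctx$site_length)
  } else {
    cds_o <- ctx$cds
    site_start <- ctx$site_start
  }
  site_end <- site_start + ctx$site_length  # half-open, 0-based
  chars <- strsplit(cds_o, "", fixed = TRUE)[[1]]
  eng <- chars
  per_codon <- integer(0)
  stops <- character(0)

  codon_starts <- if (L - 3L >= ctx$frame_offset) {
    seq.int(ctx$frame_offset, L - 3L, by = 3L)
  } else integer(0)
  for (cs in codon_starts) {
    if (cs < site_start || cs + 3L > site_end) next  # not fully inside site
    codon <- paste0(chars[(cs + 1L):(cs + 3L)], collapse = "")
    if (grepl("N", codon, fixed = TRUE)) next
    if (is_stop_codon(codon)) {
      stops <- c(stops, codon)
      per_codon <- c(per_codon, 0L)
      next
    }
    syn <- sort(synonymous_codons(codon))
    mism <- vapply(syn, function(s) hamming(s, codon), integer(1L))
    pick <- syn[which.max(mism)]  # which.max -> first (lexicographic) on ties
    eng[(cs + 1L):(cs + 3L)] <- strsplit(pick, "", fixed = TRUE)[[1]]
    per_codon <- c(per_codon, max(mism))
  }

  eng_cds_o <- paste0(eng, collapse = "")
  orig_site_o <- substr(cds_o, site_start + 1L, site_end)
  eng_site_o <- substr(eng_cds_o, site_start + 1L, site_end)
  synonymy <- identical(translate_frame(cds_o, ctx$frame_offset),
                        translate_frame(eng_cds_o, ctx$frame_offset))
  # report in the input orientation of cds
  if (ctx$orientation == "antisense") {
    original <- reverse_complement(orig_site_o)
    engineered <- reverse_complement(eng_site_o)
  } else {
    original <- orig_site_o
    engineered <- eng_site_o
  }
  structure(list(
    original = original,
    engineered = engineered,
    n_substitutions = hamming(original, engineered),
    substitution_positions = diff_positions(original, engineered),
    synonymy_verified = synonymy,
    per_codon_mismatches = per_codon,
    stop_codons_preserved = stops,
    frame_offset = ctx$frame_offset,
    orientation = ctx$orientation
  ), class = "recoded_site")
}

#' Pair an original site with a provided engineered site
#'
#' The "match a provided engineered sequence" companion to [recode_site()]:
#' builds a `recoded_site` from an existing original/engineered pair,
#' inferring the frame under which the pair is synonymous via
#' [infer_matching_frame()].
#'
#' @param original,engineered Equal-length site sequences.
#' @return A `recoded_site` list (with the inferred `frame_result` attached
#'   as `frame`).
#' @export
recoded_site_pair <- function(original, engineered) {
  original <- as_dna(original, "original")
  engineered <- as_dna(engineered, "engineered")
  if (nchar(original) != nchar(engineered)) {
    stop("original and engineered sites must have equal length", call. = FALSE)
  }
  fr <- infer_matching_frame(original, engineered)
  structure(list(
    original = original,
    engineered = engineered,
    n_substitutions = hamming(original, engineered),
    substitution_positions = diff_positions(original, engineered),
    synonymy_verified = fr$synonymous,
    per_codon_mismatches = NULL,
    stop_codons_preserved = character(0),
    frame_offset = fr$frame_offset,
    orientation = fr$orientation,
    frame = fr
  ), class = "recoded_site")
}

#' Check an engineered site against resistance thresholds
#'
#' A recoded site is declared resistant when its total mismatch count reaches
#' `min_total_mismatches` and the mismatches falling inside the declared seed
#' interval reach `min_seed_mismatches`. The seed interval is given 1-based,
#' inclusive, in site coordinates (the seed of the guide maps to one end of
#' its complementary site; pass the interval appropriate to how the site is
#' oriented).
#'
#' @param recoded A `recoded_site` (from [recode_site()] or
#'   [recoded_site_pair()]).
#' @param min_total_mismatches Minimum total substitutions.
#' @param min_seed_mismatches Minimum substitutions inside `seed_interval`.
#' @param seed_interval Length-2 integer vector `c(start, end)`, 1-based
#'   inclusive, within the site; `NULL` skips the seed check.
#' @return List: `resistant` (logical), `n_total`, `n_seed`,
#'   `positions`, `seed_positions`, and the thresholds applied.
#' @export
verify_resistance <- function(recoded, min_total_mismatches,
                              min_seed_mismatches = 0L,
                              seed_interval = NULL) {
  stopifnot(inherits(recoded, "recoded_site"))
  pos <- recoded$substitution_positions
  len <- nchar(recoded$original)
  n_seed <- 0L
  seed_pos <- integer(0)
  if (!is.null(seed_interval)) {
    stopifnot(length(seed_interval) == 2L)
    if (seed_interval[1] < 1L || seed_interval[2] > len ||
        seed_interval[1] > seed_interval[2]) {
      stop("seed interval must lie within the site (1..", len, ")",
           call. = FALSE)
    }
    seed_pos <- pos[pos >= seed_interval[1] & pos <= seed_interval[2]]
    n_seed <- length(seed_pos)
  }
  ok <- length(pos) >= min_total_mismatches &&
    (is.null(seed_interval) || n_seed >= min_seed_mismatches)
  list(resistant = ok,
       n_total = length(pos),
       n_seed = n_seed,
       positions = pos,
       seed_positions = seed_pos,
       min_total_mismatches = as.integer(min_total_mismatches),
       min_seed_mismatches = as.integer(min_seed_mismatches),
       seed_interval = seed_interval)
}

#' Rank candidate target sites of a coding sequence by recodability
#'
#' Slides a window of `site_length` along `cds` (read in frame 0, sense) and
#' scores each offset by the number of synonymous substitutions
#' [recode_site()] can place inside it. Guide-affinity and off-target scoring
#' are out of scope; this ranks sites purely by how far a resistant
#' replacement can diverge.
#'
#' @param cds Coding sequence.
#' @param site_length Window length (default 21).
#' @return data.frame with columns `offset` (0-based), `site`,
#'   `max_recodable_mismatches`, sorted by score descending, ties by offset.
#' @export
enumerate_candidate_sites <- function(cds, site_length = 21L) {
  cds <- as_dna(cds, "cds")
  site_length <- as.integer(site_length)
  if (nchar(cds) < site_length) {
    stop("cds shorter than site_length", call. = FALSE)
  }
  offsets <- 0:(nchar(cds) - site_length)
  score <- vapply(offsets, function(o) {
    recode_site(coding_context(cds, o, site_length))$n_substitutions
  }, integer(1L))
  site <- vapply(offsets, function(o) substr(cds, o + 1L, o + site_length),
                 character(1L))
  out <- data.frame(offset = offsets, site = site,
                    max_recodable_mismatches = score,
                    stringsAsFactors = FALSE)
  out[order(-out$max_recodable_mismatches, out$offset), , drop = FALSE]
}
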
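#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T); undetermined (N) bases are excluded
#' from both numerator and denominator.
#'
#' @param seq character vector of sequences
#' @return numeric vector of fractions in [0, 1]
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq)) || !length(seq)) stopf("empty sequence")
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "")[[1]]
    b <- b[b %in% c("A", "C", "G", "T")]
    if (!length(b)) stopf("sequence has no determined bases")
    sum(b %in% c("G", "C")) / length(b)
  }, 0, USE.NAMES = FALSE)
}

#' Branch-point search in the 3' intronic window
#'
#' Enumerates heptamer candidates matching the relaxed branch-point consensus
#' `nnYTRAY` (branch adenosine at position 6) within the last `window` nt of
#' the intron, scores each with a PWM log-odds model, and reports the best
#' score, the distances of the top three candidates to the 3' splice site
#' (ties broken towards the 3' splice site) and the polypyrimidine-tract
#' length between the best branch point and the 3' splice site. The tract is
#' the longest C/T stretch tolerating at most one purine interruption.
#' Sequences shorter than `window` are scanned in full; the scan never reads
#' outside the supplied sequence. An adapter function may replace the PWM
#' (signature `f(heptamer)` returning a score).
#'
#' @param seq intron sequence (3' end at the right); at most the last
#'   `window` nt are used
#' @param pwm 4 x 7 branch-point PWM, or a scoring function
#' @param window maximum scan window in nt (default 150)
#' @return list with bp_score, bp_distance, top3_distances,
#'   median_bp_distance, ppt_length, missing (logical)
#' @export
find_branch_points <- function(seq, pwm, window = 150L) {
  n <- nchar(seq)
  region <- if (n > window) substring(seq, n - window + 1L, n) else seq
  region <- toupper(region)
  rl <- nchar(region)
  miss <- list(bp_score = NA_real_, bp_distance = NA_real_,
               top3_distances = numeric(0), median_bp_distance = NA_real_,
               ppt_length = NA_real_, missing = TRUE)
  if (rl < 7L) return(miss)
  starts <- seq_len(rl - 6L)
  hept <- substring(region, starts, starts + 6L)
  ok <- grepl("^[ACGT]{2}[CT]T[AG]A[CT]$", hept)
  if (!any(ok)) return(miss)
  starts <- starts[ok]; hept <- hept[ok]
  score <- if (is.function(pwm)) vapply(hept, pwm, 0, USE.NAMES = FALSE)
           else vapply(hept, pwm_score, 0, pwm = pwm, USE.NAMES = FALSE)
  dist <- rl - (starts + 5L)            # nt from branch A to the 3' splice site
  o <- order(-score, dist)
  top <- o[seq_len(min(3L, length(o)))]
  best <- top[1]
  list(bp_score = score[best], bp_distance = dist[best],
       top3_distances = dist[top], median_bp_distance = stats::median(dist[top]),
       ppt_length = ppt_length(substring(region, starts[best] + 6L, rl)),
       missing = FALSE)
}

# longest C/T stretch with at most one purine interruption
ppt_length <- function(seq) {
  if (!nchar(seq)) return(0L)
  py <- strsplit(toupper(seq), "")[[1]] %in% c("C", "T")
  n <- length(py)
  best <- 0L; left <- 1L; bad <- 0L
  for (right in seq_len(n)) {
    if (!py[right]) bad <- bad + 1L
    while (bad > 1L) {
      if (!py[left]) bad <- bad - 1L
      left <- left + 1L
    }
    best <- max(best, right - left + 1L)
  }
  as.integer(best)
}

#' Extract the intron/exon feature panel
#'
#' Assembles, for every catalogued intron, the predictor panel used for group
#' comparisons and dependence modelling: intron and flanking-exon lengths and
#' GC content, exon/intron length and GC ratios (per flank and mean flank),
#' splice-site scores, branch-point features, SF1 maximum log-score, position
#' along the transcript, transcript length, wild-type expression and (when a
#' `nmd_class` column is present) an NMD indicator. Introns whose
#' branch-point scan finds no candidate are imputed with the cohort minimum
#' score, distance equal to the scan window and tract length 0, and flagged
#' via `bp_missing`.
#'
#' @param catalog an `intron_catalog`, optionally with an `nmd_class` column
#' @param genome named `DNAStringSet`
#' @param pwms list with elements donor, acceptor, branchpoint, sf1 (matrices
#'   from [read_pwm()] or scoring functions)
#' @param expression optional named numeric vector of wild-type cRPKM per
#'   gene_id (log2(1+x) is taken); missing genes get 0
#' @param bp_window branch-point scan window (default 150)
#' @return data.frame, one row per intron: intron_id plus named features
#' @export
extract_features <- function(catalog, genome, pwms, expression = NULL,
                             bp_window = 150L) {
  for (p in c("donor", "acceptor", "branchpoint", "sf1"))
    if (is.null(pwms[[p]])) stopf("incomplete feature inputs: missing %s PWM", p)
  n <- nrow(catalog)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- catalog[i, ]
    iseq <- fetch_seq(genome, r$chrom, r$start, r$end, r$strand)
    up_seq <- fetch_seq(genome, r$chrom, r$up_exon_start, r$up_exon_end,
                        r$strand)
    dn_seq <- fetch_seq(genome, r$chrom, r$down_exon_start, r$down_exon_end,
                        r$strand)
    ilen <- nchar(iseq)
    if (ilen < 26L || nchar(up_seq) < 3L || nchar(dn_seq) < 3L)
      stopf("incomplete features for %s: intron or flanking exon too short for site scoring",
            r$intron_id)
    donor <- paste0(substring(up_seq, nchar(up_seq) - 2L), substring(iseq, 1L, 6L))
    acceptor <- paste0(substring(iseq, ilen - 19L), substring(dn_seq, 1L, 3L))
    bp <- find_branch_points(iseq, pwms$branchpoint, window = bp_window)
    sf1_region <- if (ilen > bp_window)
      substring(iseq, ilen - bp_window + 1L, ilen) else iseq
    igc <- gc_content(iseq); ugc <- gc_content(up_seq); dgc <- gc_content(dn_seq)
    ulen <- nchar(up_seq); dlen <- nchar(dn_seq)
    expr <- if (is.null(expression)) 0 else expression[r$gene_id]
    if (is.null(expr) || is.na(expr)) expr <- 0
    rows[[i]] <- data.frame(
      intron_id = r$intron_id,
      intron_length = ilen, log_intron_length = log10(ilen), intron_gc = igc,
      up_exon_length = ulen, down_exon_length = dlen,
      up_exon_gc = ugc, down_exon_gc = dgc,
      len_ratio_up = ulen / ilen, len_ratio_down = dlen / ilen,
      len_ratio_mean = mean(c(ulen, dlen)) / ilen,
      gc_ratio_up = ugc / igc, gc_ratio_down = dgc / igc,
      gc_ratio_mean = mean(c(ugc, dgc)) / igc,
      ss5_score = score_splice_site(donor, "donor", pwms$donor),
      ss3_score = score_splice_site(acceptor, "acceptor", pwms$acceptor),
      bp_score = bp$bp_score, bp_dist_median = bp$median_bp_distance,
      ppt_length = as.numeric(bp$ppt_length),
      bp_missing = as.numeric(bp$missing),
      sf1_score = scan_pwm_max(sf1_region, pwms$sf1),
      ordinal = r$ordinal, rel_position = r$ordinal / r$n_introns,
      first_two = as.numeric(r$ordinal <= 2L),
      last_intron = as.numeric(r$ordinal == r$n_introns),
      n_introns = r$n_introns,
      transcript_length = NA_real_,
      wt_expression_log = log2(1 + expr),
      stringsAsFactors = FALSE)
    if ("nmd_class" %in% names(catalog))
      rows[[i]]$nmd_ind <- as.numeric(r$nmd_class == "NMD")
  }
  out <- do.call(rbind, rows)
  # transcript length = spliced exon sum, from the catalog's exon bookkeeping
  txlen <- tapply(
    catalog$up_exon_end - catalog$up_exon_start, catalog$transcript_id, sum)
  lastex <- tapply(seq_len(n), catalog$transcript_id, function(ix) {
    j <- ix[which.max(catalog$ordinal[ix])]
    catalog$down_exon_end[j] - catalog$down_exon_start[j]
  })
  out$transcript_length <- as.numeric(txlen[catalog$transcript_id] +
                                        lastex[catalog$transcript_id])
  # impute missing branch points with the cohort minimum / window distance
  if (any(out$bp_missing > 0)) {
    have <- out$bp_missing == 0
    min_score <- if (any(have)) min(out$bp_score[have]) else 0
    out$bp_score[!have] <- min_score
    out$bp_dist_median[!have] <- bp_window
    out$ppt_length[!have] <- 0
  }
  rownames(out) <- NULL
  out
}

#' Compare feature distributions between two intron groups
#'
#' Per-feature two-sided Mann-Whitney U test (Wilcoxon rank-sum) with group
#' medians, as used to contrast retained and control introns.
#'
#' @param features data.frame of numeric features (non-numeric columns are
#'   ignored; an `intron_id` column is dropped)
#' @param group two-level factor/character vector, one entry per row
#' @return data.frame: feature, median per group, p_value
#' @export
compare_feature_groups <- function(features, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stopf("need exactly two groups")
  if (any(table(g) < 3L)) stopf("each group needs at least 3 members")
  num <- features[vapply(features, is.numeric, TRUE)]
  out <- do.call(rbind, lapply(names(num), function(f) {
    a <- num[[f]][g == levels(g)[1]]
    b <- num[[f]][g == levels(g)[2]]
    p <- tryCatch(stats::wilcox.test(a, b, exact = FALSE)$p.value,
                  error = function(e) NA_real_)
    data.frame(feature = f, median_a = stats::median(a),
               median_b = stats::median(b), p_value = p,
               stringsAsFactors = FALSE)
  }))
  names(out)[2:3] <- paste0("median_", levels(g))
  out
}

#' Fisher's exact enrichment test for set overlaps
#'
#' Convenience wrapper building the 2x2 contingency table for "membership in
#' set A" vs "membership in set B" over a universe of ids.
#'
#' @param a,b id vectors
#' @param universe id vector containing both sets
#' @return htest object from [stats::fisher.test()]
#' @export
fisher_enrichment <- function(a, b, universe) {
  ina <- universe %in% a
  inb <- universe %in% b
  stats::fisher.test(table(ina, inb))
}
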
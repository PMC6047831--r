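#' Percent intron retention (PIR) from junction counts
#'
#' PIR is the average number of reads spanning the 5' and 3' exon-intron
#' junctions over that average plus all exon-exon junction reads supporting
#' removal of the intron:
#' \deqn{PIR = 100 \cdot m / (m + EE), \quad m = (EI_5 + EI_3)/2.}
#' All exon-exon junctions whose splicing removes the intron count towards
#' `ee`, not only the one joining the two neighbouring exons; this guards
#' against false positives at introns involved in other splicing events.
#'
#' @param ei5,ei3 non-negative integer counts of reads spanning the 5' and 3'
#'   exon-intron junctions
#' @param ee total count of reads on all exon-exon junctions supporting
#'   splicing of the intron
#' @return PIR in percent (0-100); `NA` where all three counts are zero
#'   (undefined, distinct from 0)
#' @export
compute_pir <- function(ei5, ei3, ee) {
  check_counts(ei5, ei3, ee)
  m <- (ei5 + ei3) / 2
  out <- 100 * m / (m + ee)
  out[ei5 == 0 & ei3 == 0 & ee == 0] <- NA_real_
  out
}

check_counts <- function(...) {
  for (x in list(...)) {
    if (any(x < 0) || any(x != floor(x)))
      stopf("junction counts must be non-negative integers")
  }
  invisible(TRUE)
}

#' Junction read-coverage filter
#'
#' An intron is quantifiable in a sample when at least 15 reads support the
#' inclusion of one splice site and 10 the other, or when splicing of the
#' intron is supported by a total of at least 15 reads. The default reads the
#' second clause as `ee >= 15` (splicing = exon-exon reads); `rule = "total"`
#' applies the alternative reading of 15 reads across all junction types.
#'
#' @inheritParams compute_pir
#' @param min_hi,min_lo inclusion-read thresholds (defaults 15 and 10)
#' @param min_splice splicing-read threshold (default 15)
#' @param rule interpretation of the splicing clause, `"ee"` or `"total"`
#' @return logical vector
#' @export
passes_coverage <- function(ei5, ei3, ee, min_hi = 15L, min_lo = 10L,
                            min_splice = 15L, rule = c("ee", "total")) {
  rule <- match.arg(rule)
  check_counts(ei5, ei3, ee)
  incl <- pmax(ei5, ei3) >= min_hi & pmin(ei5, ei3) >= min_lo
  spl <- if (rule == "ee") ee >= min_splice else (ei5 + ei3 + ee) >= min_splice
  incl | spl
}

#' Per-intron PIR table across a paired design
#'
#' Computes PIR for every intron/sample pair, applies the junction coverage
#' filter, and derives delta-PIR (mutant minus matched sibling) per pair. An
#' intron is `covered` only when it passes the coverage filter in all samples;
#' introns with an undefined PIR in any sample are treated as uncovered.
#'
#' @param junctions data.frame with columns intron_id, sample_id, ei5, ei3,
#'   ee_support
#' @param metadata data.frame with columns sample_id, condition (`"mutant"` or
#'   `"sibling"`), pair_id, library_size
#' @param rule coverage-filter clause interpretation, see [passes_coverage()]
#' @return data.frame with one row per intron: pir_<sample> columns,
#'   delta_<pair> columns, and `covered`
#' @export
pir_table <- function(junctions, metadata, rule = c("ee", "total")) {
  rule <- match.arg(rule)
  need <- c("intron_id", "sample_id", "ei5", "ei3", "ee_support")
  if (!all(need %in% names(junctions)))
    stopf("junction table must have columns %s", paste(need, collapse = ", "))
  samples <- metadata$sample_id
  pairs <- sort(unique(metadata$pair_id))
  if (!all(vapply(pairs, function(p)
    all(c("mutant", "sibling") %in%
          metadata$condition[metadata$pair_id == p]), TRUE)))
    stopf("incomplete design: every pair needs one mutant and one sibling sample")
  ids <- sort(unique(junctions$intron_id))
  pir <- matrix(NA_real_, length(ids), length(samples),
                dimnames = list(ids, samples))
  pass <- matrix(FALSE, length(ids), length(samples),
                 dimnames = list(ids, samples))
  for (s in samples) {
    sub <- junctions[junctions$sample_id == s, , drop = FALSE]
    idx <- match(sub$intron_id, ids)
    pir[idx, s] <- compute_pir(sub$ei5, sub$ei3, sub$ee_support)
    pass[idx, s] <- passes_coverage(sub$ei5, sub$ei3, sub$ee_support,
                                    rule = rule)
  }
  covered <- rowSums(pass) == length(samples) & stats::complete.cases(pir)
  out <- data.frame(intron_id = ids, stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("pir_", s)]] <- pir[, s]
  for (p in pairs) {
    mut <- metadata$sample_id[metadata$pair_id == p &
                                metadata$condition == "mutant"][1]
    sib <- metadata$sample_id[metadata$pair_id == p &
                                metadata$condition == "sibling"][1]
    out[[paste0("delta_", p)]] <- pir[, mut] - pir[, sib]
  }
  out$covered <- covered
  out
}

#' Call retained and control intron sets
#'
#' The confidently factor-dependent set ("RESdep") contains introns with
#' delta-PIR strictly above `delta_high` and a net intron-body read-density
#' increase of at least `density_fold` in at least `min_mutants` of the pairs.
#' The control set ("Ctr") contains introns with absolute delta-PIR strictly
#' below `delta_ctr` in all pairs. Per-pair sets at `delta_high` and
#' `delta_shared` are emitted as logical columns. Introns not covered in every
#' sample are excluded from all sets. All delta-PIR thresholds are strict;
#' the density threshold is inclusive ("at least 1.5-fold").
#'
#' @param pir a table from [pir_table()] (columns delta_<pair>, covered)
#' @param density data.frame with intron_id and ratio_<pair> columns of net
#'   density increase values (see [net_density_increase()]); an `NA` ratio
#'   fails the density criterion for that pair
#' @param delta_high RESdep and per-mutant delta-PIR cutoff (default 15)
#' @param delta_ctr control absolute delta-PIR cutoff (default 0.5)
#' @param delta_shared relaxed per-mutant cutoff for overlap summaries
#'   (default 5)
#' @param density_fold net density-increase cutoff (default 1.5)
#' @param min_mutants pairs required for RESdep (default 2)
#' @return `pir` with added logical columns `resdep`, `ctr`,
#'   `dep15_<pair>`, `dep5_<pair>`
#' @export
call_intron_sets <- function(pir, density, delta_high = 15, delta_ctr = 0.5,
                             delta_shared = 5, density_fold = 1.5,
                             min_mutants = 2L) {
  dcols <- grep("^delta_", names(pir), value = TRUE)
  pairs <- sub("^delta_", "", dcols)
  if (length(pairs) < 3L)
    stopf("incomplete design: need 3 mutant/sibling pairs, got %d",
          length(pairs))
  rcols <- paste0("ratio_", pairs)
  if (!all(rcols %in% names(density)))
    stopf("density table must have columns %s", paste(rcols, collapse = ", "))
  dmat <- as.matrix(pir[dcols])
  rmat <- as.matrix(density[rcols])[match(pir$intron_id, density$intron_id), ,
                                    drop = FALSE]
  dep_pair <- dmat > delta_high & !is.na(rmat) & rmat >= density_fold
  ok <- pir$covered & stats::complete.cases(dmat)
  pir$resdep <- ok & rowSums(dep_pair, na.rm = TRUE) >= min_mutants
  pir$ctr <- ok & apply(abs(dmat) < delta_ctr, 1, all)
  for (i in seq_along(pairs)) {
    pir[[paste0("dep15_", pairs[i])]] <- ok & dmat[, i] > delta_high
    pir[[paste0("dep5_", pairs[i])]] <- ok & dmat[, i] > delta_shared
  }
  stopifnot(!any(pir$resdep & pir$ctr))
  pir
}

#' Three-set overlap summary
#'
#' Counts the seven regions of the three-set partition (as drawn in an Euler
#' diagram of per-mutant retained-intron sets).
#'
#' @param a,b,c vectors of member ids
#' @return named integer vector: a_only, b_only, c_only, ab, ac, bc, abc
#' @export
summarize_overlaps <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  out <- c(a_only = sum(ina & !inb & !inc),
           b_only = sum(!ina & inb & !inc),
           c_only = sum(!ina & !inb & inc),
           ab = sum(ina & inb & !inc),
           ac = sum(ina & !inb & inc),
           bc = sum(!ina & inb & inc),
           abc = sum(ina & inb & inc))
  stopifnot(sum(out) == length(u))
  out
}
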
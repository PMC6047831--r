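#' Count uniquely mappable positions of a feature
#'
#' Every `window`-nt segment of the feature in 1-nt sliding windows is matched,
#' allowing up to `max_mismatch` mismatches, against a library of full-length
#' feature sequences (forward strand) plus the whole genome (both strands),
#' emulating a short-read aligner run with "-m 2 -v 2" semantics. A window
#' from a unique locus is expected to hit exactly twice: once at its own
#' position in the library and once at the corresponding genomic position.
#' Windows with more than two hits are multi-mappable; windows with zero hits
#' (e.g. runs of undetermined N bases, which are treated as unmappable) are
#' non-mappable. Uniquely mappable positions are the remainder.
#'
#' Matching is exact brute-force mismatch counting (via
#' [Biostrings::countPattern()]), intended for desk-scale genomes.
#'
#' @param feature_seq character or `DNAString`, the feature sequence
#' @param genome named `DNAStringSet` of chromosomes
#' @param library `DNAStringSet` (or character vector) of all feature
#'   sequences, including this feature
#' @param window segment width in nt (default 50)
#' @param max_mismatch allowed mismatches per hit (default 2)
#' @param both_strands match the genome on both strands (default TRUE,
#'   the aligner's behaviour); the library is always forward-strand only
#' @return list with n_segments, n_multi, n_unmappable, n_unique
#' @export
count_mappable_positions <- function(feature_seq, genome, library,
                                     window = 50L, max_mismatch = 2L,
                                     both_strands = TRUE) {
  feature_seq <- Biostrings::DNAString(as.character(feature_seq))
  if (!methods::is(library, "DNAStringSet"))
    library <- Biostrings::DNAStringSet(as.character(library))
  len <- length(feature_seq)
  n_seg <- max(0L, len - window + 1L)
  if (n_seg == 0L)
    return(list(n_segments = 0L, n_multi = 0L, n_unmappable = 0L,
                n_unique = 0L))
  n_multi <- 0L; n_unmap <- 0L
  for (i in seq_len(n_seg)) {
    w <- Biostrings::subseq(feature_seq, start = i, width = window)
    ws <- as.character(w)
    if (grepl("[^ACGT]", ws)) { n_unmap <- n_unmap + 1L; next }
    hits <- sum(Biostrings::vcountPattern(w, library,
                                          max.mismatch = max_mismatch,
                                          fixed = TRUE)) +
      sum(Biostrings::vcountPattern(w, genome, max.mismatch = max_mismatch,
                                    fixed = TRUE))
    if (both_strands) {
      rc <- Biostrings::reverseComplement(w)
      hits <- hits + sum(Biostrings::vcountPattern(rc, genome,
                                                   max.mismatch = max_mismatch,
                                                   fixed = TRUE))
    }
    if (hits > 2L) n_multi <- n_multi + 1L
    else if (hits == 0L) n_unmap <- n_unmap + 1L
  }
  list(n_segments = n_seg, n_multi = n_multi, n_unmappable = n_unmap,
       n_unique = n_seg - n_multi - n_unmap)
}

#' Mappability table for a set of features
#'
#' Applies [count_mappable_positions()] to every sequence of a feature set
#' against the set itself as library.
#'
#' @param seqs named character vector or `DNAStringSet` of feature sequences
#' @param genome named `DNAStringSet`
#' @inheritParams count_mappable_positions
#' @return data.frame with feature_id, n_segments, n_multi, n_unmappable,
#'   n_unique
#' @export
mappability_table <- function(seqs, genome, window = 50L, max_mismatch = 2L,
                              both_strands = TRUE) {
  lib <- if (methods::is(seqs, "DNAStringSet")) seqs
         else Biostrings::DNAStringSet(seqs)
  rows <- lapply(seq_along(lib), function(i) {
    m <- count_mappable_positions(lib[[i]], genome, lib, window = window,
                                  max_mismatch = max_mismatch,
                                  both_strands = both_strands)
    data.frame(feature_id = names(lib)[i] %||% as.character(i),
               n_segments = m$n_segments, n_multi = m$n_multi,
               n_unmappable = m$n_unmappable, n_unique = m$n_unique,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cap per-position intronic read counts
#'
#' Positions with a read count more than five times the median count of the
#' whole intron (median taken over all positions, zeros included) are set to
#' `cap_fold` times the median; when the median is zero, counts are capped at
#' `cap_fold`. This limits artefacts from heterogeneous intronic sequence such
#' as expressed repeats or nested genes.
#'
#' @param counts numeric vector of per-position read counts
#' @param cap_fold cap multiplier (default 5)
#' @return capped counts, same length
#' @export
cap_position_counts <- function(counts, cap_fold = 5) {
  if (!length(counts)) stopf("empty coverage profile")
  med <- stats::median(counts)
  cap <- if (med == 0) cap_fold else cap_fold * med
  pmin(counts, cap)
}

#' Mappability-corrected read density (cRPKM / ciRPKM)
#'
#' Reads per kilobase of uniquely mappable positions per million mapped reads:
#' `count / (n_unique/1000) / (library_size/1e6)`. Applied to capped intronic
#' counts this is the ciRPKM; applied to exonic transcript counts, the cRPKM.
#'
#' @param count read count for the feature (after capping, for introns)
#' @param n_unique number of uniquely mappable positions
#' @param library_size total mapped reads in the sample
#' @return density value; `NA` where `n_unique` is 0 (undefined)
#' @export
compute_density <- function(count, n_unique, library_size) {
  if (any(library_size <= 0)) stopf("library_size must be positive")
  out <- count / (n_unique / 1000) / (library_size / 1e6)
  out[n_unique == 0] <- NA_real_
  out
}

#' Net intron-body read-density increase
#'
#' Ratio of retention-normalized intronic densities between mutant and
#' sibling: `[ciRPKM_mut/(100-PIR_mut)] / [ciRPKM_sib/(100-PIR_sib)]`.
#' Compared against the 1.5-fold criterion when calling confidently retained
#' introns. Undefined (NA) when either PIR is 100.
#'
#' @param cirpkm_mut,cirpkm_sib intronic densities
#' @param pir_mut,pir_sib PIR values in percent
#' @return ratio; `NA` where either PIR equals 100
#' @export
net_density_increase <- function(cirpkm_mut, pir_mut, cirpkm_sib, pir_sib) {
  out <- (cirpkm_mut / (100 - pir_mut)) / (cirpkm_sib / (100 - pir_sib))
  out[pir_mut >= 100 | pir_sib >= 100] <- NA_real_
  out
}

#' Quantile normalization of an expression matrix
#'
#' Standard quantile normalization (each sample's sorted values replaced by
#' the across-sample mean of sorted values; ties receive the mean of their
#' rank range), as implemented in limma's `normalizeQuantiles`. Features are
#' rows, samples are columns.
#'
#' @param mat numeric matrix, features x samples
#' @return normalized matrix of the same shape
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stopf("need at least 2 samples")
  if (anyNA(mat)) stopf("missing values: filter features before normalization")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Call differentially expressed genes
#'
#' Genes are first filtered for minimum expression (cRPKM above `min_crpkm`
#' in all sibling samples or all mutant samples) and quantification support
#' (at least `min_reads` raw read counts in at least one sample). Among the
#' remaining genes, fold changes are computed per mutant/sibling pair on
#' quantile-normalized cRPKM; a gene is `up` (resp. `down`) when its fold
#' change is at least `fc_all` in the same direction in all pairs and at
#' least `fc_two` in at least two of them; all other genes are `unaffected`.
#'
#' @param crpkm numeric matrix of cRPKM values, genes x samples
#' @param counts numeric matrix of raw read counts, genes x samples
#' @param metadata data.frame with sample_id, condition, pair_id
#' @param min_crpkm expression filter (default 2)
#' @param min_reads read-support filter (default 50)
#' @param fc_all fold-change required in all pairs (default 1.5)
#' @param fc_two fold-change required in two pairs (default 2)
#' @return data.frame with gene_id, passed_filter, fc_<pair> columns, label
#' @export
call_differential_expression <- function(crpkm, counts, metadata,
                                         min_crpkm = 2, min_reads = 50,
                                         fc_all = 1.5, fc_two = 2) {
  pairs <- sort(unique(metadata$pair_id))
  if (length(pairs) < 3L)
    stopf("incomplete design: need 3 mutant/sibling pairs, got %d",
          length(pairs))
  sib <- metadata$sample_id[metadata$condition == "sibling"]
  mut <- metadata$sample_id[metadata$condition == "mutant"]
  passed <- (rowSums(crpkm[, sib, drop = FALSE] > min_crpkm) == length(sib) |
               rowSums(crpkm[, mut, drop = FALSE] > min_crpkm) == length(mut)) &
    apply(counts >= min_reads, 1, any)
  norm <- quantile_normalize(crpkm)
  fc <- sapply(pairs, function(p) {
    m <- metadata$sample_id[metadata$pair_id == p &
                              metadata$condition == "mutant"][1]
    s <- metadata$sample_id[metadata$pair_id == p &
                              metadata$condition == "sibling"][1]
    norm[, m] / norm[, s]
  })
  colnames(fc) <- pairs
  up <- rowSums(fc >= fc_all) == length(pairs) & rowSums(fc >= fc_two) >= 2
  dn <- rowSums(fc <= 1 / fc_all) == length(pairs) &
    rowSums(fc <= 1 / fc_two) >= 2
  label <- rep("unaffected", nrow(crpkm))
  label[passed & up] <- "up"
  label[passed & dn] <- "down"
  out <- data.frame(gene_id = rownames(crpkm) %||%
                      as.character(seq_len(nrow(crpkm))),
                    passed_filter = passed, stringsAsFactors = FALSE)
  for (p in pairs) out[[paste0("fc_", p)]] <- fc[, p]
  out$label <- label
  out
}
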
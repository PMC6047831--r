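# Shared fixtures: toy transcripts with hand-derivable structure, a pure-R
# Hamming-distance mappability oracle, and tiny PWMs with analytic optima.

# stop-free filler: only G/C/A, so no stop codon can occur in any frame
filler <- function(n) {
  if (n == 0) return("")
  substring(strrep("GCA", ceiling(n / 3)), 1, n)
}

# intron body from the same safe alphabet, with GT...AG ends; the only T is
# at position 2 and is followed by G, so no stop can form in any frame
toy_intron <- function(n, stop_at = NA) {
  stopifnot(n >= 6)
  s <- paste0("GT", filler(n - 4), "AG")
  if (!is.na(stop_at))  # 0-based offset of "TAA" within the intron
    s <- paste0(substring(s, 1, stop_at), "TAA", substring(s, stop_at + 4, n))
  stopifnot(nchar(s) == n)
  s
}

# Assemble a toy gene from alternating exon/intron sequences. `segments` is a
# character vector starting and ending with an exon. The CDS covers spliced
# positions [utr5, utr5 + cds_len); cds_len = NULL means non-coding,
# cds_len = "auto" uses the largest multiple of 3 leaving >= 3 nt of 3' UTR.
toy_gene <- function(segments, utr5 = 9L, cds_len = "auto", strand = "+",
                     pad = 25L, transcript_id = "t1", gene_id = "g1") {
  n_seg <- length(segments)
  stopifnot(n_seg %% 2L == 1L)
  lens <- nchar(segments)
  seg_ends <- cumsum(lens); seg_starts <- c(0L, seg_ends[-n_seg])
  ex_idx <- seq(1L, n_seg, by = 2L)
  exons_t <- cbind(seg_starts[ex_idx], seg_ends[ex_idx])  # tx orientation
  spliced <- sum(lens[ex_idx])
  gene_seq <- paste(segments, collapse = "")
  glen <- nchar(gene_seq)
  genome_seq <- paste0(filler(pad), gene_seq, filler(pad))
  L <- nchar(genome_seq)
  cds <- NULL
  if (!is.null(cds_len)) {
    if (identical(cds_len, "auto")) cds_len <- 3L * ((spliced - utr5 - 3L) %/% 3L)
    # map spliced coordinate to gene coordinate (plus orientation)
    sp2g <- function(pos) {
      off <- 0L
      for (j in seq_len(nrow(exons_t))) {
        w <- exons_t[j, 2] - exons_t[j, 1]
        if (pos < off + w) return(exons_t[j, 1] + (pos - off))
        off <- off + w
      }
      stop("spliced position out of range")
    }
    cds <- c(sp2g(utr5), sp2g(utr5 + cds_len - 1L) + 1L)
  }
  if (strand == "+") {
    exons <- pad + exons_t
    if (!is.null(cds)) cds <- pad + cds
  } else {
    genome_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genome_seq)))
    exons <- cbind(L - (pad + exons_t[, 2]), L - (pad + exons_t[, 1]))
    exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    if (!is.null(cds)) cds <- c(L - (pad + cds[2]), L - (pad + cds[1]))
  }
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "chr1"
  model <- transcript_model(transcript_id, gene_id, "chr1", strand, exons,
                            cds = cds)
  list(genome = genome, model = model)
}

toy_catalog <- function(toy) {
  models <- stats::setNames(list(toy$model), toy$model$transcript_id)
  build_intron_catalog(models)
}

# ---- independent mappability oracle: exhaustive Hamming enumeration --------

enc_seq <- function(s) utf8ToInt(toupper(s))

# hits of every `window`-wide segment of `feat` in `subj` with <= mm
# mismatches, via exhaustive sliding of the whole feature at every lag
oracle_hits_subject <- function(feat, subj, window, mm) {
  nf <- length(feat); ns <- length(subj)
  nw <- nf - window + 1L
  hits <- integer(max(nw, 0L))
  if (nw < 1L) return(hits)
  for (lag in (-(nf - 1L)):(ns - 1L)) {
    j1 <- max(1L, 1L - lag); j2 <- min(nf, ns - lag)
    len <- j2 - j1 + 1L
    if (len < window) next
    eq <- feat[j1:j2] == subj[(j1:j2) + lag]
    cs <- cumsum(!eq)
    mis <- cs[window:len] - c(0L, cs[seq_len(len - window)])
    ks <- j1:(j2 - window + 1L)
    ok <- mis <= mm
    hits[ks[ok]] <- hits[ks[ok]] + 1L
  }
  hits
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# oracle equivalent of count_mappable_positions()
oracle_mappability <- function(feature_seq, genome_seqs, library_seqs,
                               window = 50L, mm = 2L) {
  f <- enc_seq(feature_seq)
  nw <- max(0L, length(f) - window + 1L)
  if (nw == 0L)
    return(list(n_segments = 0L, n_multi = 0L, n_unmappable = 0L,
                n_unique = 0L))
  hits <- integer(nw)
  for (s in library_seqs)
    hits <- hits + oracle_hits_subject(f, enc_seq(s), window, mm)
  for (g in genome_seqs) {
    hits <- hits + oracle_hits_subject(f, enc_seq(g), window, mm)
    hits <- hits + oracle_hits_subject(f, enc_seq(revcomp_chr(g)), window, mm)
  }
  # windows containing an undetermined base are unmappable by definition
  is_acgt <- f %in% utf8ToInt("ACGT")
  cs <- cumsum(!is_acgt)
  hasN <- (cs[window:length(f)] -
             c(0L, cs[seq_len(length(f) - window)])) > 0L
  n_multi <- sum(!hasN & hits > 2L)
  n_unmap <- sum(hasN | hits == 0L)
  list(n_segments = nw, n_multi = n_multi, n_unmappable = n_unmap,
       n_unique = nw - n_multi - n_unmap)
}

# ---- tiny PWM fixtures ------------------------------------------------------

uniform_pwm <- function(width) {
  m <- matrix(0.25, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}

# PWM whose consensus is `consensus`, with given consensus probability
consensus_pwm <- function(consensus, p = 0.7) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, 4, length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(bases)) m[bases[i], i] <- p
  m
}

pwm_max_score <- function(pwm) sum(log2(apply(pwm, 2, max) / 0.25))

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---- read-level PIR simulator (independent of compute_pir internals) -------

# Draw `n_reads` junction reads from a transcript pool with true retention
# fraction rho: a read lands on a junction position; a retained transcript
# exposes two exon-intron junctions, a spliced one exposes one exon-exon
# junction, so P(exon-intron read) = 2 rho / (1 + rho).
simulate_junction_reads <- function(n_reads, rho) {
  ei <- stats::rbinom(1L, n_reads, 2 * rho / (1 + rho))
  ei5 <- stats::rbinom(1L, ei, 0.5)
  c(ei5 = ei5, ei3 = ei - ei5, ee = n_reads - ei)
}

# ---- NMD toy panel ----------------------------------------------------------
# Constructed transcripts whose NMD consequence on intron retention is
# hand-derivable. Fillers use only G/C/A so the only stop codons present are
# the planted TAAs; coordinates below are spliced-transcript positions with
# the CDS starting at 9 unless stated.
#
# Per strand the panel covers:
#  - last introns                                       -> noNMD_last
#  - a non-coding transcript                            -> noNMD_utr_or_noncoding
#  - an intron upstream of the CDS (5' UTR)             -> noNMD_utr_or_noncoding
#  - an intron downstream of the CDS (3' UTR)           -> noNMD_utr_or_noncoding
#  - frame-preserving stop-free introns (30, 99 nt)     -> noNMD_orf_preserving
#  - planted in-frame TAA at retained-mRNA position 81..84 with the last
#    exon-exon junction at 60+30+e2: e2 = 90 -> distance 96, e2 = 45 ->
#    distance 51 (both NMD); e2 = 44 -> 50, e2 = 24 -> 30 (both not NMD,
#    frame intact but stop inside the intron -> frameshift_no_nmd)
#  - frameshifting stop-free introns (100 nt)           -> frameshift_no_nmd
build_nmd_panel <- function(strands = c("+", "-")) {
  cases <- list()
  add <- function(segments, expected, utr5 = 9L, cds_len = "auto") {
    for (st in strands) {
      toy <- toy_gene(segments, utr5 = utr5, cds_len = cds_len, strand = st,
                      transcript_id = sprintf("t%02d%s", length(cases) + 1L, st))
      cases[[length(cases) + 1L]] <<- list(toy = toy, expected = expected)
    }
  }
  e <- filler
  # single-intron gene: its only intron is the last one
  add(c(e(60), toy_intron(30), e(60)), c("noNMD_last"))
  # non-coding transcript
  add(c(e(60), toy_intron(30), e(60), toy_intron(33), e(60)),
      c("noNMD_utr_or_noncoding", "noNMD_last"), cds_len = NULL)
  # CDS starts in exon 2: intron 1 sits in the 5' UTR
  add(c(e(60), toy_intron(30), e(60), toy_intron(33), e(60)),
      c("noNMD_utr_or_noncoding", "noNMD_last"), utr5 = 70L)
  # CDS ends in exon 2 (cds 9..69): intron 2 sits in the 3' UTR; intron 1 is
  # frame-preserving and stop-free
  add(c(e(60), toy_intron(30), e(30), toy_intron(33), e(30), toy_intron(36),
        e(60)),
      c("noNMD_orf_preserving", "noNMD_utr_or_noncoding", "noNMD_last"),
      cds_len = 60L)
  # TAA at intron offset 21 -> retained-mRNA 81..84 (in frame: (81-9) %% 3 == 0);
  # last junction at 90 + e2
  add(c(e(60), toy_intron(30, stop_at = 21L), e(90), toy_intron(33), e(60)),
      c("NMD", "noNMD_last"))                               # distance 96
  add(c(e(60), toy_intron(30, stop_at = 21L), e(45), toy_intron(33), e(60)),
      c("NMD", "noNMD_last"))                               # distance 51
  add(c(e(60), toy_intron(30, stop_at = 21L), e(44), toy_intron(33), e(60)),
      c("frameshift_no_nmd", "noNMD_last"))                 # distance 50
  add(c(e(60), toy_intron(30, stop_at = 21L), e(24), toy_intron(33), e(60)),
      c("frameshift_no_nmd", "noNMD_last"))                 # distance 30
  # 99-nt stop-free intron preserves the ORF
  add(c(e(60), toy_intron(99), e(90), toy_intron(33), e(60)),
      c("noNMD_orf_preserving", "noNMD_last"))
  # 100-nt stop-free intron shifts the frame without creating a stop
  add(c(e(60), toy_intron(100), e(90), toy_intron(33), e(60)),
      c("frameshift_no_nmd", "noNMD_last"))
  cases
}

nmd_panel_results <- function(cases, ptc_distance = 50L) {
  do.call(rbind, lapply(cases, function(cs) {
    catal <- toy_catalog(cs$toy)
    models <- stats::setNames(list(cs$toy$model), cs$toy$model$transcript_id)
    got <- predict_nmd(catal, models, cs$toy$genome,
                       ptc_distance = ptc_distance)
    data.frame(intron_id = catal$intron_id, ordinal = catal$ordinal,
               strand = catal$strand,
               expected = cs$expected[catal$ordinal], got = got,
               stringsAsFactors = FALSE)
  }))
}

# Differential-expression fixture: every sample column carries the same value
# multiset, so quantile normalization is the identity and per-gene fold
# changes are exactly the planted swaps. Planted pattern (mutant/sibling):
#   g1  (2, 2, 1.5)                -> up
#   g2  (0.5, 0.5, 1)              -> unaffected (direction not in all pairs)
#   g3  (1, 1, 2/3)                -> unaffected
#   g4  (2, 2, 1)                  -> unaffected (1.5-fold not in all pairs)
#   g5  (0.5, 0.5, 0.625)          -> down
#   g6  (1, 1, 1.6)                -> unaffected
#   g7  (2.2, 2.2, 2.2)            -> up
#   g8  (1/2.2 x3)                 -> down
#   g9  (2, 2, 2) but < 50 reads   -> unaffected (read filter)
#   g10 (0.5 x3) but < 50 reads    -> unaffected (read filter)
#   g11 cRPKM 1.5 everywhere       -> unaffected (expression filter)
#   g12 (1, 1, 1)                  -> unaffected
de_fixture <- function() {
  v <- c(g1 = 10, g2 = 20, g3 = 15, g4 = 40, g5 = 80, g6 = 50,
         g7 = 100, g8 = 220, g9 = 200, g10 = 400, g11 = 1.5, g12 = 650)
  swap <- function(x, i, j) { x[c(i, j)] <- x[c(j, i)]; x }
  sib <- v
  mut12 <- swap(swap(swap(swap(v, "g1", "g2"), "g4", "g5"), "g7", "g8"),
                "g9", "g10")
  mut3 <- swap(swap(swap(swap(v, "g1", "g3"), "g5", "g6"), "g7", "g8"),
               "g9", "g10")
  crpkm <- cbind(s1 = sib, m1 = mut12, s2 = sib, m2 = mut12,
                 s3 = sib, m3 = mut3)
  counts <- matrix(1000, 12, 6, dimnames = dimnames(crpkm))
  counts[c("g9", "g10"), ] <- 30
  meta <- data.frame(sample_id = colnames(crpkm),
                     condition = rep(c("sibling", "mutant"), 3),
                     pair_id = rep(c("p1", "p2", "p3"), each = 2))
  list(crpkm = crpkm, counts = counts, metadata = meta)
}

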
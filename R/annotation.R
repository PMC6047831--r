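#' Construct a transcript model
#'
#' A transcript model holds one reference transcript: its exon structure on
#' genomic coordinates and, when the transcript is coding, the genomic span of
#' the CDS. All internal coordinates are 0-based half-open; GTF input/output
#' converts from/to the 1-based closed convention at the file boundary.
#'
#' @param transcript_id,gene_id identifiers
#' @param chrom chromosome name
#' @param strand "+" or "-"
#' @param exons two-column matrix (start, end) of exon intervals, 0-based
#'   half-open, in ascending genomic order, non-overlapping
#' @param cds length-2 vector (start, end) of the genomic CDS span including
#'   the termination codon, or `NULL` for non-coding transcripts
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stopf("transcript %s has no exons", transcript_id)
  if (any(exons[, 2] <= exons[, 1]))
    stopf("malformed annotation: empty exon in transcript %s", transcript_id)
  if (nrow(exons) > 1L) {
    if (any(diff(exons[, 1]) <= 0) || any(exons[-1, 1] < exons[-nrow(exons), 2]))
      stopf("malformed annotation: exons out of order or overlapping in transcript %s",
            transcript_id)
  }
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (cds[1] < exons[1, 1] || cds[2] > exons[nrow(exons), 2] || cds[2] <= cds[1])
      stopf("malformed annotation: CDS outside exon span in transcript %s",
            transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s %d exon(s)%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              if (is.null(x$cds)) ", non-coding" else
                sprintf(", CDS %d-%d", x$cds[1], x$cds[2])))
  invisible(x)
}

#' Read reference transcript models from a GTF file
#'
#' Parses an Ensembl-dialect GTF and assembles one `transcript_model` per
#' transcript from its `exon` and `CDS` features. When `reference_transcripts`
#' is given (one transcript id per gene, mirroring a BioMart-style export) only
#' those transcripts are kept; no internal longest-isoform heuristic is
#' applied.
#'
#' @param path GTF file path
#' @param reference_transcripts optional character vector of transcript ids to
#'   retain
#' @return named list of `transcript_model` objects
#' @export
read_gtf_models <- function(path, reference_transcripts = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  keep <- df$type %in% c("exon", "CDS")
  df <- df[keep, , drop = FALSE]
  if (!is.null(reference_transcripts))
    df <- df[df$transcript_id %in% reference_transcripts, , drop = FALSE]
  out <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds_rows <- sub[sub$type == "CDS", , drop = FALSE]
    cds <- if (nrow(cds_rows)) c(min(cds_rows$start) - 1L, max(cds_rows$end))
           else NULL
    out[[tid]] <- transcript_model(
      transcript_id = tid, gene_id = ex$gene_id[1], chrom = ex$seqnames[1],
      strand = ex$strand[1],
      exons = cbind(ex$start - 1L, ex$end), cds = cds)
  }
  out
}

#' Genomic span of each gene
#'
#' @param models list of `transcript_model`
#' @return data.frame with gene_id, chrom, strand, start, end
#' @export
gene_spans <- function(models) {
  gid <- vapply(models, `[[`, "", "gene_id")
  out <- do.call(rbind, lapply(split(models, gid), function(ms) {
    ex <- do.call(rbind, lapply(ms, `[[`, "exons"))
    data.frame(gene_id = ms[[1]]$gene_id, chrom = ms[[1]]$chrom,
               strand = ms[[1]]$strand, start = min(ex[, 1]),
               end = max(ex[, 2]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build the valid intron catalog
#'
#' Enumerates the introns of every reference transcript and removes any intron
#' whose genomic interval overlaps (by at least 1 bp) the span of a different
#' gene. By default the overlap test ignores strand, since nested or
#' overlapping genes on either strand compromise intronic read assignment;
#' set `strand_aware = TRUE` to only consider same-strand genes.
#'
#' @param models list of `transcript_model` (one reference transcript per gene)
#' @param spans optional gene span table as from [gene_spans()]
#' @param strand_aware consider only same-strand gene overlaps
#' @return data.frame of class `intron_catalog`, one row per intron, with the
#'   number of removed introns in `attr(, "n_removed_overlapping")`
#' @export
build_intron_catalog <- function(models, spans = NULL, strand_aware = FALSE) {
  if (is.null(spans)) spans <- gene_spans(models)
  rows <- lapply(models, function(tx) {
    n_ex <- nrow(tx$exons)
    if (n_ex < 2L) return(NULL)
    n <- n_ex - 1L
    ist <- tx$exons[-n_ex, 2]
    ien <- tx$exons[-1, 1]
    if (any(ien - ist < 1L))
      stopf("malformed annotation: zero-length intron in transcript %s",
            tx$transcript_id)
    gidx <- seq_len(n)                       # genomic order
    ord <- if (tx$strand == "+") gidx else rev(gidx)
    data.frame(
      intron_id = sprintf("%s.i%d", tx$transcript_id, ord),
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      chrom = tx$chrom, strand = tx$strand,
      start = ist, end = ien, ordinal = ord, n_introns = n,
      up_exon_start = if (tx$strand == "+") tx$exons[-n_ex, 1] else tx$exons[-1, 1],
      up_exon_end   = if (tx$strand == "+") tx$exons[-n_ex, 2] else tx$exons[-1, 2],
      down_exon_start = if (tx$strand == "+") tx$exons[-1, 1] else tx$exons[-n_ex, 1],
      down_exon_end   = if (tx$strand == "+") tx$exons[-1, 2] else tx$exons[-n_ex, 2],
      stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, rows)
  if (is.null(cat))
    cat <- data.frame(intron_id = character(), transcript_id = character(),
                      gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      ordinal = integer(), n_introns = integer(),
                      up_exon_start = integer(), up_exon_end = integer(),
                      down_exon_start = integer(), down_exon_end = integer(),
                      stringsAsFactors = FALSE)
  rownames(cat) <- NULL
  # remove introns overlapping any other gene's span
  drop <- rep(FALSE, nrow(cat))
  for (j in seq_len(nrow(spans))) {
    hit <- cat$gene_id != spans$gene_id[j] &
      cat$chrom == spans$chrom[j] &
      cat$start < spans$end[j] & cat$end > spans$start[j]
    if (strand_aware) hit <- hit & cat$strand == spans$strand[j]
    drop <- drop | hit
  }
  out <- cat[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out$position_class <- classify_position(out$ordinal, out$n_introns)
  attr(out, "n_removed_overlapping") <- sum(drop)
  class(out) <- c("intron_catalog", "data.frame")
  out
}

#' Classify intron position along the transcript
#'
#' Position classes follow the transcript 5'->3' ordinal: `last` is the final
#' intron, `last_three` the final three (excluding the last itself, which keeps
#' its own label), `first_two` the first two, and `internal` everything else,
#' i.e. all introns excluding the first two and the last three. For transcripts
#' short enough that the windows overlap, precedence is
#' last > last_three > first_two.
#'
#' @param ordinal 1-based intron index, 5'->3'
#' @param n_introns number of introns in the transcript
#' @return character vector of position classes
#' @export
classify_position <- function(ordinal, n_introns) {
  if (any(n_introns < 1L)) stopf("transcript has no introns")
  if (any(ordinal < 1L | ordinal > n_introns)) stopf("ordinal out of range")
  ifelse(ordinal == n_introns, "last",
    ifelse(ordinal >= n_introns - 2L, "last_three",
      ifelse(ordinal <= 2L, "first_two", "internal")))
}

## sequence helpers -----------------------------------------------------------

fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Extract intron sequences (transcript orientation)
#'
#' @param catalog an `intron_catalog`
#' @param genome a named `DNAStringSet`
#' @return character vector of sequences, named by intron_id
#' @export
intron_sequences <- function(catalog, genome) {
  vapply(seq_len(nrow(catalog)), function(i)
    fetch_seq(genome, catalog$chrom[i], catalog$start[i], catalog$end[i],
              catalog$strand[i]), "")
}

## NMD prediction -------------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Predict the NMD consequence of retaining each intron
#'
#' For each catalogued intron the single-intron-retained isoform is built (all
#' other introns spliced out) and translated from the annotated start codon.
#' Following the 50-nt rule, retention is predicted to trigger NMD when the
#' first in-frame termination codon at or after the retained intron lies more
#' than `ptc_distance` nucleotides upstream of the last exon-exon junction of
#' the retained isoform. Last introns cannot trigger NMD by definition;
#' introns of non-coding transcripts or lying entirely within a UTR are
#' likewise non-triggering. Frame-preserving introns (length a multiple of
#' three) containing no in-frame stop leave the ORF intact. Remaining cases
#' disrupt the reading frame (or introduce a stop) without meeting the NMD
#' rule. Introns straddling the stop codon are treated as coding-region
#' introns.
#'
#' @param catalog an `intron_catalog`
#' @param models named list of `transcript_model`
#' @param genome named `DNAStringSet`
#' @param ptc_distance minimum distance (nt) between a premature stop and the
#'   last exon-exon junction required to trigger NMD (default 50)
#' @return character vector of classes: `NMD`, `noNMD_last`,
#'   `noNMD_utr_or_noncoding`, `noNMD_orf_preserving`, `frameshift_no_nmd`
#' @export
predict_nmd <- function(catalog, models, genome, ptc_distance = 50L) {
  vapply(seq_len(nrow(catalog)), function(i) {
    predict_nmd_one(catalog[i, ], models[[catalog$transcript_id[i]]], genome,
                    ptc_distance)
  }, "")
}

predict_nmd_one <- function(rec, tx, genome, ptc_distance) {
  if (is.null(tx)) stopf("no transcript model for %s", rec$transcript_id)
  n <- rec$n_introns
  if (rec$ordinal == n) return("noNMD_last")
  if (is.null(tx$cds)) return("noNMD_utr_or_noncoding")
  cs <- tx$cds[1]; ce <- tx$cds[2]
  if (rec$end <= cs || rec$start >= ce) return("noNMD_utr_or_noncoding")

  # reference spliced CDS length must be a multiple of three
  ov <- pmax(0L, pmin(tx$exons[, 2], ce) - pmax(tx$exons[, 1], cs))
  if (sum(ov) %% 3L != 0L)
    stopf("malformed CDS in transcript %s: spliced CDS length %d not a multiple of 3",
          tx$transcript_id, sum(ov))

  # retained isoform: merge the two exons flanking this intron
  gi <- if (tx$strand == "+") rec$ordinal else n - rec$ordinal + 1L
  ex <- tx$exons
  merged <- c(ex[gi, 1], ex[gi + 1L, 2])
  exR <- rbind(if (gi > 1L) ex[seq_len(gi - 1L), , drop = FALSE],
               matrix(merged, ncol = 2),
               if (gi + 1L < nrow(ex)) ex[seq(gi + 2L, nrow(ex)), , drop = FALSE])

  ord_rows <- if (tx$strand == "+") seq_len(nrow(exR)) else rev(seq_len(nrow(exR)))
  seqs <- vapply(ord_rows, function(j)
    fetch_seq(genome, tx$chrom, exR[j, 1], exR[j, 2], tx$strand), "")
  mrna <- paste(seqs, collapse = "")
  lens <- nchar(seqs)
  junctions <- cumsum(lens)[-length(lens)]      # nt upstream of each junction
  last_junction <- max(junctions)

  # transcript coordinate (0-based) of a genomic position
  tx_coord <- function(gpos) {
    off <- 0L
    for (j in ord_rows) {
      w <- exR[j, 2] - exR[j, 1]
      if (gpos >= exR[j, 1] && gpos < exR[j, 2]) {
        within <- if (tx$strand == "+") gpos - exR[j, 1] else exR[j, 2] - 1L - gpos
        return(off + within)
      }
      off <- off + w
    }
    stopf("position %d not exonic in retained isoform of %s", gpos,
          tx$transcript_id)
  }
  start_pos <- tx_coord(if (tx$strand == "+") cs else ce - 1L)

  # intron span in retained-isoform coordinates (transcript orientation)
  intron_5p <- tx_coord(if (tx$strand == "+") rec$start else rec$end - 1L)
  intron_len <- rec$end - rec$start
  intron_3p_excl <- intron_5p + intron_len

  # scan codons from the annotated start
  cds_seq <- substring(mrna, start_pos + 1L, nchar(mrna))
  n_codon <- nchar(cds_seq) %/% 3L
  stop_rel <- NA_integer_
  if (n_codon > 0L) {
    starts <- start_pos + 3L * (seq_len(n_codon) - 1L)
    codons <- substring(mrna, starts + 1L, starts + 3L)
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit)) stop_rel <- hit[1]
  }
  frame_ok <- intron_len %% 3L == 0L
  if (is.na(stop_rel)) {
    return(if (frame_ok) "noNMD_orf_preserving" else "frameshift_no_nmd")
  }
  stop_start <- start_pos + 3L * (stop_rel - 1L)
  stop_end <- stop_start + 3L
  stop_in_intron <- stop_start < intron_3p_excl && stop_end > intron_5p
  if (last_junction - stop_end > ptc_distance) return("NMD")
  if (frame_ok && !stop_in_intron) return("noNMD_orf_preserving")
  "frameshift_no_nmd"
}

#' Write an intron catalog as a BED-like TSV
#'
#' @param catalog an `intron_catalog` (with optional `nmd_class` column)
#' @param path output path
#' @param meta optional metadata written as "#key=value" lines
#' @export
write_intron_catalog <- function(catalog, path, meta = NULL) {
  cols <- c("chrom", "start", "end", "intron_id", "ordinal", "strand",
            "transcript_id", "position_class",
            intersect("nmd_class", names(catalog)))
  meta <- c(list(n_removed_overlapping =
                   attr(catalog, "n_removed_overlapping") %||% NA), meta)
  write_tsv(as.data.frame(catalog)[, cols], path, meta = meta)
}
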
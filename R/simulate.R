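#' Simulation configuration
#'
#' Returns the configuration of the synthetic retention experiment: a
#' multi-gene genome with CDS-bearing transcripts, three mutant/sibling
#' pairs, and introns whose retention increase in mutants follows a logistic
#' function of their sequence features. The defaults emulate the statistical
#' structure expected of factor-dependent introns: they are short (length
#' median 281 nt vs 749 nt for controls), GC-rich (mean 0.55 vs 0.38),
#' flanked by exons of lower GC content, and carry weak branch points. The
#' three pairs use different effect attenuations so the "2 of 3 mutants"
#' calling rule is non-degenerate. Count noise is Poisson by default;
#' `dispersion` switches junction counts to negative binomial.
#'
#' @param n_genes number of genes
#' @param introns_per_gene integer vector sampled from per gene
#' @param p_dependent probability an intron is of the dependent class
#' @param dep_length_meanlog,dep_length_sdlog,ctr_length_meanlog,ctr_length_sdlog
#'   log-normal intron length parameters per class
#' @param dep_gc,ctr_gc mean intron GC per class (sd 0.05)
#' @param dep_flank_gc,ctr_flank_gc mean flanking-exon GC per class (sd 0.04)
#' @param p_weak_bp_dep,p_weak_bp_ctr probability of a weak/absent branch
#'   point per class
#' @param beta0,beta,delta_max,noise_sd retention model: the retention
#'   increase is `delta_max * attenuation * plogis(beta0 + beta' z + eps)`
#'   with `z` the cohort-standardized features (intron_gc, log_length,
#'   flank_gc, bp_strength) and `eps ~ N(0, noise_sd)`
#' @param attenuation per-pair effect attenuation (length = n_pairs)
#' @param baseline_pir_range sibling PIR drawn uniformly from this range (%)
#' @param junction_depth expected junction reads per intron at unit
#'   expression
#' @param coverage_depth expected intron-body reads per position at unit
#'   expression and full retention
#' @param hotspot_rate,hotspot_fold rate and fold of planted single-position
#'   coverage hotspots (exercises the capping rule)
#' @param low_coverage_rate,low_coverage_factor fraction of introns with
#'   strongly reduced junction-read efficiency (emulating the bulk of introns
#'   that fail the read-coverage filter and form the prediction cohort), and
#'   the depth multiplier applied to them
#' @param repeat_rate,repeat_length fraction of introns with a verbatim
#'   repeat copy planted elsewhere in the genome, and its length
#' @param de_fraction fraction of genes with a planted expression fold change
#' @param dispersion negative-binomial size for junction counts
#'   (`Inf` = Poisson)
#' @param n_pairs number of mutant/sibling pairs
#' @return list of class `ir_sim_config`
#' @export
ir_sim_config <- function(n_genes = 500L, introns_per_gene = 3:6,
                          p_dependent = 0.15,
                          dep_length_meanlog = log(281), dep_length_sdlog = 0.35,
                          ctr_length_meanlog = log(749), ctr_length_sdlog = 0.5,
                          dep_gc = 0.55, ctr_gc = 0.38,
                          dep_flank_gc = 0.40, ctr_flank_gc = 0.48,
                          p_weak_bp_dep = 0.8, p_weak_bp_ctr = 0.1,
                          beta0 = -4.3,
                          beta = c(intron_gc = 1.8, log_length = -1.5,
                                   flank_gc = -1.2, bp_strength = -0.9),
                          delta_max = 45, noise_sd = 0.4,
                          attenuation = c(1, 0.9, 0.75),
                          baseline_pir_range = c(0.2, 2),
                          junction_depth = 2000, coverage_depth = 25,
                          low_coverage_rate = 0.1, low_coverage_factor = 0.001,
                          hotspot_rate = 0.02, hotspot_fold = 30,
                          repeat_rate = 0, repeat_length = 80L,
                          de_fraction = 0.06, dispersion = Inf,
                          n_pairs = 3L) {
  cfg <- as.list(environment())
  stopifnot(cfg$junction_depth > 0, cfg$coverage_depth > 0,
            cfg$p_dependent >= 0, cfg$p_dependent <= 1,
            all(is.finite(cfg$beta)), length(cfg$attenuation) == cfg$n_pairs)
  if (any(exp(c(dep_length_meanlog, ctr_length_meanlog)) < 70))
    stopf("infeasible length configuration: median intron length below 70 nt")
  class(cfg) <- "ir_sim_config"
  cfg
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# stop-free CDS body of length n (multiple of 3) plus TAA terminator
rand_cds <- function(n, gc = 0.45) {
  body <- rand_seq(n - 3L, gc)
  starts <- seq(1L, n - 3L, by = 3L)
  if (length(starts)) {
    codons <- substring(body, starts, starts + 2L)
    bad <- codons %in% STOP_CODONS
    if (any(bad)) {
      codons[bad] <- sub("^T", "C", codons[bad])
      body <- paste(codons, collapse = "")
    }
  }
  paste0(body, "TAA")
}

plant_str <- function(seq, s, insert) {
  # overwrite positions s..s+nchar(insert)-1 (1-based)
  paste0(substring(seq, 1L, s - 1L), insert,
         substring(seq, s + nchar(insert), nchar(seq)))
}

make_intron_seq <- function(len, gc, weak_bp) {
  s <- rand_seq(len, gc)
  s <- plant_str(s, 1L, "GT")
  s <- plant_str(s, len - 1L, "AG")
  bp_dist <- sample(18:40, 1L)
  # polypyrimidine tract between branch point and the 3' splice site
  ppt_len <- min(bp_dist - 3L, len - 10L)
  if (ppt_len > 4L) {
    py_frac <- if (weak_bp) 0.55 else 0.85
    ppt <- paste(sample(c("C", "T", "A", "G"), ppt_len, replace = TRUE,
                        prob = c(py_frac / 2, py_frac / 2,
                                 (1 - py_frac) / 2, (1 - py_frac) / 2)),
                 collapse = "")
    s <- plant_str(s, len - 2L - ppt_len, ppt)
  }
  hept <- if (weak_bp) "TTCTAAT" else "TACTAAC"
  plant <- !weak_bp || stats::runif(1) < 0.5   # weak introns often lack a BP
  if (plant && len >= bp_dist + 12L)
    s <- plant_str(s, len - bp_dist - 5L, hept)
  s
}

map_spliced_to_genomic <- function(exons, strand, pos) {
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  off <- 0L
  for (j in ord) {
    w <- exons[j, 2] - exons[j, 1]
    if (pos < off + w) {
      within <- pos - off
      return(if (strand == "+") exons[j, 1] + within
             else exons[j, 2] - 1L - within)
    }
    off <- off + w
  }
  stopf("spliced position %d beyond transcript", pos)
}

#' Generate a synthetic genome, annotation and ground-truth features
#'
#' Builds a multi-gene single-chromosome genome whose introns are drawn from
#' class-specific length/GC/branch-point distributions (see
#' [ir_sim_config()]), with CDS-bearing transcripts on both strands,
#' optional verbatim repeat insertions, and a ground-truth table of the
#' per-intron generative features. Deterministic given the seed.
#'
#' @param cfg an `ir_sim_config`
#' @param seed RNG seed
#' @return list with genome (`DNAStringSet`), models (list of
#'   `transcript_model`), truth (data.frame), gene_expr (data.frame)
#' @export
generate_genome_and_annotation <- function(cfg = ir_sim_config(), seed = 1L) {
  set.seed(seed)
  chrom_parts <- character(0)
  offset <- 0L
  models <- list()
  truth <- list()
  repeat_bank <- character(0)
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("g%04d", g)
    tid <- sprintf("t%04d", g)
    strand <- sample(c("+", "-"), 1L)
    n_int <- if (length(cfg$introns_per_gene) > 1L)
      sample(cfg$introns_per_gene, 1L) else cfg$introns_per_gene
    n_ex <- n_int + 1L
    dep <- stats::runif(n_int) < cfg$p_dependent
    ilen <- ifelse(dep,
                   stats::rlnorm(n_int, cfg$dep_length_meanlog, cfg$dep_length_sdlog),
                   stats::rlnorm(n_int, cfg$ctr_length_meanlog, cfg$ctr_length_sdlog))
    ilen <- as.integer(pmin(pmax(round(ilen), 70L), 4000L))
    igc_t <- pmin(pmax(stats::rnorm(n_int, ifelse(dep, cfg$dep_gc, cfg$ctr_gc),
                                    0.05), 0.2), 0.75)
    fgc_t <- pmin(pmax(stats::rnorm(n_int,
                                    ifelse(dep, cfg$dep_flank_gc,
                                           cfg$ctr_flank_gc), 0.04),
                       0.3), 0.65)
    weak_bp <- stats::runif(n_int) <
      ifelse(dep, cfg$p_weak_bp_dep, cfg$p_weak_bp_ctr)
    # exon GC targets from adjacent intron flank targets
    exon_gc <- vapply(seq_len(n_ex), function(e) {
      adj <- fgc_t[stats::na.omit(c(if (e > 1L) e - 1L, if (e <= n_int) e))]
      mean(adj)
    }, 0)
    exlen <- as.integer(round(stats::runif(n_ex, 100, 250)))
    tx_len <- sum(exlen)
    utr5 <- as.integer(round(stats::runif(1, 40, 80)))
    cds_len <- 3L * ((tx_len - utr5 - 80L) %/% 3L)
    utr3 <- tx_len - utr5 - cds_len
    tx_seq <- paste0(rand_seq(utr5, exon_gc[1]),
                     rand_cds(cds_len, mean(exon_gc)),
                     rand_seq(utr3, exon_gc[n_ex]))
    exon_seqs <- substring(tx_seq, cumsum(c(1L, exlen[-n_ex])),
                           cumsum(exlen))
    intron_seqs <- vapply(seq_len(n_int), function(i)
      make_intron_seq(ilen[i], igc_t[i], weak_bp[i]), "")
    # interleave exons and introns (transcript orientation)
    parts <- character(2L * n_ex - 1L)
    parts[seq(1L, by = 2L, length.out = n_ex)] <- exon_seqs
    parts[seq(2L, by = 2L, length.out = n_int)] <- intron_seqs
    gene_seq <- paste(parts, collapse = "")
    glen <- nchar(gene_seq)
    # exon intervals within the gene (transcript orientation, 0-based)
    seg_ends <- cumsum(nchar(parts))
    seg_starts <- c(0L, seg_ends[-length(seg_ends)])
    ex_idx <- seq(1L, by = 2L, length.out = n_ex)
    ex_t <- cbind(seg_starts[ex_idx], seg_ends[ex_idx])
    spacer <- rand_seq(as.integer(round(stats::runif(1, 200, 400))), 0.4)
    gene_offset <- offset + nchar(spacer)
    if (strand == "+") {
      exons <- gene_offset + ex_t
      genomic_gene_seq <- gene_seq
    } else {
      exons <- gene_offset + cbind(glen - ex_t[, 2], glen - ex_t[, 1])
      exons <- exons[rev(seq_len(n_ex)), , drop = FALSE]
      genomic_gene_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_seq)))
    }
    cds_g <- sort(c(map_spliced_to_genomic(exons, strand, utr5),
                    map_spliced_to_genomic(exons, strand,
                                           utr5 + cds_len - 1L)))
    models[[tid]] <- transcript_model(tid, gid, "chr1", strand, exons,
                                      cds = c(cds_g[1], cds_g[2] + 1L))
    chrom_parts <- c(chrom_parts, spacer, genomic_gene_seq)
    offset <- gene_offset + glen
    ord <- seq_len(n_int)
    truth[[g]] <- data.frame(
      intron_id = sprintf("%s.i%d", tid, ord),
      gene_id = gid, transcript_id = tid,
      dependent = dep, intron_gc = gc_content(intron_seqs),
      log_length = log10(ilen), flank_gc = (exon_gc[ord] + exon_gc[ord + 1L]) / 2,
      bp_strength = as.numeric(!weak_bp), intron_length = ilen,
      stringsAsFactors = FALSE)
    if (cfg$repeat_rate > 0) {
      take <- which(stats::runif(n_int) < cfg$repeat_rate &
                      ilen >= cfg$repeat_length + 20L)
      for (i in take)
        repeat_bank <- c(repeat_bank,
                         substring(intron_seqs[i], 10L,
                                   9L + cfg$repeat_length))
    }
  }
  if (length(repeat_bank))
    chrom_parts <- c(chrom_parts,
                     paste(vapply(repeat_bank, function(s)
                       paste0(rand_seq(60L, 0.4), s), ""), collapse = ""))
  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- "chr1"
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  gene_expr <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    expr = stats::rlnorm(cfg$n_genes, log(30), 1),
    de = sample(c("up", "down", "none"), cfg$n_genes, replace = TRUE,
                prob = c(cfg$de_fraction / 2, cfg$de_fraction / 2,
                         1 - cfg$de_fraction)),
    stringsAsFactors = FALSE)
  gene_expr$fc <- ifelse(gene_expr$de == "none", 1,
                         stats::runif(cfg$n_genes, 2.2, 3.5))
  gene_expr$fc[gene_expr$de == "down"] <- 1 / gene_expr$fc[gene_expr$de == "down"]
  list(genome = genome, models = models, truth = truth, gene_expr = gene_expr)
}

#' Simulate true per-sample retention from features
#'
#' Sibling PIR is drawn from the baseline distribution; the mutant retention
#' increase is `delta_max * attenuation_p * plogis(beta0 + beta' z + eps)`
#' with `z` the cohort-standardized generative features, truncated so PIR
#' stays in [0, 100].
#'
#' @param features data.frame with columns intron_gc, log_length, flank_gc,
#'   bp_strength
#' @param cfg an `ir_sim_config`
#' @return list with true_pir (matrix introns x samples, columns
#'   sib_p*/mut_p*), true_delta (matrix introns x pairs), baseline
#' @export
simulate_true_retention <- function(features, cfg = ir_sim_config()) {
  z <- scale(as.matrix(features[, names(cfg$beta), drop = FALSE]))
  z[is.nan(z)] <- 0
  n <- nrow(z)
  base <- stats::runif(n, cfg$baseline_pir_range[1], cfg$baseline_pir_range[2])
  true_pir <- matrix(0, n, 2L * cfg$n_pairs)
  colnames(true_pir) <- as.vector(rbind(paste0("sib_p", seq_len(cfg$n_pairs)),
                                        paste0("mut_p", seq_len(cfg$n_pairs))))
  true_delta <- matrix(0, n, cfg$n_pairs,
                       dimnames = list(NULL, paste0("p", seq_len(cfg$n_pairs))))
  eta0 <- cfg$beta0 + drop(z %*% cfg$beta)
  for (p in seq_len(cfg$n_pairs)) {
    eta <- eta0 + stats::rnorm(n, 0, cfg$noise_sd)
    delta <- cfg$delta_max * cfg$attenuation[p] * stats::plogis(eta)
    mut <- pmin(100, base + delta)
    true_pir[, paste0("sib_p", p)] <- base
    true_pir[, paste0("mut_p", p)] <- mut
    true_delta[, p] <- mut - base
  }
  list(true_pir = true_pir, true_delta = true_delta, baseline = base)
}

rcount <- function(n, mu, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, mu)
  else stats::rnbinom(n, size = dispersion, mu = mu)
}

#' Simulate junction counts, coverage profiles and expression counts
#'
#' Junction reads are drawn with the exon-intron mean structure implied by
#' the true retention fraction rho: both exon-intron junctions at rate
#' `depth * rho` and the pooled exon-exon junctions at `depth * (1 - rho)`,
#' so the PIR estimator is unbiased for rho. Intron-body coverage is
#' per-position Poisson at a rate proportional to expression and retention,
#' with occasional planted hotspots to exercise the capping rule. Gene-level
#' exonic counts carry the planted expression fold changes.
#'
#' @param sim output of [generate_genome_and_annotation()]
#' @param retention output of [simulate_true_retention()]
#' @param cfg an `ir_sim_config`
#' @param seed RNG seed
#' @return list with junctions (data.frame), coverage (named list of
#'   position x sample integer matrices), metadata, expr_counts (gene x
#'   sample matrix), tx_len (named, spliced transcript lengths)
#' @export
simulate_counts <- function(sim, retention, cfg = ir_sim_config(), seed = 1L) {
  set.seed(seed)
  truth <- sim$truth
  n <- nrow(truth)
  pairs <- paste0("p", seq_len(cfg$n_pairs))
  samples <- as.vector(rbind(paste0("sib_", pairs), paste0("mut_", pairs)))
  metadata <- data.frame(
    sample_id = samples,
    condition = rep(c("sibling", "mutant"), cfg$n_pairs),
    pair_id = rep(pairs, each = 2L),
    library_size = round(2e7 * stats::runif(2L * cfg$n_pairs, 0.9, 1.1)),
    stringsAsFactors = FALSE)
  expr <- sim$gene_expr$expr[match(truth$gene_id, sim$gene_expr$gene_id)]
  scale_i <- pmin(pmax(expr / 30, 0.1), 5)
  low_cov <- stats::runif(n) < cfg$low_coverage_rate
  jct_scale <- scale_i * ifelse(low_cov, cfg$low_coverage_factor, 1)
  jrows <- vector("list", length(samples))
  coverage <- stats::setNames(vector("list", n), truth$intron_id)
  ilen <- truth$intron_length
  for (i in seq_len(n)) {
    coverage[[i]] <- matrix(0L, ilen[i], length(samples),
                            dimnames = list(NULL, samples))
  }
  hot <- which(stats::runif(n) < cfg$hotspot_rate)
  hot_pos <- sapply(hot, function(i) sample(ilen[i], 1L))
  for (s in seq_along(samples)) {
    pair_i <- (s + 1L) %/% 2L
    cond <- metadata$condition[s]
    col <- paste0(ifelse(cond == "sibling", "sib_p", "mut_p"), pair_i)
    rho <- retention$true_pir[, col] / 100
    depth <- cfg$junction_depth * jct_scale
    jrows[[s]] <- data.frame(
      intron_id = truth$intron_id, sample_id = samples[s],
      ei5 = rcount(n, depth * rho, cfg$dispersion),
      ei3 = rcount(n, depth * rho, cfg$dispersion),
      ee_support = rcount(n, depth * (1 - rho), cfg$dispersion),
      stringsAsFactors = FALSE)
    rate <- cfg$coverage_depth * scale_i * (rho + 0.002)
    for (i in seq_len(n))
      coverage[[i]][, s] <- stats::rpois(ilen[i], rate[i])
    if (length(hot))
      for (k in seq_along(hot)) {
        i <- hot[k]
        coverage[[i]][hot_pos[k], s] <-
          coverage[[i]][hot_pos[k], s] +
          stats::rpois(1L, cfg$hotspot_fold * max(rate[i], 0.05))
      }
  }
  junctions <- do.call(rbind, jrows)
  rownames(junctions) <- NULL
  # gene-level exonic counts with planted fold changes
  tx_len <- vapply(sim$models, function(m) sum(m$exons[, 2] - m$exons[, 1]), 0)
  gid <- vapply(sim$models, `[[`, "", "gene_id")
  gl <- tx_len[match(sim$gene_expr$gene_id, gid)]
  expr_counts <- sapply(seq_along(samples), function(s) {
    fc <- if (metadata$condition[s] == "mutant") sim$gene_expr$fc else 1
    mu <- sim$gene_expr$expr * fc * (gl / 1000) *
      (metadata$library_size[s] / 1e6)
    stats::rpois(length(mu), mu)
  })
  dimnames(expr_counts) <- list(sim$gene_expr$gene_id, samples)
  list(junctions = junctions, coverage = coverage, metadata = metadata,
       expr_counts = expr_counts, low_coverage = low_cov,
       tx_len = stats::setNames(tx_len[match(sim$gene_expr$gene_id, gid)],
                                sim$gene_expr$gene_id))
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: genome + annotation, true retention, counts.
#'
#' @param cfg an `ir_sim_config`
#' @param seed RNG seed (drives all stages)
#' @return list combining the outputs of [generate_genome_and_annotation()],
#'   [simulate_true_retention()] and [simulate_counts()]
#' @export
simulate_ir_experiment <- function(cfg = ir_sim_config(), seed = 1L) {
  sim <- generate_genome_and_annotation(cfg, seed = seed)
  set.seed(seed + 1L)
  ret <- simulate_true_retention(sim$truth, cfg)
  # an intron is truly retained when its noise-free retention increase
  # satisfies the calling rule (consistent with the generating coefficients)
  sim$truth$retained_true <- rowSums(ret$true_delta > 15) >= 2L
  cnt <- simulate_counts(sim, ret, cfg, seed = seed + 2L)
  sim$truth$low_coverage <- cnt$low_coverage
  c(sim, ret, cnt, list(config = cfg, seed = seed))
}

#' Simulate a feature-level classifier cohort
#'
#' Draws a cohort directly at the feature level for classifier evaluation:
#' standard-normal features of which `length(beta)` are informative and
#' `n_null` carry no signal, and labels drawn from the logistic model
#' `P(dependent) = plogis(intercept + X beta)`.
#'
#' @param n cohort size (default 2000)
#' @param beta planted coefficients of the informative features (default four
#'   graded effects)
#' @param n_null number of null features (default 26)
#' @param intercept logistic intercept (default -0.5)
#' @param seed RNG seed
#' @return list with x (matrix), y (logical), beta (named true coefficients,
#'   zeros for null features)
#' @export
simulate_classifier_cohort <- function(n = 2000L,
                                       beta = c(2.0, 1.2, 0.7, 0.35),
                                       n_null = 26L, intercept = -0.5,
                                       seed = 1L) {
  set.seed(seed)
  p <- length(beta) + n_null
  x <- matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- c(sprintf("inf_%02d", seq_along(beta)),
                   sprintf("null_%02d", seq_len(n_null)))
  full_beta <- stats::setNames(c(beta, rep(0, n_null)), colnames(x))
  eta <- intercept + drop(x %*% full_beta)
  y <- stats::runif(n) < stats::plogis(eta)
  list(x = x, y = y, beta = full_beta)
}

## writers --------------------------------------------------------------------

#' Write simulated annotation as an Ensembl-dialect GTF
#'
#' @param models list of `transcript_model`
#' @param path output path
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (tx in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id,
                     tx$transcript_id)
    ex <- tx$exons
    lines <- c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom, ex[, 1] + 1L, ex[, 2], tx$strand,
                              attrs))
    if (!is.null(tx$cds)) {
      cs <- tx$cds[1]; ce <- tx$cds[2]
      ov <- cbind(pmax(ex[, 1], cs), pmin(ex[, 2], ce))
      ov <- ov[ov[, 2] > ov[, 1], , drop = FALSE]
      lines <- c(lines, sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                tx$chrom, ov[, 1] + 1L, ov[, 2], tx$strand,
                                attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated experiment to disk
#'
#' Writes FASTA (genome), GTF (annotation), junction-count TSV, coverage TSV,
#' sample metadata TSV and ground-truth TSV under `dir`.
#'
#' @param sim output of [simulate_ir_experiment()]
#' @param dir output directory (created if needed)
#' @param write_coverage write the (large) per-position coverage TSV
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir, write_coverage = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$models, file.path(dir, "annotation.gtf"))
  write_tsv(sim$junctions, file.path(dir, "junctions.tsv"))
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  truth <- cbind(sim$truth, sim$true_delta)
  write_tsv(truth, file.path(dir, "truth.tsv"))
  if (write_coverage) {
    cov <- do.call(rbind, lapply(names(sim$coverage), function(id) {
      m <- sim$coverage[[id]]
      data.frame(intron_id = id, position = rep(seq_len(nrow(m)), ncol(m)),
                 sample_id = rep(colnames(m), each = nrow(m)),
                 count = as.vector(m), stringsAsFactors = FALSE)
    }))
    write_tsv(cov, file.path(dir, "coverage.tsv"))
  }
  invisible(dir)
}
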
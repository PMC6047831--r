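#' Pipeline run configuration
#'
#' All thresholds of the analysis are explicit here, so a resolved
#' configuration dump documents every cutoff used by a run.
#'
#' @param delta_high delta-PIR cutoff for dependent calls (default 15)
#' @param delta_ctr absolute delta-PIR cutoff for control calls (default 0.5)
#' @param delta_shared relaxed per-mutant cutoff for overlaps (default 5)
#' @param density_fold net density-increase cutoff (default 1.5)
#' @param min_mutants pairs required for a dependent call (default 2)
#' @param min_hi,min_lo,min_splice junction coverage thresholds (15/10/15)
#' @param coverage_rule splicing-clause reading, "ee" or "total"
#' @param window,max_mismatch mappability window and mismatch allowance
#'   (50/2)
#' @param mappability_mode `"uniform"` treats every window as uniquely
#'   mappable (n_unique = n_segments; exact for repeat-free genomes) while
#'   `"exact"` runs the window matcher (desk-scale genomes)
#' @param ptc_distance NMD premature-stop distance rule (default 50)
#' @param bp_window branch-point scan window (default 150)
#' @param min_crpkm,min_reads expression filters (2 / 50)
#' @param fc_all,fc_two differential-expression fold cutoffs (1.5 / 2)
#' @param n_repeats,train_fraction holdout settings (200 / 0.9)
#' @param predict_k introns selected per side in the prediction stage
#' @param seed RNG seed for the model and prediction stages
#' @return list of class `ir_config`
#' @export
ir_config <- function(delta_high = 15, delta_ctr = 0.5, delta_shared = 5,
                      density_fold = 1.5, min_mutants = 2L,
                      min_hi = 15L, min_lo = 10L, min_splice = 15L,
                      coverage_rule = "ee",
                      window = 50L, max_mismatch = 2L,
                      mappability_mode = c("uniform", "exact"),
                      ptc_distance = 50L, bp_window = 150L,
                      min_crpkm = 2, min_reads = 50,
                      fc_all = 1.5, fc_two = 2,
                      n_repeats = 200L, train_fraction = 0.9,
                      predict_k = 100L, seed = 1L) {
  cfg <- as.list(environment())
  cfg$mappability_mode <- match.arg(mappability_mode)
  class(cfg) <- "ir_config"
  cfg
}

load_coverage <- function(coverage, samples) {
  if (is.list(coverage) && !is.data.frame(coverage)) return(coverage)
  out <- lapply(split(coverage, coverage$intron_id), function(d) {
    m <- matrix(0L, max(d$position), length(samples),
                dimnames = list(NULL, samples))
    m[cbind(d$position, match(d$sample_id, samples))] <- d$count
    m
  })
  out
}

#' Run the full retention-dependence pipeline
#'
#' Executes catalog construction, retention quantification,
#' coverage/expression analysis, NMD and position annotation, feature
#' extraction, set calling, dependence modelling and prediction, writing one
#' TSV per stage plus a resolved-config snapshot and per-stage record counts
#' under `out_dir`. Reruns with identical inputs and seed are byte-identical.
#'
#' @param inputs either the in-memory result of [simulate_ir_experiment()],
#'   or a named list of file paths: genome (FASTA), annotation (GTF),
#'   junctions, coverage, metadata (TSV)
#' @param out_dir output directory
#' @param config an [ir_config()]
#' @param pwms PWM list for feature extraction; defaults to the shipped
#'   synthetic matrices
#' @return invisible list of stage results
#' @export
run_ir_pipeline <- function(inputs, out_dir, config = ir_config(),
                            pwms = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  if (is.null(pwms))
    pwms <- list(donor = read_pwm(default_pwm_file("donor")),
                 acceptor = read_pwm(default_pwm_file("acceptor")),
                 branchpoint = read_pwm(default_pwm_file("branchpoint")),
                 sf1 = read_pwm(default_pwm_file("sf1")))
  counts_log <- list()
  note <- function(stage, n) counts_log[[stage]] <<- n

  # -- load ------------------------------------------------------------------
  genome <- if (is.character(inputs$genome))
    Biostrings::readDNAStringSet(inputs$genome) else inputs$genome
  if (!is.null(names(genome)))
    names(genome) <- sub("\\s.*$", "", names(genome))
  models <- if (is.character(inputs$annotation))
    read_gtf_models(inputs$annotation) else inputs$models
  junctions <- if (is.character(inputs$junctions))
    read_tsv(inputs$junctions) else inputs$junctions
  metadata <- if (is.character(inputs$metadata))
    read_tsv(inputs$metadata) else inputs$metadata
  samples <- metadata$sample_id
  pairs <- sort(unique(metadata$pair_id))
  coverage <- load_coverage(inputs$coverage, samples)

  # -- catalog ---------------------------------------------------------------
  catalog <- build_intron_catalog(models)
  catalog$nmd_class <- predict_nmd(catalog, models, genome,
                                   ptc_distance = config$ptc_distance)
  note("introns_cataloged", nrow(catalog))
  note("introns_removed_overlapping",
       attr(catalog, "n_removed_overlapping"))
  write_intron_catalog(catalog, file.path(out_dir, "catalog.tsv"))

  # -- retention -------------------------------------------------------------
  pir <- pir_table(junctions, metadata, rule = config$coverage_rule)
  note("introns_quantified", nrow(pir))
  note("introns_covered", sum(pir$covered))
  write_tsv(pir, file.path(out_dir, "pir.tsv"))

  # -- mappability & intronic density ----------------------------------------
  iseq <- intron_sequences(catalog, genome)
  names(iseq) <- catalog$intron_id
  if (config$mappability_mode == "exact") {
    mapp <- mappability_table(iseq, genome, window = config$window,
                              max_mismatch = config$max_mismatch)
  } else {
    nseg <- pmax(0L, nchar(iseq) - config$window + 1L)
    mapp <- data.frame(feature_id = names(iseq), n_segments = nseg,
                       n_multi = 0L, n_unmappable = 0L, n_unique = nseg,
                       stringsAsFactors = FALSE)
  }
  write_tsv(mapp, file.path(out_dir, "mappability.tsv"))
  libsize <- stats::setNames(metadata$library_size, samples)
  cirpkm <- matrix(NA_real_, nrow(catalog), length(samples),
                   dimnames = list(catalog$intron_id, samples))
  nu_all <- stats::setNames(mapp$n_unique[match(catalog$intron_id,
                                                mapp$feature_id)],
                            catalog$intron_id)
  for (id in catalog$intron_id) {
    cv <- coverage[[id]]
    if (is.null(cv)) next
    nu <- nu_all[[id]]
    for (s in samples)
      cirpkm[id, s] <- compute_density(sum(cap_position_counts(cv[, s])),
                                       nu, libsize[s])
  }
  density <- data.frame(intron_id = catalog$intron_id,
                        stringsAsFactors = FALSE)
  for (p in pairs) {
    mut <- metadata$sample_id[metadata$pair_id == p &
                                metadata$condition == "mutant"][1]
    sib <- metadata$sample_id[metadata$pair_id == p &
                                metadata$condition == "sibling"][1]
    pm <- pir[[paste0("pir_", mut)]][match(catalog$intron_id, pir$intron_id)]
    ps <- pir[[paste0("pir_", sib)]][match(catalog$intron_id, pir$intron_id)]
    density[[paste0("ratio_", p)]] <-
      net_density_increase(cirpkm[, mut], pm, cirpkm[, sib], ps)
  }
  write_tsv(density, file.path(out_dir, "density.tsv"))

  # -- expression ------------------------------------------------------------
  expression <- NULL
  wt_expr <- NULL
  if (!is.null(inputs$expr_counts)) {
    ec <- inputs$expr_counts
    txl <- inputs$tx_len
    nu_tx <- pmax(txl - config$window + 1L, 0L)
    crpkm <- sapply(samples, function(s)
      compute_density(ec[, s], nu_tx[rownames(ec)], libsize[s]))
    rownames(crpkm) <- rownames(ec)
    expression <- call_differential_expression(
      crpkm, ec, metadata, min_crpkm = config$min_crpkm,
      min_reads = config$min_reads, fc_all = config$fc_all,
      fc_two = config$fc_two)
    note("genes_expression_filtered", sum(!expression$passed_filter))
    note("genes_up", sum(expression$label == "up"))
    note("genes_down", sum(expression$label == "down"))
    write_tsv(expression, file.path(out_dir, "expression.tsv"))
    sib <- metadata$sample_id[metadata$condition == "sibling"]
    wt_expr <- rowMeans(crpkm[, sib, drop = FALSE])
  }

  # -- set calling -----------------------------------------------------------
  sets <- call_intron_sets(pir, density, delta_high = config$delta_high,
                           delta_ctr = config$delta_ctr,
                           delta_shared = config$delta_shared,
                           density_fold = config$density_fold,
                           min_mutants = config$min_mutants)
  note("introns_resdep", sum(sets$resdep))
  note("introns_ctr", sum(sets$ctr))
  write_tsv(sets, file.path(out_dir, "sets.tsv"))
  ov <- summarize_overlaps(sets$intron_id[sets[[paste0("dep5_", pairs[1])]]],
                           sets$intron_id[sets[[paste0("dep5_", pairs[2])]]],
                           sets$intron_id[sets[[paste0("dep5_", pairs[3])]]])
  write_tsv(data.frame(region = names(ov), count = as.integer(ov)),
            file.path(out_dir, "overlaps.tsv"))

  # -- features --------------------------------------------------------------
  features <- extract_features(catalog, genome, pwms, expression = wt_expr,
                               bp_window = config$bp_window)
  note("introns_with_features", nrow(features))
  write_tsv(features, file.path(out_dir, "features.tsv"))

  # -- dependence model ------------------------------------------------------
  fit <- NULL
  feat_cols <- setdiff(names(features), "intron_id")
  lab <- sets[match(features$intron_id, sets$intron_id), ]
  model_rows <- which(lab$resdep | lab$ctr)
  n_pos <- sum(lab$resdep, na.rm = TRUE)
  n_neg <- sum(lab$ctr, na.rm = TRUE)
  if (n_pos >= 20L && n_neg >= n_pos) {
    x <- as.matrix(features[model_rows, feat_cols])
    y <- lab$resdep[model_rows]
    fit <- ir_dependence(x, y, n_repeats = config$n_repeats,
                         train_fraction = config$train_fraction,
                         seed = config$seed)
    write_tsv(data.frame(feature = names(coef(fit)),
                         mean_coefficient = unname(coef(fit)),
                         selection_freq = c(NA, unname(fit$selection_freq))),
              file.path(out_dir, "coefficients.tsv"),
              meta = list(mean_auc = fit$mean_auc, auc_ci = fit$auc_ci))
    write_tsv(fit$mean_roc, file.path(out_dir, "roc.tsv"))
    note("model_mean_auc", round(fit$mean_auc, 6))
  } else {
    note("model_skipped_insufficient_sets", sprintf("%d/%d", n_pos, n_neg))
  }

  # -- prediction on uncovered introns ---------------------------------------
  predictions <- NULL
  if (!is.null(fit)) {
    unc <- features[!features$intron_id %in% pir$intron_id[pir$covered], ,
                    drop = FALSE]
    if (nrow(unc) >= 2L) {
      score <- predict(fit, unc[, feat_cols], type = "response")
      predictions <- data.frame(intron_id = unc$intron_id, score = score,
                                stringsAsFactors = FALSE)
      k <- min(config$predict_k, nrow(unc) %/% 2L)
      if (k >= 1L) {
        sel <- rank_and_select(predictions$intron_id, predictions$score, k)
        predictions$predicted_class <- "intermediate"
        predictions$predicted_class[predictions$intron_id %in%
                                      sel$dependent] <- "dependent"
        predictions$predicted_class[predictions$intron_id %in%
                                      sel$independent] <- "independent"
      }
      predictions <- predictions[order(-predictions$score,
                                       predictions$intron_id), ]
      note("introns_predicted", nrow(predictions))
      write_tsv(predictions, file.path(out_dir, "predictions.tsv"))
    }
  }

  # -- provenance ------------------------------------------------------------
  cfgdump <- data.frame(key = names(unclass(config)),
                        value = vapply(unclass(config), function(v)
                          paste(as.character(v), collapse = ","), ""),
                        stringsAsFactors = FALSE)
  write_tsv(cfgdump, file.path(out_dir, "config.tsv"))
  write_tsv(data.frame(stage = names(counts_log),
                       value = vapply(counts_log, as.character, "")),
            file.path(out_dir, "stage_counts.tsv"))

  invisible(list(catalog = catalog, pir = pir, mappability = mapp,
                 cirpkm = cirpkm, density = density, expression = expression,
                 sets = sets, overlaps = ov, features = features, fit = fit,
                 predictions = predictions, counts_log = counts_log))
}
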
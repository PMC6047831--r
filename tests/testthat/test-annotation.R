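test_that("two non-overlapping genes yield all introns, none removed", {
  g1 <- toy_gene(c(filler(60), toy_intron(30), filler(60), toy_intron(33),
                   filler(60)), transcript_id = "tA", gene_id = "gA")
  # second gene placed on its own chromosome via a separate toy
  g2 <- toy_gene(c(filler(50), toy_intron(40), filler(50), toy_intron(44),
                   filler(50)), transcript_id = "tB", gene_id = "gB")
  m2 <- g2$model; m2$chrom <- "chr2"
  models <- list(tA = g1$model, tB = m2)
  catal <- build_intron_catalog(models)
  expect_equal(nrow(catal), 4L)
  expect_equal(attr(catal, "n_removed_overlapping"), 0L)
  expect_true(all(catal$end - catal$start >= 1))
})

test_that("an intron hosting a nested gene is removed from the catalog", {
  # gene A: 3 exons, intron 2 spans [150, 250) on chr1; gene B nested inside
  ga <- transcript_model("tA", "gA", "chr1", "+",
                        exons = rbind(c(0, 100), c(130, 150), c(250, 300)))
  gb <- transcript_model("tB", "gB", "chr1", "+",
                        exons = rbind(c(160, 190), c(210, 240)))
  catal <- build_intron_catalog(list(tA = ga, tB = gb))
  # brute-force overlap check: A.i2 = [150,250) overlaps gB span [160,240),
  # and B's intron [190,210) lies inside gA's span, so both are removed
  expect_false("tA.i2" %in% catal$intron_id)
  expect_false("tB.i1" %in% catal$intron_id)
  expect_true("tA.i1" %in% catal$intron_id)
  expect_equal(attr(catal, "n_removed_overlapping"), 2L)
  # strand-aware mode keeps the intron when the nested gene is antisense
  gb_rev <- transcript_model("tB", "gB", "chr1", "-",
                             exons = rbind(c(160, 190), c(210, 240)))
  catal2 <- build_intron_catalog(list(tA = ga, tB = gb_rev),
                                 strand_aware = TRUE)
  expect_true("tA.i2" %in% catal2$intron_id)
})

test_that("malformed annotation is rejected with the transcript named", {
  expect_error(transcript_model("tX", "gX", "chr1", "+",
                                exons = rbind(c(100, 200), c(0, 50))),
               "tX")
  expect_error(transcript_model("tY", "gY", "chr1", "+",
                                exons = rbind(c(0, 100), c(50, 150))),
               "tY")
})

test_that("catalog construction is order-independent and idempotent", {
  toys <- lapply(1:3, function(i)
    toy_gene(c(filler(60), toy_intron(30 + i), filler(60)),
             transcript_id = paste0("t", i), gene_id = paste0("g", i)))
  models <- lapply(toys, `[[`, "model")
  names(models) <- paste0("t", 1:3)
  c1 <- build_intron_catalog(models)
  c2 <- build_intron_catalog(rev(models))
  o1 <- c1[order(c1$intron_id), ]; rownames(o1) <- NULL
  o2 <- c2[order(c2$intron_id), ]; rownames(o2) <- NULL
  expect_equal(as.data.frame(o1), as.data.frame(o2))
  c3 <- build_intron_catalog(models)
  expect_equal(as.data.frame(c1), as.data.frame(c3))
})

test_that("position classes follow the first-two / internal / last-three rule", {
  expect_equal(classify_position(12L, 12L), "last")
  expect_equal(classify_position(5L, 12L), "internal")
  expect_equal(classify_position(2L, 12L), "first_two")
  expect_equal(classify_position(10L, 12L), "last_three")
  expect_equal(classify_position(c(1, 3, 9, 11), rep(12L, 4)),
               c("first_two", "internal", "internal", "last_three"))
  expect_error(classify_position(1L, 0L), "no introns")
  expect_error(classify_position(5L, 4L), "out of range")
})

test_that("every intron gets exactly one position and one NMD class", {
  cases <- build_nmd_panel(strands = "+")
  res <- nmd_panel_results(cases)
  expect_true(all(res$got %in% c("NMD", "noNMD_last", "noNMD_utr_or_noncoding",
                                 "noNMD_orf_preserving", "frameshift_no_nmd")))
  expect_false(anyNA(res$got))
  # exactly one class per intron, and last introns are always noNMD_last
  expect_equal(anyDuplicated(res$intron_id), 0L)
  expect_true(all(res$got[res$expected == "noNMD_last"] == "noNMD_last"))
})

test_that("NMD spot checks match hand-derived consequences", {
  # planted TAA ends at retained-mRNA position 84; last junction at 90 + e2
  far <- toy_gene(c(filler(60), toy_intron(30, stop_at = 21L), filler(90),
                    toy_intron(33), filler(60)))
  near <- toy_gene(c(filler(60), toy_intron(30, stop_at = 21L), filler(24),
                     toy_intron(33), filler(60)))
  for (case in list(list(far, "NMD"), list(near, "frameshift_no_nmd"))) {
    catal <- toy_catalog(case[[1]])
    models <- stats::setNames(list(case[[1]]$model),
                              case[[1]]$model$transcript_id)
    got <- predict_nmd(catal, models, case[[1]]$genome)
    expect_equal(got[catal$ordinal == 1L], case[[2]])
  }
})

test_that("strand reversal leaves all classifications unchanged", {
  plus <- nmd_panel_results(build_nmd_panel(strands = "+"))
  minus <- nmd_panel_results(build_nmd_panel(strands = "-"))
  # align introns across representations (catalog row order is genomic)
  key <- function(d) order(gsub("[+-]", "", d$intron_id))
  expect_equal(plus$got[key(plus)], minus$got[key(minus)])
  expect_equal(plus$ordinal[key(plus)], minus$ordinal[key(minus)])
})

test_that("a CDS whose spliced length breaks frame is rejected", {
  toy <- toy_gene(c(filler(60), toy_intron(30), filler(60)), cds_len = 60L)
  toy$model$cds[2] <- toy$model$cds[2] + 1L   # 61 nt spliced CDS
  catal <- toy_catalog(toy)
  # the single intron is last, which short-circuits; force a non-last intron
  toy2 <- toy_gene(c(filler(60), toy_intron(30), filler(60), toy_intron(33),
                     filler(60)), cds_len = 60L)
  toy2$model$cds[2] <- toy2$model$cds[2] + 1L
  catal2 <- toy_catalog(toy2)
  models <- stats::setNames(list(toy2$model), toy2$model$transcript_id)
  expect_error(predict_nmd(catal2[catal2$ordinal == 1L, ], models,
                           toy2$genome),
               "multiple of 3")
})

test_that("GTF round trip preserves exons, CDS and strand", {
  skip_if_not_installed("rtracklayer")
  cfg <- ir_sim_config(n_genes = 6L)
  sim <- generate_genome_and_annotation(cfg, seed = 5L)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$models, path)
  back <- read_gtf_models(path)
  expect_setequal(names(back), names(sim$models))
  for (tid in names(sim$models)) {
    expect_equal(back[[tid]]$exons, sim$models[[tid]]$exons)
    expect_equal(back[[tid]]$cds, sim$models[[tid]]$cds)
    expect_equal(back[[tid]]$strand, sim$models[[tid]]$strand)
  }
  # selecting reference transcripts keeps only the requested ids
  sub <- read_gtf_models(path, reference_transcripts = names(back)[1:2])
  expect_setequal(names(sub), names(back)[1:2])
})
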
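test_that("GC content excludes undetermined bases", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_equal(gc_content(c("AT", "GC")), c(0, 1))
  expect_error(gc_content(""), "empty")
})

test_that("PWM log-odds scoring matches hand arithmetic", {
  # toy 3-column PWM: consensus ACG at p = 0.7, others 0.1
  pwm <- consensus_pwm("ACG", p = 0.7)
  expect_equal(pwm_score("ACG", pwm), 3 * log2(0.7 / 0.25))
  expect_equal(pwm_score("AAG", pwm),
               2 * log2(0.7 / 0.25) + log2(0.1 / 0.25))
  # consensus input attains the analytic maximum
  expect_equal(pwm_score("ACG", pwm), pwm_max_score(pwm))
  # uniform PWM scores zero for any input
  expect_equal(pwm_score("GAT", uniform_pwm(3)), 0)
  expect_error(pwm_score("AC", pwm), "length")
  expect_error(pwm_score("ACN", pwm), "non-ACGT")
})

test_that("splice-site scorer checks geometry and supports adapters", {
  donor_pwm <- consensus_pwm("CAGGTAAGT")
  expect_equal(score_splice_site("CAGGTAAGT", "donor", donor_pwm),
               pwm_max_score(donor_pwm))
  expect_error(score_splice_site("CAGGT", "donor", donor_pwm), "9 nt")
  acc <- strrep("T", 20)
  expect_error(score_splice_site(acc, "acceptor", donor_pwm), "23 nt")
  # any function can stand in for the PWM (external-tool adapter contract)
  expect_equal(score_splice_site("CAGGTAAGT", "donor",
                                 scorer = function(s) nchar(s)), 9)
})

test_that("PWM window scan finds the embedded consensus maximum", {
  pwm <- consensus_pwm("TTGACC", p = 0.8)
  seq1 <- paste0(random_dna(40, 0.3), "TTGACC", random_dna(40, 0.3))
  expect_equal(scan_pwm_max(seq1, pwm), pwm_max_score(pwm))
  # two embedded copies give the same maximum as one
  seq2 <- paste0("TTGACC", random_dna(20), "TTGACC")
  expect_equal(scan_pwm_max(seq2, pwm), pwm_max_score(pwm))
  # reversing an asymmetric consensus scores below the maximum
  expect_lt(scan_pwm_max("CCAGTT", pwm), pwm_max_score(pwm))
  expect_error(scan_pwm_max("ACG", pwm), "shorter")
})

bp_fixture_pwm <- consensus_pwm("TACTAAC", p = 0.8)

test_that("branch-point scan finds a planted consensus at the right distance", {
  set.seed(11)
  # poly-G background excludes accidental candidates; branch A 25 nt from 3'ss
  left <- strrep("G", 80)
  seq1 <- paste0(left, "TACTAAC", strrep("G", 22), "AG")
  # branch A sits at position 86 of 111: 25 nt lie 3' of it
  got <- find_branch_points(seq1, bp_fixture_pwm)
  expect_false(got$missing)
  expect_equal(got$bp_distance, 25)
  expect_equal(got$bp_score, pwm_max_score(bp_fixture_pwm))
  # a poly-A sequence has no nnYTRAY candidate at all
  miss <- find_branch_points(strrep("A", 100), bp_fixture_pwm)
  expect_true(miss$missing)
  expect_true(is.na(miss$bp_score))
})

test_that("branch-point ties break towards the 3' splice site", {
  seq1 <- paste0(strrep("G", 30), "TACTAAC", strrep("G", 40), "TACTAAC",
                 strrep("G", 10), "AG")
  got <- find_branch_points(seq1, bp_fixture_pwm)
  # identical scores: the candidate nearer the 3' splice site wins
  expect_equal(got$bp_distance, 13)
  expect_equal(got$top3_distances[1:2], c(13, 60))
})

test_that("branch-point scan never reads beyond the 150-nt suffix", {
  set.seed(12)
  tail150 <- paste0(random_dna(100), "TACTAAC", random_dna(41), "AG")
  long <- paste0("TACTAAC", strrep("C", 400), tail150)   # decoy far upstream
  expect_equal(find_branch_points(long, bp_fixture_pwm),
               find_branch_points(tail150, bp_fixture_pwm))
})

test_that("polypyrimidine tract tolerates at most one purine interruption", {
  # CCTTTTATTTCC is one 12-nt tract with a single purine interruption
  seq1 <- paste0(strrep("G", 40), "TACTAAC", "G", "CCTTTTATTTCC", "GG", "AG")
  got <- find_branch_points(seq1, bp_fixture_pwm)
  expect_equal(got$ppt_length, 12)
})

test_that("feature extraction assembles the documented panel", {
  set.seed(21)
  toy <- toy_gene(c(filler(150), toy_intron(281), filler(150),
                    toy_intron(60), filler(90)))
  catal <- toy_catalog(toy)
  pwms <- list(donor = uniform_pwm(9), acceptor = uniform_pwm(23),
               branchpoint = bp_fixture_pwm, sf1 = uniform_pwm(6))
  fv <- extract_features(catal, toy$genome, pwms,
                         expression = c(g1 = 31))
  fv1 <- fv[fv$intron_id == "t1.i1", ]
  expect_equal(fv1$intron_length, 281)
  expect_equal(fv1$len_ratio_up, 150 / 281)
  expect_equal(fv1$len_ratio_mean, 150 / 281)
  iseq <- intron_sequences(catal, toy$genome)[1]
  expect_equal(fv1$gc_ratio_up, gc_content(filler(150)) / gc_content(iseq))
  expect_equal(fv1$ss5_score, 0)       # uniform PWM
  expect_equal(fv1$wt_expression_log, log2(32))
  expect_equal(fv1$rel_position, 0.5)
  expect_equal(fv1$transcript_length, 150 + 150 + 90)
  # last intron indicator and terminal-exon bookkeeping
  fv2 <- fv[fv$intron_id == "t1.i2", ]
  expect_equal(fv2$last_intron, 1)
  expect_equal(fv2$down_exon_length, 90)
  expect_equal(fv2$first_two, 1)       # ordinal 2 of 2
})

test_that("features are invariant to the strand representation of a locus", {
  set.seed(22)
  segs <- c(random_dna(120), paste0("GT", random_dna(200), "AG"),
            random_dna(100), paste0("GT", random_dna(150), "AG"),
            random_dna(80))
  pwms <- list(donor = consensus_pwm("CAGGTAAGT"),
               acceptor = consensus_pwm(paste0(strrep("T", 18), "AGGAA")),
               branchpoint = bp_fixture_pwm, sf1 = consensus_pwm("AACTAAC"))
  tp <- toy_gene(segs, strand = "+"); tm <- toy_gene(segs, strand = "-")
  fplus <- extract_features(toy_catalog(tp), tp$genome, pwms)
  fminus <- extract_features(toy_catalog(tm), tm$genome, pwms)
  fplus <- fplus[order(fplus$intron_id), ]; rownames(fplus) <- NULL
  fminus <- fminus[order(fminus$intron_id), ]; rownames(fminus) <- NULL
  expect_equal(fplus, fminus)
})

test_that("missing branch points are imputed and flagged", {
  set.seed(30)
  # intron 2 has no candidate heptamer (poly-G body)
  segs <- c(filler(60), paste0("GT", random_dna(100), "TACTAAC",
                               random_dna(20), "AG"),
            filler(60), paste0("GT", strrep("G", 96), "AG"), filler(60))
  toy <- toy_gene(segs)
  pwms <- list(donor = uniform_pwm(9), acceptor = uniform_pwm(23),
               branchpoint = bp_fixture_pwm, sf1 = uniform_pwm(6))
  fv <- extract_features(toy_catalog(toy), toy$genome, pwms)
  i2 <- fv[fv$intron_id == "t1.i2", ]
  expect_equal(i2$bp_missing, 1)
  expect_equal(i2$bp_dist_median, 150)
  expect_equal(i2$ppt_length, 0)
  expect_equal(i2$bp_score, min(fv$bp_score[fv$bp_missing == 0]))
})

test_that("group comparison reports Mann-Whitney p-values and medians", {
  feats <- data.frame(f1 = c(rnorm(20), rnorm(20)))
  # identical groups: p = 1 under the rank test
  same <- compare_feature_groups(data.frame(f = rep(1:10, 2)),
                                 rep(c("a", "b"), each = 10))
  expect_equal(same$p_value, 1)
  # disjoint support: extremely small p
  dis <- compare_feature_groups(data.frame(f = c(1:20, 101:120)),
                                rep(c("a", "b"), each = 20))
  expect_lt(dis$p_value, 0.001)
  expect_equal(dis$median_a, 10.5)
  expect_equal(dis$median_b, 110.5)
  expect_error(compare_feature_groups(feats, rep("a", 40)), "two groups")
})

test_that("a one-SD location shift is detected at the 0.001 level", {
  set.seed(99)
  hits <- replicate(40, {
    x <- data.frame(f = c(rnorm(200), rnorm(200, mean = 1)))
    compare_feature_groups(x, rep(c("a", "b"), each = 200))$p_value <= 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Fisher helper recovers a planted set enrichment", {
  universe <- paste0("i", 1:200)
  a <- universe[1:50]
  b <- c(universe[1:40], universe[191:200])   # strongly overlapping a
  ft <- fisher_enrichment(a, b, universe)
  expect_lt(ft$p.value, 1e-6)
  expect_gt(ft$estimate, 1)
})
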
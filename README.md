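# pirdep

Quantify intron retention from RNA-seq junction counts and model which
introns depend on a splicing factor.

When a spliceosome component is disrupted — in the motivating setting, each
subunit of a trimeric splicing complex knocked out in a vertebrate embryo,
with a matched wild-type sibling per mutant — a specific subset of introns is
retained in mature mRNA. `pirdep` implements the full analysis for such a
paired three-mutant design:

* **Retention quantification.** Percent intron retention per intron and
  sample, `PIR = 100·m/(m + EE)` with `m = (EI5' + EI3')/2`, where the
  exon–intron junction reads are averaged and *all* exon–exon junctions
  supporting removal of the intron count against them; junction coverage
  filters (15/10 inclusion reads or 15 splicing reads, in all six samples).
* **Mappability-corrected densities.** 50-nt sliding-window mappability with
  2 mismatches against the feature library plus both genome strands;
  per-position intron counts capped at 5× the intron median; ciRPKM/cRPKM
  (reads per kilobase of uniquely mappable positions per million mapped
  reads); quantile normalization; a fold-change based differential
  expression caller (≥1.5 in all pairs, ≥2 in at least two, after
  expression and read-support filters).
* **Set calling.** Confidently dependent introns ("RESdep": ΔPIR > 15 and a
  ≥1.5-fold net intron-body density increase
  `[ciRPKM_mut/(100−PIR_mut)]/[ciRPKM_sib/(100−PIR_sib)]` in ≥2 of 3
  mutants) and control introns ("Ctr": |ΔPIR| < 0.5 in all three), plus
  per-mutant sets and their Euler-region overlap counts.
* **Consequence annotation.** Intron position classes and the 50-nt
  premature-termination-codon rule for nonsense-mediated decay applied to
  the single-intron-retained isoform.
* **Feature panel.** Intron/exon lengths and GC, exon/intron length and GC
  ratios, PWM splice-site scores, branch-point score/distance and
  polypyrimidine-tract length from a 150-nt 3' scan, SF1 binding maximum,
  position along the transcript, transcript length, wild-type expression.
* **Dependence model.** L1-penalized logistic regression (RESdep vs Ctr)
  under repeated 90/10 holdout with balanced control sampling: averaged ROC
  and rank-based AUC, averaged standardized coefficients, transfer
  evaluation of fixed models on alternate intron sets, per-feature AUC and
  null-deviance reduction, and top-k prediction with false-prediction rates
  (ΔPIR < 2 / > 5) for introns lacking junction coverage.
* **Synthetic data.** A generator for genomes, annotations and count tables
  with known ground truth — dependent introns short, GC-rich, with weak
  branch points and low-GC flanking exons — so the entire pipeline is
  testable without external data.

## Worked example

```r
library(pirdep)

sim <- simulate_ir_experiment(ir_sim_config(n_genes = 120), seed = 1)
res <- run_ir_pipeline(sim, "runs/demo",
                       config = ir_config(n_repeats = 50, seed = 1))
str(res$counts_log)
#> List of 12
#>  $ introns_cataloged          : int 536
#>  $ introns_removed_overlapping: int 0
#>  $ introns_quantified         : int 536
#>  $ introns_covered            : int 489
#>  $ genes_expression_filtered  : int 1
#>  $ genes_up                   : int 3
#>  $ genes_down                 : int 3
#>  $ introns_resdep             : int 67
#>  $ introns_ctr                : int 204
#>  $ introns_with_features      : int 536
#>  $ model_mean_auc             : num 1
#>  $ introns_predicted          : int 47
```

536 introns were catalogued, 489 passed the junction-coverage filter in all
six samples, 67 were called confidently dependent and 204 confidently
unaffected; 47 introns without sufficient coverage were scored by the fitted
model. The model itself:

```r
print(res$fit)
#> Repeated-holdout L1-logistic dependence model
#>   67 positives vs 204 controls; 50 repeats, 60/7 train/test
#>   mean AUC 1.000 (95% CI +/- 0.000)
head(summary(res$fit)$coefficients, 6)
#>             feature mean_coefficient selection_freq
#> 1     gc_ratio_mean            -3.71           0.98
#> 2 log_intron_length            -2.76           1.00
#> 3          bp_score            -1.34           1.00
#> 4       gc_ratio_up            -0.80           0.58
#> 5    len_ratio_down             0.50           0.84
#> 6        ppt_length            -0.38           0.88
```

On this synthetic cohort the classes separate essentially perfectly (mean
holdout AUC 1.000), and the averaged coefficients point the expected way:
dependent introns are shorter (negative log-length), have a lower
exon-to-intron GC ratio and weaker branch points. Each pipeline stage also
writes a TSV (catalog, PIR, sets, features, coefficients, ROC, predictions)
plus a resolved-config snapshot and per-stage record counts under the run
directory.

Individual operations are exported and usable on their own, e.g.
`compute_pir(12, 18, 15)` is `50`, `cap_position_counts(c(1,1,1,1,100))`
returns `c(1,1,1,1,5)`, and `predict_nmd()` classifies constructed
transcripts.

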
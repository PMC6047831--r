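#' Select top predicted dependent and independent introns
#'
#' Deterministically orders scored introns (ties broken lexicographically by
#' id) and returns the `k` highest-scoring (predicted dependent) and `k`
#' lowest-scoring (predicted independent) ids. Intended for introns without
#' sufficient junction read coverage, whose dependence the model predicts
#' from sequence features alone.
#'
#' @param ids character vector of intron ids
#' @param scores numeric model scores (probability of dependence)
#' @param k number of introns to select on each side
#' @return list with elements `dependent` and `independent`, each a character
#'   vector of length `k` ordered from most extreme inward
#' @export
rank_and_select <- function(ids, scores, k) {
  if (length(ids) != length(scores)) stopf("ids and scores differ in length")
  if (k > length(ids) / 2) stopf("k = %d exceeds half the cohort (%d)",
                                 k, length(ids))
  o_dep <- order(-scores, ids)
  o_ind <- order(scores, ids)
  list(dependent = ids[o_dep[seq_len(k)]],
       independent = ids[o_ind[seq_len(k)]])
}

#' False-prediction rates of selected intron sets
#'
#' For predicted-dependent introns the false-prediction rate is the fraction
#' whose observed delta-PIR is below `dep_threshold`; for predicted-independent
#' introns, the fraction whose observed delta-PIR exceeds `indep_threshold`.
#'
#' @param dep_delta observed delta-PIR of the predicted-dependent set
#' @param indep_delta observed delta-PIR of the predicted-independent set
#' @param dep_threshold delta-PIR below which a dependent call is false
#'   (default 2)
#' @param indep_threshold delta-PIR above which an independent call is false
#'   (default 5)
#' @return named numeric vector (fpr_dep, fpr_indep)
#' @export
false_prediction_rate <- function(dep_delta, indep_delta, dep_threshold = 2,
                                  indep_threshold = 5) {
  if (!length(dep_delta) || !length(indep_delta))
    stopf("empty selection")
  c(fpr_dep = mean(dep_delta < dep_threshold),
    fpr_indep = mean(indep_delta > indep_threshold))
}
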
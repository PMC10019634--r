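#' Simulate phenotypic sparsity or noise on a term-set corpus
#'
#' Applies the term-ratio perturbation to each variant's raw annotation set
#' before similarity computation:
#' * `ratio < 1` (sparsity): keep `round(ratio * |set|)` terms chosen
#'   uniformly at random, never fewer than 1 (ratio 0.25 on a 4-term set
#'   removes 3 of 4 terms);
#' * `ratio = 1`: unchanged;
#' * `ratio > 1` (noise): add `(ratio - 1) * |set|` terms sampled without
#'   replacement from the ontology's terms outside the set (ratio 4 adds 3
#'   random terms per original term).
#'
#' Rounding is half-up. Propagation is re-applied to the perturbed raw sets.
#'
#' @param corpus List of [term_set()] objects.
#' @param ratio Positive term ratio.
#' @param graph The [ontology_graph()] (supplies the candidate universe and
#'   re-propagation).
#' @param seed Optional integer seed for reproducible perturbation.
#' @param universe Candidate term ids for noise terms; defaults to all terms
#'   of the ontology.
#' @return Perturbed list of [term_set()] objects.
#' @export
perturb_termsets <- function(corpus, ratio, graph, seed = NULL, universe = NULL) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0) stop("ratio must be > 0")
  if (is.null(universe)) universe <- graph$terms
  if (!is.null(seed)) set.seed(seed)
  if (ratio == 1) return(corpus)
  rhu <- function(x) floor(x + 0.5)
  lapply(corpus, function(ts) {
    raw <- ts$raw_terms
    if (length(raw) == 0L) stop("raw term set for ", ts$variant_id, " is empty")
    if (ratio < 1) {
      keep <- max(1L, rhu(ratio * length(raw)))
      raw2 <- sort(sample(raw, keep))
    } else {
      n_add <- rhu((ratio - 1) * length(raw))
      pool <- setdiff(universe, raw)
      if (n_add > length(pool)) {
        stop("term universe exhausted for ", ts$variant_id, ": need ", n_add,
             " novel terms, only ", length(pool), " available")
      }
      raw2 <- sort(c(raw, sample(pool, n_add)))
    }
    term_set(ts$variant_id, raw2, graph)
  })
}

#' Robustness sweep over phenotype sparsity/noise levels
#'
#' For every (ratio, measure, seed) combination: perturb the raw term sets,
#' rebuild the phenotype kernel and run [nested_cv()], collecting mean and
#' SD of accuracy and AU-ROC.
#'
#' @param dataset An `mkl_dataset`.
#' @param ratios Positive term ratios (1 = unperturbed).
#' @param measures Similarity measures to sweep.
#' @param grid A [hyper_grid()] (its `measure` slot is overridden per run).
#' @param seeds Integer seeds (used both for the perturbation draw and the
#'   CV fold assignment).
#' @param mode Model configuration for [nested_cv()].
#' @param k,inner_k Fold counts.
#' @return data.frame with columns ratio, measure, seed, acc_mean, acc_sd,
#'   auroc_mean, auroc_sd.
#' @export
robustness_sweep <- function(dataset, ratios, measures = "jaccard",
                             grid = hyper_grid(), seeds = 1,
                             mode = "mkl_uniform", k = 5, inner_k = 5) {
  if (length(ratios) == 0L) stop("ratios must be nonempty")
  rows <- list()
  for (ratio in ratios) {
    for (ms in measures) {
      for (s in seeds) {
        d <- dataset
        d$term_sets <- perturb_termsets(dataset$term_sets, ratio, dataset$ontology,
                                        seed = s + 5000L)
        g <- grid
        g$measure <- ms
        rep_ <- nested_cv(d, mode, g, k = k, inner_k = inner_k, seed = s)
        agg <- rep_$aggregate
        rows[[length(rows) + 1L]] <- data.frame(
          ratio = ratio, measure = ms, seed = s,
          acc_mean = agg$mean[agg$metric == "acc"],
          acc_sd = agg$sd[agg$metric == "acc"],
          auroc_mean = agg$mean[agg$metric == "au_roc"],
          auroc_sd = agg$sd[agg$metric == "au_roc"],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
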
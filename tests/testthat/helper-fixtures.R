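# Small fixtures built in code, shared across test files.

## diamond ontology: R <- A, R <- C, A <- D, C <- D, plus a spare leaf B <- A
diamond_graph <- function() {
  ontology_graph(list(
    R = character(0),
    A = "R",
    C = "R",
    B = "A",
    D = c("A", "C")
  ))
}

chain_graph <- function() {
  ontology_graph(list(R = character(0), A = "R", B = "A"))
}

obo_text <- function(...) {
  tmp <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", ...), tmp)
  tmp
}

## random propagated corpus over a random DAG ontology
random_corpus <- function(n_sets, graph, min_terms = 2, max_terms = 6) {
  lapply(seq_len(n_sets), function(i) {
    k <- sample(min_terms:max_terms, 1)
    term_set(paste0("v", i), sample(graph$terms, k), graph)
  })
}

## independent eigendecomposition oracle for the PSD corrections
psd_oracle <- function(S, method) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  V <- e$vectors
  l <- e$values
  switch(method,
    clip = V %*% diag(pmax(l, 0), nrow(S)) %*% t(V),
    flip = V %*% diag(abs(l), nrow(S)) %*% t(V),
    shift = if (min(l) < -1e-8 * max(1, max(l))) S + abs(min(l)) * diag(nrow(S)) else S
  )
}

## brute-force confusion-matrix metric panel (independent of compute_metrics)
brute_metrics <- function(y_true, y_pred, positive = "GOF") {
  yt <- as.character(y_true) == positive
  yp <- as.character(y_pred) == positive
  tp <- sum(yt & yp); fp <- sum(!yt & yp); fn <- sum(yt & !yp); tn <- sum(!yt & !yp)
  n <- length(yt)
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  list(
    acc = (tp + tn) / n,
    f1 = 2 * tp / (2 * tp + fp + fn),
    mcc = (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
    kappa = ((tp + tn) / n - pe) / (1 - pe)
  )
}

## small cohort tuned for fast CV tests
quick_cohort <- function(seed = 1, n = 80, phenotype_effect = 0.6,
                         feature_effect = 0.2, n_terms = 100) {
  generate_cohort(synthetic_config(
    n_variants = n, n_terms = n_terms, seed = seed,
    phenotype_effect = phenotype_effect, feature_effect = feature_effect
  ))
}

quick_grid <- function(sigma = 8) {
  hyper_grid(C = 1, sigma = sigma, a = 5, measure = "jaccard", correction = "clip")
}
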
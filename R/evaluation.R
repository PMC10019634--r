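#' Hyperparameter grid for nested cross-validation
#'
#' Defaults are the full tuning grid: cost `C` in 1e-4..1e4 (powers of 100),
#' RBF bandwidth `sigma` in 1e-5..1, task-similarity baseline `a` in
#' \{1, 3, 5, 10, 100\}, and — treated as hyperparameters — the semantic
#' similarity measure and the PSD correction method.
#'
#' @param C,sigma,a Numeric grids.
#' @param measure,correction Character grids.
#' @return Object of class `hyper_grid`.
#' @export
hyper_grid <- function(C = c(1e-4, 1e-2, 1, 1e2, 1e4),
                       sigma = 10^(-5:0),
                       a = c(1, 3, 5, 10, 100),
                       measure = c("jaccard", "resnik", "lin"),
                       correction = c("clip", "flip", "shift")) {
  structure(
    list(C = C, sigma = sigma, a = a, measure = measure, correction = correction),
    class = "hyper_grid"
  )
}

## rank-based AU-ROC (Mann-Whitney with midranks for ties)
auc_roc <- function(pos, scores) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AU-ROC undefined: single-class truth")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## step-integrated AU-PRC (precision-recall, score-tie groups as blocks)
auc_prc <- function(pos, scores) {
  P <- sum(pos)
  if (P == 0L || all(pos)) stop("AU-PRC undefined: single-class truth")
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  scores <- scores[ord]
  grp <- cumsum(!duplicated(scores))
  tp_g <- tapply(as.numeric(pos), grp, sum)
  n_g <- tapply(rep(1, length(pos)), grp, sum)
  tp <- cumsum(tp_g)
  npred <- cumsum(n_g)
  prec <- tp / npred
  dtp <- diff(c(0, tp))
  sum(dtp / P * prec)
}

#' Classification metric panel
#'
#' Accuracy, sensitivity (TPR for the positive class), specificity, F1,
#' Cohen's kappa, Matthews correlation coefficient, AU-PRC and AU-ROC (the
#' curve metrics from the real-valued scores). Degenerate 0/0 ratios are
#' reported as 0 (F1 with no predicted or true positives; MCC/kappa with a
#' zero denominator).
#'
#' @param y_true,y_pred Labels (`"GOF"`/`"LOF"`, factor or character).
#' @param scores Real decision values (higher = more GOF-like).
#' @param positive Positive class label (default `"GOF"`).
#' @return Named list of class `metric_panel`.
#' @export
compute_metrics <- function(y_true, y_pred, scores, positive = "GOF") {
  stopifnot(length(y_true) == length(y_pred), length(y_true) == length(scores))
  yt <- as.character(y_true) == positive
  yp <- as.character(y_pred) == positive
  if (all(yt) || !any(yt)) stop("y_true contains a single class; stratify folds")
  tp <- sum(yt & yp)
  fp <- sum(!yt & yp)
  fn <- sum(yt & !yp)
  tn <- sum(!yt & !yp)
  n <- tp + fp + fn + tn
  acc <- (tp + tn) / n
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) 0 else (po - pe) / (1 - pe)
  structure(
    list(
      acc = acc, sensitivity = sens, specificity = spec, f1 = f1,
      kappa = kappa, mcc = mcc,
      au_prc = auc_prc(yt, scores), au_roc = auc_roc(yt, scores)
    ),
    class = "metric_panel"
  )
}

#' Stratified cross-validation fold assignment
#'
#' Deals each class round-robin into `k` folds after a seeded shuffle, so
#' every fold carries both classes whenever class counts permit.
#'
#' @param y Labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
cv_folds <- function(y, k, seed = 1) {
  if (k < 2L) stop("k must be >= 2")
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in unique(as.character(y))) {
    idx <- which(as.character(y) == cl)
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

## ---- kernel caches ---------------------------------------------------------

## Precompute every kernel the grid can ask for, once per dataset. All of
## these are label-free, so computing them on the full cohort leaks nothing.
build_kernel_cache <- function(dataset, grid, modes) {
  X <- dataset$features
  cache <- list(struct = list(), task = list(), pheno = list())
  for (s in grid$sigma) {
    cache$struct[[as.character(s)]] <- normalize_kernel(rbf_kernel(X, s))
  }
  need_task <- any(modes %in% c("mtl", "mkl_uniform", "mkl_global", "mkl_hierarchical"))
  if (need_task) {
    for (a in grid$a) {
      Kt <- task_similarity(dataset$tree, a)
      Ks <- normalize_kernel(task_kernel(Kt, dataset$tasks))
      attr(Ks, "psd_status") <- "verified"
      cache$task[[as.character(a)]] <- Ks
    }
  }
  need_pheno <- any(modes %in% c("mkl_uniform", "mkl_global", "mkl_hierarchical"))
  if (need_pheno) {
    ic <- information_content(dataset$term_sets)
    for (ms in grid$measure) {
      S <- similarity_matrix(ms, dataset$term_sets, dataset$ontology, ic = ic)
      corrections <- if (ms == "jaccard") "clip" else grid$correction
      for (co in corrections) {
        K <- nearest_psd(S, co)
        attr(K, "eigen") <- NULL
        key <- pheno_key(ms, co)
        if (is.null(cache$pheno[[key]])) {
          Kp <- normalize_kernel(K)
          attr(Kp, "psd_status") <- psd_status(K)
          cache$pheno[[key]] <- Kp
        }
      }
    }
  }
  cache
}

pheno_key <- function(measure, correction) {
  if (measure == "jaccard") "jaccard" else paste(measure, correction, sep = ":")
}

## grid combos relevant for a mode, ordered so ties resolve toward smaller C
## then larger sigma (smoother models)
mode_combos <- function(mode, grid) {
  base <- list(C = grid$C, sigma = grid$sigma)
  if (mode %in% c("mtl", "mkl_uniform", "mkl_global", "mkl_hierarchical")) base$a <- grid$a
  if (mode %in% c("mkl_uniform", "mkl_global", "mkl_hierarchical")) {
    keys <- unique(unlist(lapply(grid$measure, function(ms) {
      if (ms == "jaccard") "jaccard" else paste(ms, grid$correction, sep = ":")
    })))
    base$pheno <- keys
  }
  g <- expand.grid(base, stringsAsFactors = FALSE)
  g[order(g$C, -g$sigma), , drop = FALSE]
}

## the combined kernel for a mode at one grid point (full cohort)
mode_kernel <- function(mode, combo, cache, dataset) {
  Kx <- cache$struct[[as.character(combo$sigma)]]
  if (mode %in% c("dirac", "union")) return(Kx)
  Kt <- cache$task[[as.character(combo$a)]]
  if (mode == "mtl") {
    K <- Kx * Kt
    attr(K, "psd_status") <- "verified"
    dimnames(K) <- dimnames(Kx)
    return(K)
  }
  Kp <- cache$pheno[[combo$pheno]]
  list(struct = Kx, task = Kt, pheno = Kp)
}

## fit on training indices + predict decision values on test indices
fit_predict <- function(mode, K, dataset, tr, te, C, weights = NULL) {
  y <- dataset$labels
  if (mode == "dirac") {
    f <- numeric(length(te))
    for (task in unique(dataset$tasks[te])) {
      te_t <- te[dataset$tasks[te] == task]
      tr_t <- tr[dataset$tasks[tr] == task]
      if (length(tr_t) < 2L || length(unique(as.character(y[tr_t]))) < 2L) {
        ## too few/one-class training variants for this channel: constant vote
        maj <- if (length(tr_t) > 0 && mean(as.character(y[tr_t]) == "GOF") > 0.5) 1 else -1
        f[match(te_t, te)] <- maj
      } else {
        m <- train_svm(K[tr_t, tr_t, drop = FALSE], y[tr_t], C = C)
        f[match(te_t, te)] <- decision_values(m, K[te_t, tr_t, drop = FALSE])
      }
    }
    return(f)
  }
  Kfull <- if (is.list(K) && !is.matrix(K)) combine_kernels(K, weights) else K
  m <- train_svm(Kfull[tr, tr, drop = FALSE], y[tr], C = C)
  decision_values(m, Kfull[te, tr, drop = FALSE])
}

#' Nested k-fold cross-validated model assessment
#'
#' Outer folds (stratified by label) estimate generalization performance;
#' inner folds of each outer-training set select hyperparameters by mean
#' inner AU-ROC, with ties broken toward smaller `C` and larger `sigma`.
#' The fold model is retrained on the full outer-training set and scored on
#' the held-out fold.
#'
#' Modes: `dirac` (one SVM per channel), `union` (one pooled SVM), `mtl`
#' (multi-task kernel = task similarity x structure RBF), `mkl_uniform`
#' (uniform-weight sum of task, structure and phenotype kernels),
#' `mkl_global` (weights learned by wrapper on the outer-training set) and
#' `mkl_hierarchical` (localized hierarchical-decomposition weights). For
#' the learned-weight modes, hyperparameters are selected with uniform
#' weights and the weights are then learned at the selected grid point.
#'
#' @param dataset An `mkl_dataset` (see [load_dataset()] / [generate_cohort()]).
#' @param mode One of the modes above.
#' @param grid A [hyper_grid()].
#' @param k Outer folds (default 5).
#' @param inner_k Inner folds (default 5).
#' @param seed Integer seed controlling all fold assignments.
#' @param outer_folds Optional integer vector of precomputed outer-fold ids
#'   (1..k per sample), e.g. to compare model configurations on identical
#'   splits; defaults to a stratified assignment from `seed`.
#' @return Object of class `cv_report`: `folds` (per-fold metric panel and
#'   chosen hyperparameters), `aggregate` (mean and SD per metric), `mode`,
#'   `seed`, plus learned weights where applicable.
#' @export
nested_cv <- function(dataset, mode = c("mkl_uniform", "dirac", "union", "mtl",
                                        "mkl_global", "mkl_hierarchical"),
                      grid = hyper_grid(), k = 5, inner_k = 5, seed = 1,
                      outer_folds = NULL) {
  mode <- match.arg(mode)
  y <- dataset$labels
  if (length(unique(as.character(y))) < 2L) stop("dataset labels contain a single class")
  cache <- build_kernel_cache(dataset, grid, mode)
  combos <- mode_combos(mode, grid)
  if (is.null(outer_folds)) outer_folds <- cv_folds(y, k, seed)
  if (length(outer_folds) != length(y)) stop("outer_folds must assign every sample")
  fold_rows <- list()
  weights_per_fold <- list()
  for (fi in seq_len(k)) {
    tr <- which(outer_folds != fi)
    te <- which(outer_folds == fi)
    ## inner model selection on the outer-training set only
    best <- NULL
    best_auc <- -Inf
    for (ci in seq_len(nrow(combos))) {
      combo <- combos[ci, , drop = FALSE]
      K <- mode_kernel(mode, combo, cache, dataset)
      inner_folds <- cv_folds(y[tr], inner_k, seed + 1000L + fi)
      aucs <- vapply(seq_len(inner_k), function(ii) {
        itr <- tr[inner_folds != ii]
        ite <- tr[inner_folds == ii]
        if (length(unique(as.character(y[ite]))) < 2L ||
            length(unique(as.character(y[itr]))) < 2L) return(NA_real_)
        f <- fit_predict(mode, K, dataset, itr, ite, combo$C)
        auc_roc(as.character(y[ite]) == "GOF", f)
      }, numeric(1))
      mauc <- mean(aucs, na.rm = TRUE)
      if (mauc > best_auc + 1e-12) {
        best_auc <- mauc
        best <- combo
      }
    }
    ## learn weights (if any) on the outer-training block at the chosen point
    K <- mode_kernel(mode, best, cache, dataset)
    w <- NULL
    if (mode == "mkl_global") {
      sub <- lapply(K, function(Km) Km[tr, tr, drop = FALSE])
      w <- learn_global_weights(sub, y[tr],
        eval_config = list(C = best$C, k = inner_k, seed = seed + 2000L + fi))
      K <- combine_kernels(K, as.numeric(w))
    } else if (mode == "mkl_hierarchical") {
      sub <- lapply(K, function(Km) Km[tr, tr, drop = FALSE])
      hw <- learn_hierarchical_weights(dataset$tree, sub, dataset$tasks[tr], y[tr],
        eval_config = list(C = best$C, k = min(inner_k, 3L), seed = seed + 2000L + fi))
      w <- hw
      K <- hierarchical_mkl_kernel(dataset$tree, K, dataset$tasks, hw)
    } else if (mode %in% c("mkl_uniform")) {
      K <- combine_kernels(K)
    }
    f <- fit_predict(mode, K, dataset, tr, te, best$C)
    pred <- ifelse(f > 0, "GOF", "LOF")
    metrics <- compute_metrics(y[te], pred, f)
    fold_rows[[fi]] <- data.frame(
      fold = fi, as.data.frame(unclass(metrics)),
      C = best$C, sigma = best$sigma,
      a = if (!is.null(best$a)) best$a else NA_real_,
      pheno = if (!is.null(best$pheno)) best$pheno else NA_character_,
      inner_auc = best_auc,
      stringsAsFactors = FALSE
    )
    weights_per_fold[[fi]] <- w
  }
  folds <- do.call(rbind, fold_rows)
  metric_names <- c("acc", "sensitivity", "specificity", "f1", "kappa", "mcc", "au_prc", "au_roc")
  aggregate <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(folds[[m]]), numeric(1)),
    row.names = NULL
  )
  structure(
    list(mode = mode, folds = folds, aggregate = aggregate, seed = seed,
         k = k, inner_k = inner_k, weights = weights_per_fold),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Nested ", x$k, "-fold CV, mode = ", x$mode, ", seed = ", x$seed, "\n", sep = "")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %.3f ± %.3f\n", agg$metric[i], agg$mean[i], agg$sd[i]))
  }
  invisible(x)
}

#' Benchmark several model configurations
#'
#' Runs [nested_cv()] for each mode and seed and collects the aggregate
#' metrics into one table (one row per mode x seed x metric).
#'
#' @param dataset An `mkl_dataset`.
#' @param modes Character vector of modes.
#' @param grid A [hyper_grid()].
#' @param seeds Integer seeds.
#' @param k,inner_k Fold counts.
#' @return List with `summary` (data.frame) and `reports` (nested list).
#' @export
run_benchmark <- function(dataset, modes, grid = hyper_grid(), seeds = 1,
                          k = 5, inner_k = 5) {
  if (length(modes) == 0L) stop("modes must be nonempty")
  reports <- list()
  rows <- list()
  for (mode in modes) {
    reports[[mode]] <- list()
    for (s in seeds) {
      rep_ <- nested_cv(dataset, mode, grid, k = k, inner_k = inner_k, seed = s)
      reports[[mode]][[as.character(s)]] <- rep_
      agg <- rep_$aggregate
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, seed = s, metric = agg$metric, mean = agg$mean, sd = agg$sd,
        stringsAsFactors = FALSE
      )
    }
  }
  list(summary = do.call(rbind, rows), reports = reports)
}
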
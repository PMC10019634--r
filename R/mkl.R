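#' Combine modality kernels as a weighted sum
#'
#' `K = sum_m beta_m K_m` over a stack of modality kernels (e.g. structure
#' RBF, task, phenotype) sharing the same sample order. `weights = NULL`
#' assigns uniform weights `1/M`.
#'
#' @param kernels Named list of kernel matrices over identical sample ids.
#' @param weights Nonnegative weights (recycled names optional); default
#'   uniform.
#' @return Kernel matrix.
#' @export
combine_kernels <- function(kernels, weights = NULL) {
  if (length(kernels) == 0L) stop("empty kernel stack")
  ids <- rownames(kernels[[1]])
  for (K in kernels) {
    if (!all(dim(K) == dim(kernels[[1]]))) stop("kernel size mismatch across modalities")
    if (!is.null(ids) && !identical(rownames(K), ids)) stop("sample id mismatch across modalities")
  }
  if (is.null(weights)) weights <- rep(1 / length(kernels), length(kernels))
  if (length(weights) != length(kernels)) stop("one weight per modality required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  K <- Reduce(`+`, Map(`*`, weights, kernels))
  dimnames(K) <- dimnames(kernels[[1]])
  attr(K, "psd_status") <- "verified"
  K
}

as_pm1 <- function(y, positive = "GOF") {
  y <- as.character(y)
  ifelse(y == positive, 1, -1)
}

#' Train a C-SVM on a precomputed kernel matrix
#'
#' Solves the soft-margin dual on the given Gram matrix. The kernel must be
#' PSD (verified or corrected); indefinite inputs are refused since they
#' yield a non-convex problem — correct them with [nearest_psd()] first.
#' GOF is the positive class: the decision function
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` is oriented so positive values
#' predict GOF.
#'
#' @param K PSD kernel matrix over training samples.
#' @param y Labels, values `"GOF"`/`"LOF"` (factor or character).
#' @param C Positive cost parameter.
#' @param recipe Optional list recording kernel provenance (measure,
#'   correction, sigma, a, weights) stored with the model.
#' @return Object of class `phenomkl_svm` with `dual_coef` (length n,
#'   `alpha_i y_i`), `bias`, `support`, `C`, `ids`, `labels`.
#' @export
train_svm <- function(K, y, C = 1, recipe = NULL) {
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  y <- factor(as.character(y), levels = c("LOF", "GOF"))
  if (any(is.na(y))) stop("labels must be GOF or LOF")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (length(y) != nrow(K)) stop("label / kernel size mismatch")
  status <- psd_status(K)
  if (is.na(status) || status == "indefinite") {
    chk <- check_psd(K)
    if (!chk$psd) {
      stop("kernel is indefinite (lambda_min = ", signif(chk$lambda_min, 4),
           "); apply nearest_psd() before training")
    }
  }
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = C, scaled = FALSE)
  sv <- kernlab::SVindex(m)
  co <- unlist(kernlab::coef(m))
  dual <- numeric(nrow(K))
  dual[sv] <- co
  bias <- -kernlab::b(m)
  f <- as.vector(K %*% dual + bias)
  pred <- kernlab::predict(m, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]))
  ## orient the decision function so f > 0 <=> predicted GOF
  agree <- mean((f > 0) == (pred == "GOF"))
  if (agree < 0.5) {
    dual <- -dual
    bias <- -bias
  }
  structure(
    list(
      dual_coef = dual, bias = bias, support = sv, C = C,
      ids = rownames(K), labels = y, recipe = recipe
    ),
    class = "phenomkl_svm"
  )
}

#' @export
print.phenomkl_svm <- function(x, ...) {
  cat("C-SVM on precomputed kernel:", length(x$labels), "samples,",
      length(x$support), "support vectors, C =", x$C, "\n")
  invisible(x)
}

#' Decision values of a trained kernel SVM
#'
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` for new samples; the sign
#' predicts the label (positive = GOF) and the magnitude is the
#' margin-scaled distance to the separating hyperplane used for ranking
#' (ROC/PRC) and for the histogram-of-projections confidence analysis.
#'
#' @param model A [train_svm()] model.
#' @param K_cross Kernel block, new samples x training samples (columns in
#'   training order).
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, K_cross) {
  K_cross <- rbind(K_cross)
  if (ncol(K_cross) != length(model$dual_coef)) {
    stop("K_cross must have one column per training sample")
  }
  as.vector(K_cross %*% model$dual_coef + model$bias)
}

#' @param object A `phenomkl_svm` model.
#' @param K_cross Kernel block, new samples x training samples.
#' @param type `"label"` or `"decision"`.
#' @param ... Unused.
#' @rdname decision_values
#' @method predict phenomkl_svm
#' @export
predict.phenomkl_svm <- function(object, K_cross, type = c("label", "decision"), ...) {
  type <- match.arg(type)
  f <- decision_values(object, K_cross)
  if (type == "decision") return(f)
  factor(ifelse(f > 0, "GOF", "LOF"), levels = c("LOF", "GOF"))
}

## enumerate weight vectors on the simplex at a given grid resolution,
## ordered by distance from the uniform point so ties in the wrapper
## objective resolve toward the least extreme combination
simplex_grid <- function(M, resolution = 0.1) {
  steps <- round(1 / resolution)
  if (M == 1L) return(matrix(1, 1, 1))
  combos <- expand.grid(rep(list(0:steps), M - 1))
  combos <- combos[rowSums(combos) <= steps, , drop = FALSE]
  W <- cbind(as.matrix(combos), steps - rowSums(combos)) / steps
  W <- unname(W)
  W[order(rowSums((W - 1 / M)^2)), , drop = FALSE]
}

## inner-CV mean AUROC of an SVM on kernel K — the wrapper objective
kernel_cv_auc <- function(K, y, C, k = 5, seed = 1) {
  folds <- cv_folds(y, k, seed)
  aucs <- vapply(seq_len(k), function(fi) {
    tr <- folds != fi
    te <- !tr
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) return(NA_real_)
    m <- train_svm(K[tr, tr, drop = FALSE], y[tr], C = C)
    f <- decision_values(m, K[te, tr, drop = FALSE])
    auc_roc(as_pm1(y[te]) > 0, f)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Learn global kernel weights with a wrapper method
#'
#' Searches simplex weights for the convex kernel combination maximizing
#' the inner-cross-validated AU-ROC of the combined-kernel SVM. For up to 3
#' modalities the simplex is scanned exhaustively at the given resolution;
#' for more, deterministic coordinate ascent from uniform weights is used.
#'
#' @param kernels Named list of (normalized) modality kernels.
#' @param y GOF/LOF labels.
#' @param eval_config List with elements `C` (SVM cost, default 1), `k`
#'   (inner folds, default 5), `seed`, `resolution` (simplex grid step for
#'   up to 3 modalities, default 0.1) and `ascent_resolution` (coarser step
#'   for the coordinate-ascent search over many kernels, default 0.2).
#' @return Named numeric simplex weights (attribute `objective` holds the
#'   achieved inner AU-ROC).
#' @export
learn_global_weights <- function(kernels, y, eval_config = list()) {
  cfg <- utils::modifyList(
    list(C = 1, k = 5, seed = 1, resolution = 0.1, ascent_resolution = 0.2),
    eval_config
  )
  if (length(unique(as.character(y))) < 2L) stop("labels contain a single class")
  M <- length(kernels)
  nm <- names(kernels)
  if (is.null(nm)) nm <- paste0("kernel", seq_len(M))
  if (M == 1L) {
    w <- stats::setNames(1, nm)
    attr(w, "objective") <- kernel_cv_auc(kernels[[1]], y, cfg$C, cfg$k, cfg$seed)
    return(w)
  }
  score <- function(w) {
    kernel_cv_auc(combine_kernels(kernels, w), y, cfg$C, cfg$k, cfg$seed)
  }
  if (M <= 3L) {
    W <- simplex_grid(M, cfg$resolution)
    vals <- apply(W, 1, score)
    best <- W[which.max(vals), ]
    obj <- max(vals)
  } else {
    steps <- round(1 / cfg$ascent_resolution)
    best <- rep(1 / M, M)
    obj <- score(best)
    for (pass in 1:2) {
      improved <- FALSE
      for (m in seq_len(M)) {
        for (g in (0:steps) / steps) {
          w <- best
          rest <- sum(w[-m])
          w[-m] <- if (rest > 0) w[-m] * (1 - g) / rest else rep((1 - g) / (M - 1), M - 1)
          w[m] <- g
          v <- score(w)
          if (v > obj + 1e-9) {
            obj <- v
            best <- w
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  w <- stats::setNames(as.numeric(best), nm)
  attr(w, "objective") <- obj
  w
}

#' Learn localized hierarchical weights over a task taxonomy
#'
#' For each node of the taxonomy, modality weights are learned on that
#' node's sample block (the samples whose task is a leaf of the subtree) by
#' the same wrapper as [learn_global_weights()]. Blocks smaller than
#' `min_block` samples or containing a single class fall back to uniform
#' modality weights. The outer node weights `beta` over the per-node subset
#' kernels are then learned by the wrapper as well.
#'
#' @param tree A [task_tree()].
#' @param kernels Named list of normalized modality kernels (full cohort).
#' @param task_of Named character vector mapping sample id to task.
#' @param y GOF/LOF labels.
#' @param eval_config As in [learn_global_weights()].
#' @param min_block Minimum block size for learning node-local weights.
#' @return Object of class `hier_weights`: `node_weights` (named beta,
#'   simplex), `modality_weights` (named list per node), `uniform_fallback`
#'   (named logical).
#' @export
learn_hierarchical_weights <- function(tree, kernels, task_of, y,
                                       eval_config = list(), min_block = 10) {
  M <- length(kernels)
  uniform <- stats::setNames(rep(1 / M, M), names(kernels))
  mod_w <- list()
  fallback <- logical(0)
  node_kernels <- list()
  for (node in tree$nodes) {
    member <- task_of %in% tree$node_subsets[[node]]
    if (sum(member) == 0L) stop("empty task subset at node ", node)
    yb <- y[member]
    if (sum(member) < min_block || length(unique(as.character(yb))) < 2L) {
      w <- uniform
      fallback[node] <- TRUE
    } else {
      sub <- lapply(kernels, function(K) K[member, member, drop = FALSE])
      w <- learn_global_weights(sub, yb, eval_config)
      fallback[node] <- FALSE
    }
    mod_w[[node]] <- w
    mask <- outer(task_of %in% tree$node_subsets[[node]], task_of %in% tree$node_subsets[[node]])
    Kn <- combine_kernels(kernels, w) * mask
    dimnames(Kn) <- dimnames(kernels[[1]])
    node_kernels[[node]] <- Kn
  }
  beta <- learn_global_weights(node_kernels, y, eval_config)
  structure(
    list(
      node_weights = stats::setNames(as.numeric(beta), names(node_kernels)),
      modality_weights = mod_w,
      uniform_fallback = fallback,
      objective = attr(beta, "objective")
    ),
    class = "hier_weights"
  )
}

#' Assemble the hierarchical-decomposition kernel from learned weights
#'
#' @param tree A [task_tree()].
#' @param kernels Named list of modality kernels (full cohort).
#' @param task_of Named character vector mapping sample id to task.
#' @param hw A [learn_hierarchical_weights()] result.
#' @return Kernel matrix `Khat = sum_n beta_n K_leaves(n)` where each node
#'   kernel uses that node's modality weights.
#' @export
hierarchical_mkl_kernel <- function(tree, kernels, task_of, hw) {
  nodes <- names(hw$node_weights)
  Ks <- lapply(nodes, function(node) {
    member <- task_of %in% tree$node_subsets[[node]]
    mask <- outer(member, member)
    Kn <- combine_kernels(kernels, hw$modality_weights[[node]]) * mask
    dimnames(Kn) <- dimnames(kernels[[1]])
    Kn
  })
  names(Ks) <- nodes
  K <- hierarchical_kernel(Ks, hw$node_weights)
  attr(K, "psd_status") <- "verified"
  K
}
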
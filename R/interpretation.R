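#' Histogram of projections onto the SVM normal vector
#'
#' Projects training samples onto the normal of the separating hyperplane:
#' the projection of sample i is its margin-scaled decision value `f(x_i)`.
#' Support vectors fall in the `[-1, 1]` band; samples near 0 sit close to
#' the hyperplane and are predicted with low confidence.
#'
#' @param model A [train_svm()] model.
#' @param K_train Kernel matrix over the training samples (training order).
#' @return Object of class `projection_report`: data.frame with `id`,
#'   `label`, `distance`, `is_sv`.
#' @export
projection_histogram <- function(model, K_train) {
  if (!inherits(model, "phenomkl_svm")) stop("model must come from train_svm()")
  f <- decision_values(model, K_train)
  out <- data.frame(
    id = if (!is.null(model$ids)) model$ids else seq_along(f),
    label = as.character(model$labels),
    distance = f,
    is_sv = seq_along(f) %in% model$support,
    stringsAsFactors = FALSE
  )
  class(out) <- c("projection_report", "data.frame")
  out
}

#' Split samples into low/high prediction-confidence groups
#'
#' Low confidence: distance to the hyperplane within the closed band
#' `[-threshold, threshold]`; high confidence: outside it.
#'
#' @param report A [projection_histogram()] report (or any data.frame with a
#'   `distance` column).
#' @param threshold Band half-width (default 0.5).
#' @return The report with an added `confidence` factor (`low`/`high`).
#' @export
confidence_split <- function(report, threshold = 0.5) {
  if (!"distance" %in% names(report)) stop("report lacks a distance column")
  report$confidence <- factor(
    ifelse(abs(report$distance) <= threshold, "low", "high"),
    levels = c("low", "high")
  )
  attr(report, "threshold") <- threshold
  report
}

#' Feature association between confidence groups
#'
#' Compares each feature between the low- and high-confidence groups with an
#' unpaired two-sided Wilcoxon rank-sum test (exact for small tie-free
#' groups, normal approximation with tie correction otherwise), adjusting
#' p-values across features by Benjamini-Hochberg. Features constant across
#' both groups are recorded with p = 1 and flagged.
#'
#' @param features Numeric matrix (samples x features, rows aligned with the
#'   report).
#' @param groups Factor of `"low"`/`"high"` per sample (e.g. the
#'   `confidence` column of [confidence_split()]).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return data.frame: feature, statistic, p, p_adj, significant, constant.
#' @export
feature_association <- function(features, groups, alpha = 0.05) {
  features <- as.matrix(features)
  groups <- factor(as.character(groups), levels = c("low", "high"))
  if (any(table(groups) == 0)) stop("both confidence groups must be nonempty")
  if (nrow(features) != length(groups)) stop("features / groups length mismatch")
  nm <- colnames(features)
  if (is.null(nm)) nm <- paste0("feature", seq_len(ncol(features)))
  rows <- lapply(seq_len(ncol(features)), function(j) {
    x <- features[groups == "low", j]
    z <- features[groups == "high", j]
    if (length(unique(c(x, z))) == 1L) {
      return(data.frame(feature = nm[j], statistic = NA_real_, p = 1,
                        constant = TRUE, stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, z, alternative = "two.sided"))
    data.frame(feature = nm[j], statistic = unname(wt$statistic), p = wt$p.value,
               constant = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= alpha & !out$constant
  out[, c("feature", "statistic", "p", "p_adj", "significant", "constant")]
}
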
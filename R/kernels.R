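## Kernel matrices are plain base matrices with sample ids as dimnames and a
## "psd_status" attribute ("verified", "corrected:<method>", "indefinite").

#' PSD status of a kernel matrix
#' @param K A kernel matrix.
#' @return Character status or `NA` if never assessed.
#' @export
psd_status <- function(K) {
  s <- attr(K, "psd_status")
  if (is.null(s)) NA_character_ else s
}

`psd_status<-` <- function(K, value) {
  attr(K, "psd_status") <- value
  K
}

check_symmetric <- function(S, tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("input is not a square matrix")
  scale <- max(1, max(abs(S)))
  if (max(abs(S - t(S))) > tol * scale) stop("matrix is not symmetric within tolerance")
  (S + t(S)) / 2
}

#' Radial basis function kernel on a feature table
#'
#' `k(x, z) = exp(-||x - z||^2 / (2 sigma^2))`. Entries lie in (0, 1], the
#' diagonal is exactly 1 and the matrix is positive semi-definite by
#' construction.
#'
#' @param X Numeric matrix, samples in rows (rownames = sample ids).
#' @param sigma Positive bandwidth.
#' @return Kernel matrix with `psd_status = "verified"`.
#' @export
rbf_kernel <- function(X, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) stop("sigma must be > 0")
  X <- as.matrix(X)
  bad <- !stats::complete.cases(X) | apply(X, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    who <- rownames(X)[bad]
    if (is.null(who)) who <- which(bad)
    stop("non-finite feature values for sample(s): ", paste(who, collapse = ", "))
  }
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-d2 / (2 * sigma^2))
  diag(K) <- 1
  dimnames(K) <- list(rownames(X), rownames(X))
  psd_status(K) <- "verified"
  K
}

#' Normalize a kernel matrix in feature space
#'
#' `khat(x, z) = k(x, z) / sqrt(k(x, x) k(z, z))`, so the diagonal becomes
#' exactly 1 (unit-norm feature vectors). Idempotent; for a PSD input the
#' entries lie in `[-1, 1]` by Cauchy-Schwarz.
#'
#' @param K Kernel matrix with strictly positive diagonal.
#' @return Normalized kernel matrix (PSD status preserved).
#' @export
normalize_kernel <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) {
    who <- rownames(K)[d <= 0]
    if (is.null(who)) who <- which(d <= 0)
    stop("non-positive diagonal entry for sample(s): ", paste(who, collapse = ", "))
  }
  s <- attr(K, "psd_status")
  Kn <- K / sqrt(outer(d, d))
  diag(Kn) <- 1
  dimnames(Kn) <- dimnames(K)
  attr(Kn, "psd_status") <- s
  Kn
}

#' Check positive semi-definiteness
#'
#' A symmetric matrix passes when its minimum eigenvalue is at least
#' `-tol * max(1, lambda_max)` — a relative tolerance absorbing the float
#' noise expected near zero eigenvalues.
#'
#' @param S Symmetric matrix.
#' @param tol Relative tolerance (default 1e-8).
#' @return List with `psd` (logical), `lambda_min`, `lambda_max`.
#' @export
check_psd <- function(S, tol = 1e-8) {
  S <- check_symmetric(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  lmin <- min(ev)
  list(psd = lmin >= -tol * max(1, lmax), lambda_min = lmin, lambda_max = lmax)
}

#' Nearest-PSD correction of an indefinite similarity matrix
#'
#' Spectral surgeries for similarity matrices that fail Mercer's condition
#' (e.g. Resnik/Lin similarities on multi-parent ontologies):
#' * `clip`: negative eigenvalues are set to zero (the Frobenius-nearest PSD
#'   matrix);
#' * `flip`: negative eigenvalues change sign, i.e. eigenvalues are replaced
#'   by singular values;
#' * `shift`: the spectrum is shifted up by `|lambda_min|` (adds to the
#'   diagonal only); a no-op when the input is already PSD.
#'
#' @param S Symmetric similarity matrix.
#' @param method `"clip"`, `"flip"` or `"shift"`.
#' @param tol Relative eigenvalue tolerance.
#' @return Kernel matrix with `psd_status = "corrected:<method>"` and an
#'   `eigen` attribute holding the decomposition used (for out-of-sample
#'   embedding via [embed_similarities()]).
#' @export
nearest_psd <- function(S, method = c("clip", "flip", "shift"), tol = 1e-8) {
  method <- match.arg(method)
  dn <- dimnames(S)
  S <- check_symmetric(S)
  eig <- eigen(S, symmetric = TRUE)
  l <- eig$values
  lmax <- max(l)
  if (method == "shift") {
    out <- S
    if (min(l) < -tol * max(1, lmax)) {
      out <- S + abs(min(l)) * diag(nrow(S))
    }
  } else {
    g <- if (method == "clip") pmax(l, 0) else abs(l)
    out <- eig$vectors %*% (g * t(eig$vectors))
    out <- (out + t(out)) / 2
  }
  dimnames(out) <- dn
  attr(out, "psd_status") <- paste0("corrected:", method)
  attr(out, "eigen") <- eig
  attr(out, "method") <- method
  out
}

#' Embed out-of-sample similarities into a corrected kernel
#'
#' Given cross-similarities between new samples and the training cohort,
#' applies the same spectral transform used by [nearest_psd()] on the
#' training matrix (clip/flip act through the training eigenbasis; shift
#' leaves cross-similarities unchanged).
#'
#' @param S_cross Matrix of similarities, new samples x training samples.
#' @param corrected A kernel returned by [nearest_psd()].
#' @return Matrix of embedded cross-kernel values.
#' @export
embed_similarities <- function(S_cross, corrected) {
  eig <- attr(corrected, "eigen")
  method <- attr(corrected, "method")
  if (is.null(eig) || is.null(method)) stop("`corrected` must come from nearest_psd()")
  if (ncol(S_cross) != nrow(corrected)) stop("column count must match the training cohort")
  if (method == "shift") return(S_cross)
  l <- eig$values
  g <- if (method == "clip") pmax(l, 0) else abs(l)
  ratio <- ifelse(abs(l) > 1e-12 * max(1, abs(l[1])), g / l, 0)
  S_cross %*% eig$vectors %*% (ratio * t(eig$vectors))
}
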
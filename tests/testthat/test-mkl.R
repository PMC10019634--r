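make_separable <- function(n = 20, gap = 3, seed = 1, sigma = 2) {
  set.seed(seed)
  y <- rep(c("GOF", "LOF"), each = n / 2)
  X <- matrix(rnorm(n * 2, sd = 0.5), n, 2) + ifelse(y == "GOF", gap, -gap)
  rownames(X) <- paste0("s", seq_len(n))
  list(K = rbf_kernel(X, sigma), y = factor(y, levels = c("LOF", "GOF")), X = X)
}

test_that("kernel combination respects weights and validates the stack", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  K1 <- rbf_kernel(X, 1)
  K2 <- rbf_kernel(X, 3)
  expect_equal(combine_kernels(list(K1)), K1, ignore_attr = TRUE)
  expect_equal(combine_kernels(list(K1, K1)), K1, ignore_attr = TRUE)
  expect_equal(combine_kernels(list(K1, K2), c(1, 0)), K1, ignore_attr = TRUE)
  expect_equal(combine_kernels(list(K1, K2)), (K1 + K2) / 2, ignore_attr = TRUE)
  ## nonnegative combination stays PSD
  expect_true(check_psd(combine_kernels(list(K1, K2), c(0.3, 0.7)))$psd)
  K3 <- K2[1:9, 1:9]
  expect_error(combine_kernels(list(K1, K3)), "mismatch")
  expect_error(combine_kernels(list(K1, K2), c(-1, 2)), "nonnegative")
})

test_that("SVM separates separable data and refuses indefinite kernels", {
  d <- make_separable()
  m <- train_svm(d$K, d$y, C = 100)
  f <- decision_values(m, d$K)
  expect_true(all(sign(f) == ifelse(d$y == "GOF", 1, -1)))
  expect_equal(as.character(predict(m, d$K)), as.character(d$y))
  S <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(train_svm(S, c("GOF", "LOF")), "indefinite")
  expect_error(train_svm(d$K, rep("GOF", 20)), "single class")
})

test_that("dual solution satisfies the KKT optimality conditions", {
  set.seed(9)
  for (C in c(0.5, 5)) {
    n <- 30
    y <- factor(sample(c("GOF", "LOF"), n, replace = TRUE, prob = c(.5, .5)),
                levels = c("LOF", "GOF"))
    while (length(unique(y)) < 2) y <- factor(sample(c("GOF", "LOF"), n, replace = TRUE))
    X <- matrix(rnorm(n * 3), n, 3) + ifelse(y == "GOF", 0.5, -0.5)
    rownames(X) <- paste0("s", 1:n)
    K <- rbf_kernel(X, 2)
    m <- train_svm(K, y, C = C)
    alpha <- abs(m$dual_coef)
    expect_true(all(alpha >= -1e-8 & alpha <= C + 1e-6))
    ## sum alpha_i y_i = 0
    expect_lt(abs(sum(m$dual_coef)), 1e-6)
    f <- decision_values(m, K)
    ypm <- ifelse(y == "GOF", 1, -1)
    margins <- ypm * f
    ## alpha = 0  =>  y f >= 1 - tol
    expect_true(all(margins[alpha < 1e-8] >= 1 - 1e-3))
    ## 0 < alpha < C  =>  y f = 1 within tol
    unbounded <- alpha > 1e-6 & alpha < C - 1e-6
    if (any(unbounded)) expect_true(all(abs(margins[unbounded] - 1) <= 1e-3))
    ## support vectors lie in the margin band: |f| < 1 - tol implies alpha > 0
    expect_true(all(alpha[abs(f) < 1 - 1e-3] > 0))
  }
})

test_that("decision values respect dual symmetry under label flip", {
  d <- make_separable(n = 24, gap = 1, seed = 3)
  m1 <- train_svm(d$K, d$y, C = 2)
  flipped <- factor(ifelse(d$y == "GOF", "LOF", "GOF"), levels = c("LOF", "GOF"))
  m2 <- train_svm(d$K, flipped, C = 2)
  expect_equal(decision_values(m1, d$K), -decision_values(m2, d$K), tolerance = 5e-3)
  expect_error(decision_values(m1, d$K[, 1:5]), "column")
})

test_that("global weight learning never favors a label-permuted kernel", {
  ## signal modality: features shifted by the true labels; noise modality:
  ## features shifted by permuted labels. Where inner AU-ROC plateaus the
  ## wrapper ties toward uniform weights, so the informative kernel must
  ## reach at least equal weight and dominate on average.
  hits <- 0
  ws <- numeric(10)
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60
    y <- factor(rep(c("GOF", "LOF"), each = n / 2), levels = c("LOF", "GOF"))
    X <- matrix(rnorm(n * 2), n, 2) + ifelse(y == "GOF", 0.65, -0.65)
    rownames(X) <- paste0("s", 1:n)
    yperm <- sample(y)
    Xn <- matrix(rnorm(n * 2), n, 2) + ifelse(yperm == "GOF", 0.65, -0.65)
    rownames(Xn) <- rownames(X)
    w <- learn_global_weights(
      list(signal = rbf_kernel(X, 2), noise = rbf_kernel(Xn, 2)), y,
      eval_config = list(seed = seed, k = 5)
    )
    expect_equal(sum(w), 1, tolerance = 1e-9)
    ws[seed] <- w["signal"]
    if (w["signal"] >= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 8)
  expect_gt(mean(ws), 0.55)
})

test_that("weight learning degenerate cases behave", {
  d <- make_separable(n = 20, gap = 1, seed = 2)
  w1 <- learn_global_weights(list(only = d$K), d$y)
  expect_equal(as.numeric(w1), 1)
  wdup <- learn_global_weights(list(a = d$K, b = d$K), d$y,
                               eval_config = list(k = 3))
  expect_equal(sum(wdup), 1, tolerance = 1e-9)
  expect_error(learn_global_weights(list(d$K, d$K), rep("GOF", 20)), "single class")
})

test_that("hierarchical weights localize complementary planted signals", {
  ## phenotype modality carries label signal only on tasks A and B; the
  ## other modality only on task C. The localized wrapper should weight the
  ## phenotype kernel higher at node {A, B} than at node C.
  hits <- 0
  diffs <- numeric(10)
  tr <- task_tree("((A,B),C);")
  node_ab <- names(which(sapply(tr$node_subsets, function(s) setequal(s, c("A", "B")))))
  for (seed in 1:10) {
    set.seed(seed)
    n <- 150
    ids <- paste0("s", 1:n)
    task_of <- setNames(sample(c("A", "B", "C"), n, replace = TRUE), ids)
    y <- factor(sample(c("GOF", "LOF"), n, replace = TRUE), levels = c("LOF", "GOF"))
    while (min(table(y)) < 25) {
      y <- factor(sample(c("GOF", "LOF"), n, replace = TRUE), levels = c("LOF", "GOF"))
    }
    ab <- task_of %in% c("A", "B")
    ylike <- ifelse(y == "GOF", 0.8, -0.8)
    Xp <- matrix(rnorm(n * 2), n, 2) + ifelse(ab, ylike, 0)
    rownames(Xp) <- ids
    Xn <- matrix(rnorm(n * 2), n, 2) + ifelse(!ab, ylike, 0)
    rownames(Xn) <- ids
    kernels <- list(pheno = rbf_kernel(Xp, 2), other = rbf_kernel(Xn, 2))
    hw <- learn_hierarchical_weights(tr, kernels, task_of, y,
                                     eval_config = list(k = 5, seed = seed))
    w_ab <- hw$modality_weights[[node_ab]]["pheno"]
    w_c <- hw$modality_weights[["C"]]["pheno"]
    diffs[seed] <- w_ab - w_c
    if (w_ab > w_c) hits <- hits + 1
    expect_equal(sum(hw$node_weights), 1, tolerance = 1e-9)
  }
  expect_gte(hits, 7)
  expect_gt(mean(diffs), 0.1)
})

test_that("hierarchical learning falls back to uniform weights on small blocks", {
  tr <- task_tree("(A,B);")
  set.seed(4)
  n <- 12
  ids <- paste0("s", 1:n)
  task_of <- setNames(rep(c("A", "B"), each = 6), ids)
  y <- factor(rep(c("GOF", "LOF"), 6), levels = c("LOF", "GOF"))
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(ids, NULL))
  kernels <- list(k1 = rbf_kernel(X, 1), k2 = rbf_kernel(X, 5))
  hw <- learn_hierarchical_weights(tr, kernels, task_of, y, min_block = 100,
                                   eval_config = list(k = 3))
  expect_true(all(hw$uniform_fallback))
  for (node in names(hw$modality_weights)) {
    expect_equal(unname(hw$modality_weights[[node]]), c(0.5, 0.5))
  }
  ## single-task tree reduces to global weight learning over the one block
  tr1 <- task_tree("(A);")
  task1 <- setNames(rep("A", n), ids)
  hw1 <- learn_hierarchical_weights(tr1, kernels, task1, y, eval_config = list(k = 3))
  expect_equal(sum(hw1$node_weights), 1, tolerance = 1e-9)
})
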
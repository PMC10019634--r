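#' Build a task tree from a phylogeny-style taxonomy
#'
#' Wraps an `ape` phylo object as the task taxonomy: every node `n` of the
#' tree defines the task subset `S_n = leaves(n)` (the tips of the subtree
#' rooted at `n`), leaves included as their own singleton subsets. Nodes are
#' ordered by a deterministic preorder traversal.
#'
#' @param phy An `ape::phylo` object or a Newick string.
#' @return Object of class `task_tree` with `nodes` (names, preorder),
#'   `leaves`, `node_subsets` (named list of task subsets), `node_parent`
#'   (named character, `NA` for the root) and the underlying `phylo`.
#' @export
task_tree <- function(phy) {
  if (is.character(phy)) {
    phy <- tryCatch(ape::read.tree(text = phy),
                    error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(phy) || !inherits(phy, "phylo")) stop("could not parse tree (malformed Newick?)")
  tips <- phy$tip.label
  if (anyDuplicated(tips) > 0) {
    stop("duplicate leaf name(s): ", paste(unique(tips[duplicated(tips)]), collapse = ", "))
  }
  n_tip <- length(tips)
  n_node <- phy$Nnode
  total <- n_tip + n_node
  node_name <- character(total)
  node_name[seq_len(n_tip)] <- tips
  internal_labels <- phy$node.label
  for (i in seq_len(n_node)) {
    lab <- if (!is.null(internal_labels) && nzchar(internal_labels[i])) internal_labels[i] else paste0("node", i)
    node_name[n_tip + i] <- lab
  }
  if (anyDuplicated(node_name) > 0) stop("node labels collide with leaf names")

  parent_of <- rep(NA_integer_, total)
  kids <- vector("list", total)
  if (!is.null(phy$edge)) {
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]
      c <- phy$edge[e, 2]
      parent_of[c] <- p
      kids[[p]] <- c(kids[[p]], c)
    }
  }
  root <- if (total == 1L) 1L else setdiff(seq_len(total), phy$edge[, 2])
  if (length(root) != 1L) stop("tree must have exactly one root")

  ## preorder traversal
  order <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[1]
    stack <- stack[-1]
    order <- c(order, v)
    stack <- c(kids[[v]], stack)
  }

  subsets <- vector("list", total)
  for (v in rev(order)) {
    subsets[[v]] <- if (v <= n_tip) node_name[v] else {
      sort(unique(unlist(subsets[kids[[v]]], use.names = FALSE)))
    }
  }
  names(subsets) <- node_name
  structure(
    list(
      nodes = node_name[order],
      leaves = tips,
      node_subsets = subsets[node_name[order]],
      node_parent = stats::setNames(
        ifelse(is.na(parent_of[order]), NA_character_, node_name[parent_of[order]]),
        node_name[order]
      ),
      root = node_name[root],
      phylo = phy
    ),
    class = "task_tree"
  )
}

#' Read a task taxonomy from a Newick file
#' @param path Path to a Newick file.
#' @return A [task_tree()].
#' @export
read_task_tree <- function(path) {
  phy <- tryCatch(ape::read.tree(path), error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("could not parse Newick file ", path)
  task_tree(phy)
}

#' @export
print.task_tree <- function(x, ...) {
  cat("Task tree:", length(x$leaves), "tasks,", length(x$nodes), "nodes\n")
  invisible(x)
}

## ancestor node names (reflexive: leaf itself up to root) of a leaf
leaf_ancestor_nodes <- function(tree, leaf) {
  path <- leaf
  while (!is.na(tree$node_parent[[path[length(path)]]])) {
    path <- c(path, tree$node_parent[[path[length(path)]]])
  }
  path
}

#' Taxonomy-based task similarity
#'
#' Tree-alignment similarity between tasks: with `c(s, t)` the number of
#' common ancestor nodes of leaves `s` and `t` (counting the leaf itself and
#' the root) and `c_max = max_s c(s, s)`, the similarity is
#' `K_task(s, t) = (a + c(s, t)) / (a + c_max)`. The baseline parameter
#' `a > 0` controls how much unrelated tasks still share: as `a` grows all
#' entries tend to 1 (the pooled "Union" limit); small `a` approaches the
#' task-exclusive "Dirac" regime.
#'
#' @param tree A [task_tree()].
#' @param a Positive baseline similarity parameter.
#' @return Symmetric task-by-task matrix with attribute `baseline`.
#' @export
task_similarity <- function(tree, a) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stop("a must be > 0")
  leaves <- tree$leaves
  anc <- lapply(leaves, leaf_ancestor_nodes, tree = tree)
  names(anc) <- leaves
  n <- length(leaves)
  cmat <- matrix(0, n, n, dimnames = list(leaves, leaves))
  for (i in seq_len(n)) {
    for (j in i:n) {
      cmat[i, j] <- cmat[j, i] <- length(intersect(anc[[i]], anc[[j]]))
    }
  }
  cmax <- max(diag(cmat))
  K <- (a + cmat) / (a + cmax)
  attr(K, "baseline") <- a
  K
}

#' Expand a task similarity matrix to sample level
#'
#' Produces the sample-by-sample "task modality" kernel whose entry (i, j)
#' is the similarity of the tasks of samples i and j.
#'
#' @param K_task Task similarity matrix.
#' @param task_of Named character vector mapping sample id to task.
#' @return Sample-level kernel matrix.
#' @export
task_kernel <- function(K_task, task_of) {
  unknown <- setdiff(unique(task_of), rownames(K_task))
  if (length(unknown) > 0) stop("unknown task(s): ", paste(unknown, collapse = ", "))
  K <- K_task[task_of, task_of, drop = FALSE]
  dimnames(K) <- list(names(task_of), names(task_of))
  K
}

#' Multi-task kernel (Schur product with task similarity)
#'
#' Entry (i, j) is `K_task(task_i, task_j) * K_base(i, j)`; with both
#' factors PSD the product is PSD. With an identity task matrix this gives
#' the block-diagonal per-task (Dirac) kernel; with an all-ones matrix it
#' returns the pooled (Union) kernel unchanged.
#'
#' @param K_base Sample-level base kernel.
#' @param task_of Named character vector mapping sample id to task.
#' @param K_task Task similarity matrix.
#' @return Kernel matrix.
#' @export
multitask_kernel <- function(K_base, task_of, K_task) {
  Kt <- task_kernel(K_task, task_of)
  if (!all(dim(Kt) == dim(K_base))) stop("task map and base kernel size mismatch")
  K <- Kt * K_base
  dimnames(K) <- dimnames(K_base)
  s1 <- attr(K_base, "psd_status")
  if (!is.null(s1) && s1 %in% c("verified", paste0("corrected:", c("clip", "flip", "shift")))) {
    attr(K, "psd_status") <- "verified"
  }
  K
}

#' Per-node task-subset kernels
#'
#' For each node `n` of the taxonomy, the kernel restricted to samples whose
#' task belongs to `leaves(n)`: entries outside the subset block are 0. Each
#' restriction of a PSD kernel is PSD.
#'
#' @param tree A [task_tree()].
#' @param K Sample-level kernel (the modality to localize).
#' @param task_of Named character vector mapping sample id to task.
#' @return Named list (preorder nodes) of kernel matrices.
#' @export
subset_kernels <- function(tree, K, task_of) {
  unknown <- setdiff(unique(task_of), tree$leaves)
  if (length(unknown) > 0) stop("unknown task(s): ", paste(unknown, collapse = ", "))
  out <- lapply(tree$nodes, function(n) {
    member <- task_of %in% tree$node_subsets[[n]]
    mask <- outer(member, member)
    Kn <- K * mask
    dimnames(Kn) <- dimnames(K)
    Kn
  })
  names(out) <- tree$nodes
  out
}

#' Hierarchical-decomposition kernel
#'
#' `Khat = sum_n beta_n K_leaves(n)`: the weighted sum of the per-node
#' subset kernels, the localized multiple-kernel combination over the task
#' taxonomy. Weight all mass on the root and the pooled Union kernel is
#' recovered; spread it uniformly over the leaves and the block-diagonal
#' Dirac kernel (scaled) appears.
#'
#' @param kernels Named list of subset kernels (from [subset_kernels()]).
#' @param beta Named nonnegative node weights summing to 1.
#' @return Kernel matrix.
#' @export
hierarchical_kernel <- function(kernels, beta) {
  if (is.null(names(beta)) || !setequal(names(beta), names(kernels))) {
    stop("weight names must match subset-kernel node names")
  }
  if (any(beta < 0) || abs(sum(beta) - 1) > 1e-8) stop("beta must be nonnegative and sum to 1")
  K <- Reduce(`+`, Map(function(b, k) b * k, beta[names(kernels)], kernels))
  dimnames(K) <- dimnames(kernels[[1]])
  K
}

#' Latent task similarity from hierarchical weights
#'
#' `gamma(k, l) = sum of beta_n over nodes n whose subset contains both
#' tasks` — the data-driven refinement of the prior taxonomy similarity.
#' Symmetric and diagonally dominant (`gamma(k, k) >= gamma(k, l)`).
#'
#' @param tree A [task_tree()].
#' @param beta Named node weights (nonnegative, simplex).
#' @return Task-by-task matrix of latent similarities.
#' @export
latent_task_similarity <- function(tree, beta) {
  if (is.null(names(beta)) || !setequal(names(beta), tree$nodes)) {
    stop("beta must be named by the tree's nodes")
  }
  leaves <- tree$leaves
  n <- length(leaves)
  G <- matrix(0, n, n, dimnames = list(leaves, leaves))
  for (node in tree$nodes) {
    s <- tree$node_subsets[[node]]
    member <- leaves %in% s
    G <- G + beta[[node]] * outer(member, member)
  }
  G
}
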
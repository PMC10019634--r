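#' Generate a random single-root DAG ontology
#'
#' Terms are created in order; each non-root term receives 1..`max_parents`
#' parents among earlier terms, so the graph is acyclic by construction,
#' reaches a single root, and (for `max_parents > 1`) exhibits the
#' multi-parent structure that makes IC-based similarity matrices
#' indefinite.
#'
#' @param n_terms Number of terms (>= 2).
#' @param max_parents Maximum parents per term.
#' @param seed Integer seed.
#' @return An [ontology_graph()].
#' @export
generate_ontology <- function(n_terms = 446, max_parents = 3, seed = 1) {
  if (n_terms < 2L) stop("n_terms must be >= 2")
  if (max_parents < 1L) stop("max_parents must be >= 1")
  set.seed(seed)
  ids <- sprintf("T%04d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- ids
  parents[[1]] <- character(0)
  for (i in 2:n_terms) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    parents[[i]] <- sample(ids[seq_len(i - 1L)], k)
  }
  ontology_graph(parents)
}

default_task_newick <- "(((task1,task2,task3),(task4,task5)),((task6,task7),(task8,task9)));"

#' Synthetic cohort configuration
#'
#' Defaults mirror the cohort the framework targets: 375 variants over 9
#' channels (tasks) in a two-level family taxonomy, 62 numeric features,
#' 164/375 GOF, a 446-term multi-parent ontology, and raw annotation sizes
#' with mean 9 in range 3-42 terms per variant.
#'
#' @param n_terms,max_parents Ontology size and parent bound.
#' @param n_tasks Number of tasks (channels).
#' @param tree_topology `"default"` (9-leaf two-level tree), `"random"`, or
#'   a Newick string.
#' @param n_variants Cohort size.
#' @param class_balance Probability of the GOF label.
#' @param feature_dim Number of numeric features.
#' @param feature_effect Class mean shift per feature, in SD units.
#' @param phenotype_effect Probability a drawn term comes from the
#'   class-preferred pool (0 = no phenotypic signal).
#' @param task_effect Probability a (non-class) drawn term comes from the
#'   task-preferred pool.
#' @param terms_mean,terms_range Mean and clip range of raw set sizes.
#' @param seed Integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_terms = 446, max_parents = 3, n_tasks = 9,
                             tree_topology = "default", n_variants = 375,
                             class_balance = 164 / 375, feature_dim = 62,
                             feature_effect = 0.15, phenotype_effect = 0.5,
                             task_effect = 0.3, terms_mean = 9,
                             terms_range = c(3, 42), seed = 1) {
  cfg <- list(
    n_terms = n_terms, max_parents = max_parents, n_tasks = n_tasks,
    tree_topology = tree_topology, n_variants = n_variants,
    class_balance = class_balance, feature_dim = feature_dim,
    feature_effect = feature_effect, phenotype_effect = phenotype_effect,
    task_effect = task_effect, terms_mean = terms_mean,
    terms_range = terms_range, seed = seed
  )
  stopifnot(
    n_terms >= 2, n_tasks >= 1, n_variants >= 2, feature_dim >= 1,
    class_balance > 0, class_balance < 1,
    phenotype_effect >= 0, phenotype_effect <= 1,
    task_effect >= 0, task_effect <= 1
  )
  if (terms_range[1] > n_terms) stop("terms_range infeasible for n_terms")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a complete synthetic cohort
#'
#' Emulates the statistical structure the pipeline assumes: class-dependent
#' phenotype term usage (the genotype-phenotype correlation that the
#' phenotype kernel can exploit), class-shifted Gaussian features with
#' task-level random intercepts, and a task taxonomy. Ground-truth effect
#' parameters are recorded for recovery tests. Deterministic given the
#' config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return Object of class `c("synthetic_cohort", "mkl_dataset")` with
#'   fields `ids`, `features`, `term_sets`, `tasks`, `labels`, `ontology`,
#'   `tree`, `config`, `ground_truth`.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  graph <- generate_ontology(cfg$n_terms, cfg$max_parents, seed = cfg$seed)
  set.seed(cfg$seed + 1L)

  ## task taxonomy
  if (identical(cfg$tree_topology, "default") && cfg$n_tasks == 9) {
    tree <- task_tree(default_task_newick)
  } else if (identical(cfg$tree_topology, "default") || identical(cfg$tree_topology, "random")) {
    phy <- ape::rtree(cfg$n_tasks, tip.label = paste0("task", seq_len(cfg$n_tasks)))
    tree <- task_tree(phy)
  } else {
    tree <- task_tree(cfg$tree_topology)
  }
  task_names <- tree$leaves

  n <- cfg$n_variants
  ids <- sprintf("V%04d", seq_len(n))
  tasks <- stats::setNames(sample(task_names, n, replace = TRUE), ids)
  labels <- ifelse(stats::runif(n) < cfg$class_balance, "GOF", "LOF")
  if (length(unique(labels)) < 2L) labels[1] <- setdiff(c("GOF", "LOF"), labels[1])
  labels <- factor(labels, levels = c("LOF", "GOF"))

  ## features: task random intercept + class mean shift + unit noise
  d <- cfg$feature_dim
  task_int <- matrix(stats::rnorm(length(task_names) * d, sd = 0.5),
                     nrow = length(task_names), dimnames = list(task_names, NULL))
  shift <- ifelse(labels == "GOF", cfg$feature_effect / 2, -cfg$feature_effect / 2)
  X <- task_int[tasks, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d) +
    matrix(shift, n, d)
  rownames(X) <- ids
  colnames(X) <- sprintf("f%02d", seq_len(d))

  ## term pools: disjoint class- and task-preferred subsets of non-root terms
  candidates <- setdiff(graph$terms, graph$root)
  pool_size <- max(1L, floor(0.15 * length(candidates)))
  shuffled <- sample(candidates)
  class_pools <- list(
    GOF = shuffled[seq_len(pool_size)],
    LOF = shuffled[pool_size + seq_len(pool_size)]
  )
  remaining <- shuffled[-seq_len(2 * pool_size)]
  task_take <- max(1L, floor(length(remaining) / length(task_names)))
  task_pools <- list()
  for (i in seq_along(task_names)) {
    take <- min(task_take, length(remaining))
    if (take == 0L) remaining <- shuffled
    take <- max(1L, min(task_take, length(remaining)))
    task_pools[[task_names[i]]] <- remaining[seq_len(take)]
    remaining <- remaining[-seq_len(take)]
  }

  sizes <- pmin(pmax(stats::rpois(n, cfg$terms_mean), cfg$terms_range[1]), cfg$terms_range[2])
  term_sets <- vector("list", n)
  for (i in seq_len(n)) {
    sz <- sizes[i]
    n_class <- stats::rbinom(1, sz, cfg$phenotype_effect)
    n_task <- stats::rbinom(1, sz - n_class, cfg$task_effect)
    n_unif <- sz - n_class - n_task
    cp <- class_pools[[as.character(labels[i])]]
    tp <- task_pools[[tasks[i]]]
    raw <- unique(c(
      sample(cp, min(n_class, length(cp))),
      sample(tp, min(n_task, length(tp)))
    ))
    need <- sz - length(raw)
    if (need > 0) {
      pool_rest <- setdiff(candidates, raw)
      raw <- c(raw, sample(pool_rest, min(need, length(pool_rest))))
    }
    term_sets[[i]] <- term_set(ids[i], raw, graph)
  }

  structure(
    list(
      ids = ids, features = X, term_sets = term_sets, tasks = tasks,
      labels = labels, ontology = graph, tree = tree, config = cfg,
      ground_truth = list(class_pools = class_pools, task_pools = task_pools,
                          feature_shift = cfg$feature_effect)
    ),
    class = c("synthetic_cohort", "mkl_dataset")
  )
}

#' @export
print.mkl_dataset <- function(x, ...) {
  cat("mkl_dataset:", length(x$ids), "variants,",
      length(unique(x$tasks)), "tasks,",
      ncol(x$features), "features,",
      length(x$ontology$terms), "ontology terms\n")
  cat("  labels:", paste(names(table(x$labels)), as.integer(table(x$labels)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write an ontology graph as an OBO flat file
#' @param graph An [ontology_graph()].
#' @param path Output path.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2\n", con)
  for (t in graph$terms) {
    lines <- c("[Term]", paste0("id: ", t), paste0("name: ", t))
    ps <- graph$parents[[t]]
    if (length(ps) > 0) lines <- c(lines, paste0("is_a: ", ps))
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Write a cohort to the plain-text formats the pipeline reads
#'
#' Creates `ontology.obo`, `annotations.tsv` (variant_id, pipe-separated raw
#' term ids), `features.csv`, `tree.nwk` and `labels.csv` (variant_id, task,
#' label) in `dir`. Round-trips through [load_dataset()].
#'
#' @param cohort An `mkl_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(cohort$ontology, file.path(dir, "ontology.obo"))
  ann <- data.frame(
    variant_id = vapply(cohort$term_sets, `[[`, character(1), "variant_id"),
    terms = vapply(cohort$term_sets, function(ts) paste(ts$raw_terms, collapse = "|"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  feat <- data.frame(variant_id = rownames(cohort$features), cohort$features,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE, quote = FALSE)
  ape::write.tree(cohort$tree$phylo, file.path(dir, "tree.nwk"))
  lab <- data.frame(variant_id = cohort$ids, task = unname(cohort$tasks[cohort$ids]),
                    label = as.character(cohort$labels), stringsAsFactors = FALSE)
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
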
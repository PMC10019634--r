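#' Read a variant annotation table
#'
#' TSV with columns `variant_id` and `terms` (pipe-separated ontology term
#' ids).
#'
#' @param path Path to the TSV file.
#' @return Named list of raw term-id vectors, keyed by variant id.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "terms") %in% names(tab))) {
    stop("annotation file must have columns variant_id, terms")
  }
  if (anyDuplicated(tab$variant_id) > 0) {
    stop("duplicate variant id(s) in annotations: ",
         paste(unique(tab$variant_id[duplicated(tab$variant_id)]), collapse = ", "))
  }
  stats::setNames(strsplit(tab$terms, "|", fixed = TRUE), tab$variant_id)
}

#' Read a numeric feature table
#'
#' CSV with a `variant_id` column followed by numeric feature columns.
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix with variant ids as rownames.
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"variant_id" %in% names(tab)) stop("features file must have a variant_id column")
  if (anyDuplicated(tab$variant_id) > 0) stop("duplicate variant id(s) in features")
  X <- as.matrix(tab[, setdiff(names(tab), "variant_id"), drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in feature table")
  rownames(X) <- tab$variant_id
  X
}

#' Read variant labels and task assignments
#'
#' CSV with columns `variant_id`, `task`, `label` (`GOF`/`LOF`; may be empty
#' or NA for prediction-only variants).
#'
#' @param path Path to the CSV file.
#' @return data.frame with those three columns.
#' @export
read_labels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "task", "label") %in% names(tab))) {
    stop("labels file must have columns variant_id, task, label")
  }
  if (anyDuplicated(tab$variant_id) > 0) stop("duplicate variant id(s) in labels")
  bad <- !is.na(tab$label) & nzchar(tab$label) & !tab$label %in% c("GOF", "LOF")
  if (any(bad)) stop("invalid label(s): ", paste(unique(tab$label[bad]), collapse = ", "))
  tab
}

#' Load a complete dataset from its component files
#'
#' Inner-joins annotations, features and labels on `variant_id` (variants
#' missing any component are dropped with a message), validates term ids
#' against the ontology and propagates term sets.
#'
#' @param dir Directory containing `ontology.obo`, `annotations.tsv`,
#'   `features.csv`, `tree.nwk`, `labels.csv`; individual paths override.
#' @param ontology,annotations,features,tree,labels Optional explicit paths.
#' @return An `mkl_dataset`.
#' @export
load_dataset <- function(dir = NULL, ontology = NULL, annotations = NULL,
                         features = NULL, tree = NULL, labels = NULL) {
  pick <- function(p, default) if (!is.null(p)) p else file.path(dir, default)
  graph <- read_obo(pick(ontology, "ontology.obo"))
  ann <- read_annotations(pick(annotations, "annotations.tsv"))
  X <- read_features(pick(features, "features.csv"))
  ttree <- read_task_tree(pick(tree, "tree.nwk"))
  lab <- read_labels(pick(labels, "labels.csv"))

  ids <- Reduce(intersect, list(names(ann), rownames(X), lab$variant_id))
  if (length(ids) == 0L) stop("no variant ids shared across annotations, features and labels")
  dropped <- length(unique(c(names(ann), rownames(X), lab$variant_id))) - length(ids)
  if (dropped > 0) message("dropped ", dropped, " variant(s) missing from at least one input")

  lab <- lab[match(ids, lab$variant_id), ]
  unknown_tasks <- setdiff(unique(lab$task), ttree$leaves)
  if (length(unknown_tasks) > 0) {
    stop("task(s) not in the taxonomy: ", paste(unknown_tasks, collapse = ", "))
  }
  term_sets <- lapply(ids, function(id) term_set(id, ann[[id]], graph))
  labels_f <- factor(lab$label, levels = c("LOF", "GOF"))
  structure(
    list(
      ids = ids, features = X[ids, , drop = FALSE], term_sets = term_sets,
      tasks = stats::setNames(lab$task, ids), labels = labels_f,
      ontology = graph, tree = ttree
    ),
    class = "mkl_dataset"
  )
}

#' Write a kernel matrix as CSV with a metadata sidecar
#'
#' The CSV has a header row of sample ids and one row per sample; the
#' sidecar JSON (same path + `.json`) records the measure/correction
#' provenance and PSD status.
#'
#' @param K Kernel matrix.
#' @param path Output CSV path.
#' @param meta Named list of extra metadata fields.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(K, path, meta = list()) {
  utils::write.csv(as.data.frame(K), path, row.names = TRUE, quote = FALSE)
  meta$psd_status <- psd_status(K)
  meta$n <- nrow(K)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a kernel matrix written by [write_kernel_csv()]
#' @param path CSV path.
#' @return Kernel matrix (with `psd_status` restored from the sidecar if
#'   present).
#' @export
read_kernel_csv <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  K <- as.matrix(tab)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$psd_status)) attr(K, "psd_status") <- meta$psd_status
  }
  K
}

write_provenance <- function(dir, command, args, seed = NULL) {
  jsonlite::write_json(
    list(command = command, args = as.list(args), seed = seed,
         package_version = as.character(utils::packageVersion("phenomkl")),
         r_version = R.version.string, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE
  )
}
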
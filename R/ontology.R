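#' Construct an ontology graph from parent relations
#'
#' Builds the directed acyclic graph of ontology terms from `is_a`
#' (parent <- child) relations. The graph must have exactly one root (a term
#' with no parents) and every term must reach the root along parent edges.
#' Reflexive ancestor closures are precomputed for fast term-set propagation.
#'
#' @param parents Named list: for each term id, a character vector of parent
#'   term ids (empty for the root).
#' @return An object of class `ontology_graph` with elements `terms`,
#'   `parents`, `root` and `ancestors` (reflexive ancestor sets per term).
#' @export
ontology_graph <- function(parents) {
  terms <- names(parents)
  if (is.null(terms) || anyDuplicated(terms) > 0) {
    stop("`parents` must be a uniquely named list of terms")
  }
  all_parents <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(all_parents, terms)
  if (length(unknown) > 0) {
    stop("unknown parent term id(s): ", paste(unknown, collapse = ", "))
  }
  roots <- terms[vapply(parents, length, integer(1)) == 0L]
  if (length(roots) == 0L) {
    stop("no root term found (cycle among all terms?)")
  }
  if (length(roots) > 1L) {
    stop("multiple parentless terms found: ", paste(roots, collapse = ", "))
  }

  ## Kahn topological sort; also detects cycles.
  n_par <- vapply(parents, length, integer(1))
  children <- split(rep(terms, n_par), unlist(parents, use.names = FALSE))
  indeg <- n_par
  names(indeg) <- terms
  queue <- roots
  topo <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(terms)) {
    cyc <- setdiff(terms, topo)
    stop("cycle detected in ontology; involved term(s) include: ", cyc[1])
  }

  ## Reflexive ancestor closure in topological order.
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (v in topo) {
    anc[[v]] <- unique(c(v, unlist(anc[parents[[v]]], use.names = FALSE)))
  }

  structure(
    list(terms = terms, parents = parents, root = roots, ancestors = anc),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("Ontology graph:", length(x$terms), "terms, root =", x$root, "\n")
  invisible(x)
}

#' Parse an OBO flat file
#'
#' Reads the subset of OBO used for phenotype ontologies: `[Term]` stanzas
#' with `id`, `name`, `is_a` and `is_obsolete` tags. Obsolete terms are
#' dropped. Only `is_a` relations are honored.
#'
#' @param path Path to an OBO file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(0)
  parents <- list()
  for (i in seq_along(stanza_starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    ## stanza ends at the next header line
    hdr <- grep("^\\[", block)
    if (length(hdr) > 1L) block <- block[seq_len(hdr[2] - 1L)]
    get_tag <- function(tag) {
      v <- sub(paste0("^", tag, ":\\s*"), "", grep(paste0("^", tag, ":"), block, value = TRUE))
      sub("\\s*(!.*)?$", "", v)
    }
    id <- get_tag("id")
    if (length(id) != 1L) stop("OBO stanza without a unique id tag")
    if (any(grepl("true", get_tag("is_obsolete")))) next
    isa <- get_tag("is_a")
    ## strip trailing name comments like "HP:1 ! All"
    isa <- sub("\\s.*$", "", isa)
    isa <- isa[nzchar(isa)]
    ids <- c(ids, id)
    parents[[id]] <- isa
  }
  parents <- parents[ids]
  ## drop is_a references to obsolete (absent) terms only if they are unknown
  ontology_graph(parents)
}

#' Propagate a raw term set to its ancestor closure
#'
#' Returns the reflexive transitive closure of `raw` under parent edges:
#' every annotated term plus all of its ancestors up to the root.
#' Idempotent and monotone.
#'
#' @param graph An [ontology_graph()].
#' @param raw Character vector of term ids.
#' @return Character vector (sorted) of propagated term ids.
#' @export
propagate <- function(graph, raw) {
  unknown <- setdiff(raw, graph$terms)
  if (length(unknown) > 0) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  }
  sort(unique(unlist(graph$ancestors[raw], use.names = FALSE)))
}

#' Construct a variant term set
#'
#' Couples a variant id with its raw ontology annotations and their
#' propagated ancestor closure.
#'
#' @param variant_id Identifier.
#' @param raw Character vector of annotated term ids (nonempty).
#' @param graph An [ontology_graph()] used for propagation.
#' @return Object of class `term_set` with fields `variant_id`, `raw_terms`,
#'   `propagated_terms`.
#' @export
term_set <- function(variant_id, raw, graph) {
  if (length(raw) == 0L) stop("raw term set for ", variant_id, " is empty")
  structure(
    list(
      variant_id = as.character(variant_id),
      raw_terms = sort(unique(as.character(raw))),
      propagated_terms = propagate(graph, raw)
    ),
    class = "term_set"
  )
}

#' Information content of terms over a corpus of term sets
#'
#' For each term occurring in at least one propagated set, the frequency
#' `f` is the fraction of sets containing the term and the information
#' content is `-log2(f)` (bits). The root, present in every propagated set,
#' has IC 0. Terms occurring in no set are absent from the map; looking
#' them up downstream is an error.
#'
#' @param corpus List of [term_set()] objects (propagated).
#' @return Object of class `ic_map` with `ic` (named numeric, bits) and
#'   `corpus_size`.
#' @export
information_content <- function(corpus) {
  if (length(corpus) == 0L) stop("corpus is empty")
  all_terms <- unlist(lapply(corpus, `[[`, "propagated_terms"), use.names = FALSE)
  counts <- table(all_terms)
  f <- as.numeric(counts) / length(corpus)
  ic <- -log2(f)
  names(ic) <- names(counts)
  structure(list(ic = ic, corpus_size = length(corpus)), class = "ic_map")
}

#' Most informative common ancestor of two terms
#'
#' Ancestor sets are reflexive (a term is its own ancestor), so
#' `mica(g, ic, t, t)` returns `t` itself. Ties on IC are broken toward the
#' lexicographically smallest term id.
#'
#' @param graph An [ontology_graph()].
#' @param ic An [information_content()] map covering all common ancestors.
#' @param t1,t2 Term ids.
#' @return List with `term` and `ic`.
#' @export
mica <- function(graph, ic, t1, t2) {
  for (t in c(t1, t2)) {
    if (!t %in% graph$terms) stop("unknown term id: ", t)
  }
  common <- intersect(graph$ancestors[[t1]], graph$ancestors[[t2]])
  missing_ic <- setdiff(common, names(ic$ic))
  if (length(missing_ic) > 0) {
    stop(
      "term(s) absent from the IC map: ", paste(missing_ic, collapse = ", "),
      " (IC corpus must contain the propagated sets the query terms come from)"
    )
  }
  vals <- ic$ic[common]
  best <- vals == max(vals)
  term <- sort(common[best])[1]
  list(term = term, ic = unname(ic$ic[term]))
}

## Pairwise term-score matrix: entry (i, j) = IC of the MICA of terms i, j.
## Works on a fixed term vector; vectorized by filling, for each term, the
## other terms that share its highest-IC ancestors first.
term_mica_matrix <- function(graph, ic, terms) {
  missing_ic <- setdiff(terms, names(ic$ic))
  if (length(missing_ic) > 0) {
    stop("term(s) absent from the IC map: ", paste(missing_ic, collapse = ", "))
  }
  m <- length(terms)
  anc <- graph$ancestors[terms]
  anc_union <- sort(unique(unlist(anc, use.names = FALSE)))
  missing_anc <- setdiff(anc_union, names(ic$ic))
  if (length(missing_anc) > 0) {
    stop("ancestor term(s) absent from the IC map: ", paste(missing_anc, collapse = ", "))
  }
  ## incidence: A[i, k] TRUE if ancestor k is an ancestor of term i
  A <- matrix(FALSE, m, length(anc_union), dimnames = list(terms, anc_union))
  for (i in seq_len(m)) A[i, anc[[i]]] <- TRUE
  icv <- ic$ic[anc_union]
  M <- matrix(NA_real_, m, m, dimnames = list(terms, terms))
  for (i in seq_len(m)) {
    ord <- order(icv[anc[[i]]], decreasing = TRUE)
    for (k in anc[[i]][ord]) {
      todo <- is.na(M[i, ]) & A[, k]
      if (any(todo)) M[i, todo] <- icv[[k]]
      if (!anyNA(M[i, ])) break
    }
  }
  M
}

## Lin score matrix from a Resnik (MICA-IC) matrix: 2*IC(MICA)/(IC(a)+IC(b)),
## defined as 0 when both terms carry zero information.
term_lin_matrix <- function(M, ic) {
  terms <- rownames(M)
  icv <- ic$ic[terms]
  denom <- outer(icv, icv, `+`)
  L <- ifelse(denom > 0, 2 * M / denom, 0)
  dimnames(L) <- dimnames(M)
  L
}

## Best-match aggregation of a term-score matrix over two index sets.
best_match <- function(S, ia, ib, aggregate = "best_match") {
  sub <- S[ia, ib, drop = FALSE]
  switch(aggregate,
    best_match = (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2,
    max = max(sub),
    mean = mean(sub),
    stop("unknown aggregate: ", aggregate)
  )
}

#' Semantic similarity between two variant term sets
#'
#' Jaccard operates on set overlap; Resnik scores a term pair by the IC of
#' its most informative common ancestor and Lin rescales that by the ICs of
#' the two terms, `2*IC(MICA)/(IC(t1)+IC(t2))` (0 when both ICs are 0).
#' Pairwise Resnik/Lin scores are aggregated across the two sets by the
#' symmetric best-match average
#' `(mean_a max_b s(a,b) + mean_b max_a s(a,b)) / 2` by default.
#'
#' @param measure One of `"jaccard"`, `"resnik"`, `"lin"`.
#' @param a,b [term_set()] objects.
#' @param graph An [ontology_graph()].
#' @param ic An [information_content()] map (required for resnik/lin).
#' @param aggregate Set-level aggregation for resnik/lin: `"best_match"`
#'   (default), `"max"` or `"mean"`.
#' @param sets Which term sets the measure operates on: `"propagated"` for
#'   jaccard (default) and `"raw"` for resnik/lin (default); MICA scoring
#'   always uses propagated ancestors.
#' @return A single numeric similarity.
#' @export
set_similarity <- function(measure = c("jaccard", "resnik", "lin"), a, b,
                           graph, ic = NULL,
                           aggregate = c("best_match", "max", "mean"),
                           sets = NULL) {
  measure <- match.arg(measure)
  aggregate <- match.arg(aggregate)
  if (is.null(sets)) sets <- if (measure == "jaccard") "propagated" else "raw"
  sets <- match.arg(sets, c("propagated", "raw"))
  field <- if (sets == "propagated") "propagated_terms" else "raw_terms"
  ta <- a[[field]]
  tb <- b[[field]]
  if (length(ta) == 0L && length(tb) == 0L) stop("both term sets are empty")
  if (measure == "jaccard") {
    return(length(intersect(ta, tb)) / length(union(ta, tb)))
  }
  if (is.null(ic)) stop("resnik/lin require an IC map")
  terms <- sort(unique(c(ta, tb)))
  M <- term_mica_matrix(graph, ic, terms)
  if (measure == "lin") M <- term_lin_matrix(M, ic)
  best_match(M, match(ta, terms), match(tb, terms), aggregate)
}

#' Pairwise semantic-similarity matrix over a corpus
#'
#' Computes the n-by-n matrix of [set_similarity()] values over a corpus of
#' variant term sets, vectorized through a shared term-pair score matrix.
#' Jaccard matrices over propagated sets are positive semi-definite; Resnik
#' and Lin matrices on multi-parent ontologies may be indefinite and should
#' be passed through [nearest_psd()] before kernel learning.
#'
#' @inheritParams set_similarity
#' @param corpus List of [term_set()] objects (at least 2).
#' @return Symmetric numeric matrix with variant ids as dimnames and
#'   attribute `measure`.
#' @export
similarity_matrix <- function(measure = c("jaccard", "resnik", "lin"), corpus,
                              graph, ic = NULL,
                              aggregate = c("best_match", "max", "mean"),
                              sets = NULL) {
  measure <- match.arg(measure)
  aggregate <- match.arg(aggregate)
  if (length(corpus) < 2L) stop("need at least 2 term sets")
  ids <- vapply(corpus, `[[`, character(1), "variant_id")
  if (is.null(sets)) sets <- if (measure == "jaccard") "propagated" else "raw"
  sets <- match.arg(sets, c("propagated", "raw"))
  field <- if (sets == "propagated") "propagated_terms" else "raw_terms"
  term_lists <- lapply(corpus, `[[`, field)
  n <- length(corpus)

  if (measure == "jaccard") {
    terms <- sort(unique(unlist(term_lists, use.names = FALSE)))
    B <- matrix(0, n, length(terms), dimnames = list(ids, terms))
    for (i in seq_len(n)) B[i, term_lists[[i]]] <- 1
    inter <- B %*% t(B)
    sizes <- rowSums(B)
    uni <- outer(sizes, sizes, `+`) - inter
    S <- inter / uni
  } else {
    if (is.null(ic)) stop("resnik/lin require an IC map")
    prop_terms <- unique(unlist(lapply(corpus, `[[`, "propagated_terms"), use.names = FALSE))
    if (length(setdiff(prop_terms, names(ic$ic))) > 0) {
      stop("IC map does not cover the corpus (propagated sets / IC corpus mismatch)")
    }
    terms <- sort(unique(unlist(term_lists, use.names = FALSE)))
    M <- term_mica_matrix(graph, ic, terms)
    if (measure == "lin") M <- term_lin_matrix(M, ic)
    idx <- lapply(term_lists, match, table = terms)
    if (aggregate == "mean") {
      R <- matrix(0, n, length(terms))
      for (i in seq_len(n)) R[i, idx[[i]]] <- 1 / length(idx[[i]])
      S <- R %*% M %*% t(R)
      S <- (S + t(S)) / 2
    } else {
      ## best_to_set[t, j] = max over terms b of variant j of score(t, b)
      best_to_set <- vapply(idx, function(j) {
        do.call(pmax, as.data.frame(M[, j, drop = FALSE]))
      }, numeric(length(terms)))
      if (aggregate == "max") {
        S <- matrix(0, n, n)
        for (i in seq_len(n)) S[i, ] <- apply(best_to_set[idx[[i]], , drop = FALSE], 2, max)
        S <- pmax(S, t(S))
      } else {
        R <- matrix(0, n, length(terms))
        for (i in seq_len(n)) R[i, idx[[i]]] <- 1 / length(idx[[i]])
        S1 <- R %*% best_to_set
        S <- (S1 + t(S1)) / 2
      }
    }
    dimnames(S) <- list(ids, ids)
  }
  dimnames(S) <- list(ids, ids)
  attr(S, "measure") <- measure
  S
}
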
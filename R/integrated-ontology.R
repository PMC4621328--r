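#' Integrated ontology objects
#'
#' An integration result is itself a rooted tree whose nodes each contain at
#' most one vertex from every source ontology. The root is the merged
#' virtual roots and carries no members. Every vertex of every source
#' appears in exactly one node (unmatched vertices occupy singleton nodes of
#' weight 0), and restricting the tree to any single source reproduces that
#' source's ancestor order. A node's weight is the summed pairwise closeness
#' of its co-located members; the total cohesion is the sum of node weights
#' and is the objective the integration algorithms maximise.
#'
#' Objects carry: `tree` (an [ontology_tree()] over node labels), `members`
#' (tibble `node`, `ontology`, `term`), `node_weight` (numeric, aligned with
#' `tree$term`), `sources` (source ontology ids) and `total_cohesion`.
#'
#' @name integrated_ontology
NULL

new_integrated_ontology <- function(tree, members, node_weight, sources,
                                    total_cohesion, matcher = NA_character_,
                                    algorithm = NA_character_,
                                    strategy = NA_character_) {
  structure(
    list(tree = tree, members = members, node_weight = node_weight,
         sources = sources, total_cohesion = total_cohesion,
         matcher = matcher, algorithm = algorithm, strategy = strategy),
    class = "integrated_ontology"
  )
}

# Wrap a source ontology tree as a degenerate integration (every term its
# own node, zero weight) so pairwise and multi integration share one code
# path. Node labels are the terms themselves.
as_integration <- function(x) {
  if (inherits(x, "integrated_ontology")) return(x)
  stopifnot(inherits(x, "ontology_tree"))
  new_integrated_ontology(
    tree = x,
    members = tibble::tibble(node = x$term, ontology = x$id, term = x$term),
    node_weight = stats::setNames(numeric(n_vertices(x)), x$term),
    sources = x$id,
    total_cohesion = 0
  )
}

#' @export
print.integrated_ontology <- function(x, ...) {
  n_merged <- sum(table(x$members$node) > 1L)
  cat(sprintf(
    paste0("<integrated_ontology of {%s}: %d nodes, %d merged, ",
           "total cohesion %.6g>\n"),
    paste(x$sources, collapse = ", "), n_vertices(x$tree), n_merged,
    x$total_cohesion))
  invisible(x)
}

#' Tidy an integration into a merged-node table
#'
#' @param x An `integrated_ontology`.
#' @param ... Unused.
#' @return A tibble with one row per merged node in BFS order: `node`,
#'   `parent` (`NA` for the root), `members` (comma-separated
#'   `ontology:term`), `n_members` and `weight`.
#' @export
tidy.integrated_ontology <- function(x, ...) {
  mem <- x$members
  lab <- stats::setNames(
    vapply(split(paste0(mem$ontology, ":", mem$term), mem$node),
           paste, character(1), collapse = ","),
    names(split(mem$term, mem$node))
  )
  tt <- tidy(x$tree)
  tibble::tibble(
    node = tt$term,
    parent = tt$parent,
    members = unname(ifelse(is.na(lab[tt$term]), "", lab[tt$term])),
    n_members = as.integer(vapply(tt$term, function(n) sum(mem$node == n),
                                  numeric(1))),
    weight = unname(x$node_weight[tt$term])
  )
}

#' One-row summary of an integration
#'
#' @param x An `integrated_ontology`.
#' @param ... Unused.
#' @return A tibble with `n_sources`, `n_nodes`, `n_merged` (nodes holding
#'   more than one member), `n_singleton`, `total_cohesion`, `matcher`,
#'   `algorithm` and `strategy`.
#' @export
glance.integrated_ontology <- function(x, ...) {
  per_node <- table(x$members$node)
  tibble::tibble(
    n_sources = length(x$sources),
    n_nodes = n_vertices(x$tree),
    n_merged = sum(per_node > 1L),
    n_singleton = sum(per_node == 1L),
    total_cohesion = x$total_cohesion,
    matcher = x$matcher,
    algorithm = x$algorithm,
    strategy = x$strategy
  )
}

#' Recompute the cohesion of an integration from its closeness matrices
#'
#' Sums, over every merged node, the pairwise closeness of its co-located
#' members. The value is recomputed from scratch (never read from the cached
#' node weights), which makes it an independent check that a result's
#' claimed total is real.
#'
#' @param onto An `integrated_ontology`.
#' @param matrices A list of [closeness_matrix()] objects covering every
#'   ontology pair that shares a node in `onto`.
#' @return The total cohesion (a single non-negative number).
#' @export
cohesion_of <- function(onto, matrices) {
  stopifnot(inherits(onto, "integrated_ontology"))
  matrices <- key_matrices(matrices)
  mem <- onto$members
  total <- 0
  for (grp in split(mem, mem$node)) {
    if (nrow(grp) < 2L) next
    for (i in seq_len(nrow(grp) - 1L)) {
      for (j in seq(i + 1L, nrow(grp))) {
        m <- oriented_closeness(matrices, grp$ontology[i], grp$ontology[j])
        total <- total + m[grp$term[i], grp$term[j]]
      }
    }
  }
  total
}
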
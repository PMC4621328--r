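#' Build a rooted ontology tree from a child-parent edge list
#'
#' An ontology here is a rooted tree of concept terms connected by
#' child-to-parent (is_a-like) edges. Vertices are assigned dense indices
#' `1..n` by breadth-first traversal from the root, with ties broken by the
#' lexicographic order of term identifiers, so that every algorithm in the
#' package is reproducible run to run. Index `0` is reserved for a virtual
#' super-root whose only child is the real root and whose closeness to every
#' term is zero; it lets the whole-tree integration problem and the
#' root-versus-root subproblem share one recurrence.
#'
#' @param edges A data frame whose first two columns are `child` and `parent`
#'   term identifiers (character). May have zero rows if `root` is given.
#' @param id Short identifier for the ontology (used to key closeness
#'   matrices and merged-node membership).
#' @param root Optional explicit root term; required for a single-vertex
#'   tree, otherwise inferred as the unique parent that is never a child.
#' @return An object of class `ontology_tree` with fields `id`, `term`
#'   (terms in BFS index order), `parent` (parent index per vertex, `0` for
#'   the root), `depth` (root has depth 0) and `children` (list of child
#'   index vectors).
#' @examples
#' t_a <- ontology_tree(
#'   tibble::tibble(child = c("a1", "a2"), parent = c("a0", "a0")), id = "A"
#' )
#' t_a
#' @export
ontology_tree <- function(edges, id = "T", root = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    if (is.null(root)) {
      stop("empty edge list: declare a `root` for a single-vertex tree",
           call. = FALSE)
    }
    return(new_ontology_tree(id, term = as.character(root),
                             parent = 0L, depth = 0L))
  }
  if (ncol(edges) < 2L) stop("edges need child and parent columns", call. = FALSE)
  child <- as.character(edges[[1L]])
  parent <- as.character(edges[[2L]])
  if (anyNA(child) || anyNA(parent) || !all(nzchar(child) & nzchar(parent))) {
    stop("missing or empty term identifier in edge list", call. = FALSE)
  }
  if (anyDuplicated(child)) {
    stop("duplicate child: ", paste(unique(child[duplicated(child)]),
                                    collapse = ", "), call. = FALSE)
  }
  terms <- union(parent, child)
  roots <- setdiff(parent, child)
  if (!is.null(root)) {
    if (!root %in% terms) stop("declared root not present in edges", call. = FALSE)
    if (!root %in% roots) stop("declared root has a parent", call. = FALSE)
  }
  if (length(roots) == 0L) stop("cycle detected: no root vertex", call. = FALSE)
  if (length(roots) > 1L) {
    stop("multiple roots: ", paste(sort(roots), collapse = ", "), call. = FALSE)
  }
  # BFS from the root, children in lexicographic order
  kids <- split(child, parent)
  ord <- character(length(terms))
  ord[1L] <- roots
  par_of <- stats::setNames(parent, child)
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- ord[head]
    ch <- kids[[v]]
    if (!is.null(ch)) {
      ch <- sort(ch)
      ord[tail + seq_along(ch)] <- ch
      tail <- tail + length(ch)
    }
    head <- head + 1L
  }
  if (tail < length(terms)) {
    stop("cycle detected: ", length(terms) - tail,
         " vertex(es) unreachable from root", call. = FALSE)
  }
  idx <- stats::setNames(seq_along(ord), ord)
  parent_idx <- integer(length(ord))
  parent_idx[1L] <- 0L
  if (length(ord) > 1L) parent_idx[-1L] <- idx[par_of[ord[-1L]]]
  depth <- integer(length(ord))
  for (v in seq_along(ord)[-1L]) depth[v] <- depth[parent_idx[v]] + 1L
  new_ontology_tree(id, term = ord, parent = parent_idx, depth = depth)
}

new_ontology_tree <- function(id, term, parent, depth) {
  children <- vector("list", length(term))
  for (v in seq_along(term)) children[[v]] <- integer(0)
  for (v in seq_along(term)) {
    p <- parent[v]
    if (p > 0L) children[[p]] <- c(children[[p]], v)
  }
  structure(
    list(id = id, term = term, parent = as.integer(parent),
         depth = as.integer(depth), children = children),
    class = "ontology_tree"
  )
}

#' @export
print.ontology_tree <- function(x, ...) {
  cat(sprintf("<ontology_tree '%s': %d vertices, root '%s', max depth %d>\n",
              x$id, length(x$term), x$term[1L], max(x$depth)))
  invisible(x)
}

n_vertices <- function(tree) length(tree$term)

vertex_index <- function(tree, term) {
  i <- match(term, tree$term)
  if (anyNA(i)) {
    stop("unknown vertex in '", tree$id, "': ",
         paste(term[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

# children as indices; v = 0 addresses the virtual root (single child: root)
children_idx <- function(tree, v) {
  if (v == 0L) return(1L)
  tree$children[[v]]
}

#' Vertices in reverse topological order
#'
#' Every vertex appears after all of its children; the order is the reverse
#' of the breadth-first vertex indexing and therefore deterministic. This is
#' the order in which the cohesion matrix is filled.
#'
#' @param tree An [ontology_tree()].
#' @return Character vector of term identifiers, leaves first, root last.
#' @export
reverse_topological_order <- function(tree) {
  stopifnot(inherits(tree, "ontology_tree"))
  rev(tree$term)
}

#' Lowest common ancestor of two terms
#'
#' @param tree An [ontology_tree()].
#' @param x,y Term identifiers.
#' @return The term identifier of the deepest vertex that is an
#'   ancestor-or-self of both `x` and `y`.
#' @export
lca <- function(tree, x, y) {
  stopifnot(inherits(tree, "ontology_tree"))
  i <- vertex_index(tree, x)
  j <- vertex_index(tree, y)
  tree$term[lca_idx(tree$parent, tree$depth, i, j)]
}

lca_idx <- function(parent, depth, i, j) {
  while (depth[i] > depth[j]) i <- parent[i]
  while (depth[j] > depth[i]) j <- parent[j]
  while (i != j) { i <- parent[i]; j <- parent[j] }
  i
}

is_ancestor_idx <- function(parent, depth, a, d) {
  # TRUE iff a is a strict ancestor of d
  while (depth[d] > depth[a]) {
    d <- parent[d]
    if (d == a) return(TRUE)
  }
  FALSE
}

#' Forest of child subtrees
#'
#' Deleting a vertex from the subtree it roots leaves a forest; this returns
#' the roots of that forest in deterministic (vertex index) order. The
#' virtual root may be addressed with `term = NULL`, whose forest is the
#' real root alone.
#'
#' @param tree An [ontology_tree()].
#' @param term A term identifier, or `NULL` for the virtual root.
#' @return Character vector of subtree-root terms (empty for a leaf).
#' @export
children_forest <- function(tree, term) {
  stopifnot(inherits(tree, "ontology_tree"))
  if (is.null(term)) return(tree$term[1L])
  v <- vertex_index(tree, term)
  tree$term[tree$children[[v]]]
}

# all vertex indices of the subtree rooted at v (BFS order)
subtree_idx <- function(tree, v) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    frontier <- unlist(tree$children[frontier], use.names = FALSE)
    out <- c(out, frontier)
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ontology tree into a vertex table
#'
#' @param x An [ontology_tree()].
#' @param ... Unused.
#' @return A tibble with one row per vertex: `index`, `term`, `parent`
#'   (term, `NA` for the root) and `depth`.
#' @export
tidy.ontology_tree <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$term),
    term = x$term,
    parent = ifelse(x$parent == 0L, NA_character_, x$term[pmax(x$parent, 1L)]),
    depth = x$depth
  )
}
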
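#' Closeness matrix between two ontologies
#'
#' Holds the externally supplied, non-negative term-to-term closeness scores
#' between two ontologies. The constructor takes sparse triples; pairs not
#' listed score 0, and any query that involves a virtual root also scores 0
#' (a node containing a single vertex contributes nothing to cohesion).
#' Scores are dimensionless reals; nothing in the model requires them to
#' stay below 1, although the synthetic benchmark draws them from [0, 1].
#'
#' @param triples A data frame whose first three columns are `term_a`,
#'   `term_b` and `score` (finite, `>= 0`). Zero rows give an all-zero
#'   matrix.
#' @param tree_a,tree_b The two [ontology_tree()]s the scores refer to.
#' @return An object of class `closeness_matrix` with the dense score matrix
#'   in `m` (rows follow `tree_a`'s vertex order, columns `tree_b`'s) and
#'   the two ontology ids in `side_a` / `side_b`.
#' @examples
#' t_a <- ontology_tree(data.frame(child = "a1", parent = "a0"), id = "A")
#' t_b <- ontology_tree(data.frame(child = "b1", parent = "b0"), id = "B")
#' closeness_matrix(
#'   data.frame(term_a = "a1", term_b = "b1", score = 0.7), t_a, t_b
#' )
#' @export
closeness_matrix <- function(triples, tree_a, tree_b) {
  stopifnot(inherits(tree_a, "ontology_tree"), inherits(tree_b, "ontology_tree"))
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  m <- matrix(0, n_vertices(tree_a), n_vertices(tree_b),
              dimnames = list(tree_a$term, tree_b$term))
  if (nrow(triples) > 0L) {
    if (ncol(triples) < 3L) stop("triples need term_a, term_b, score columns",
                                 call. = FALSE)
    ta <- as.character(triples[[1L]])
    tb <- as.character(triples[[2L]])
    sc <- as.numeric(triples[[3L]])
    if (anyNA(sc) || any(!is.finite(sc))) {
      stop("closeness scores must be finite (no NA/NaN/Inf)", call. = FALSE)
    }
    if (any(sc < 0)) stop("negative closeness score", call. = FALSE)
    if (anyDuplicated(paste(ta, tb, sep = "\r"))) {
      stop("duplicate (term_a, term_b) pair in closeness triples", call. = FALSE)
    }
    i <- vertex_index(tree_a, ta)
    j <- vertex_index(tree_b, tb)
    m[cbind(i, j)] <- sc
  }
  new_closeness_matrix(m, tree_a$id, tree_b$id)
}

new_closeness_matrix <- function(m, side_a, side_b) {
  stopifnot(is.matrix(m), is.numeric(m))
  structure(list(side_a = side_a, side_b = side_b, m = m),
            class = "closeness_matrix")
}

#' @export
print.closeness_matrix <- function(x, ...) {
  cat(sprintf(
    "<closeness_matrix %s x %s: %d x %d, %d positive entries, max %.4g>\n",
    x$side_a, x$side_b, nrow(x$m), ncol(x$m), sum(x$m > 0),
    if (length(x$m)) max(x$m) else 0))
  invisible(x)
}

#' Look up closeness scores by term
#'
#' Symmetric in role: terms may be given in either side order. `NULL` on
#' either side addresses a virtual root and returns 0.
#'
#' @param cl A [closeness_matrix()].
#' @param term_a,term_b Term identifiers (or `NULL` for a virtual root).
#' @return The stored score (0 when absent or when a virtual root is
#'   involved).
#' @export
closeness_at <- function(cl, term_a, term_b) {
  stopifnot(inherits(cl, "closeness_matrix"))
  if (is.null(term_a) || is.null(term_b)) return(0)
  if (term_a %in% rownames(cl$m) && term_b %in% colnames(cl$m)) {
    cl$m[term_a, term_b]
  } else if (term_b %in% rownames(cl$m) && term_a %in% colnames(cl$m)) {
    cl$m[term_b, term_a]
  } else {
    stop("terms not found on opposite sides of the closeness matrix",
         call. = FALSE)
  }
}

# unordered pair key used for lists of closeness matrices
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "__")

# fetch the matrix for ontology pair (rows = side_row, cols = side_col),
# transposing as needed; errors when the pair is not covered
oriented_closeness <- function(matrices, side_row, side_col) {
  key <- pair_key(side_row, side_col)
  cl <- matrices[[key]]
  if (is.null(cl)) {
    # fall back to scanning (callers may pass unnamed lists)
    for (cand in matrices) {
      if (setequal(c(cand$side_a, cand$side_b), c(side_row, side_col))) {
        cl <- cand
        break
      }
    }
  }
  if (is.null(cl)) {
    stop("missing closeness matrix for pair ", side_row, " / ", side_col,
         call. = FALSE)
  }
  if (cl$side_a == side_row && cl$side_b == side_col) {
    cl$m
  } else if (cl$side_b == side_row && cl$side_a == side_col) {
    t(cl$m)
  } else {
    stop("closeness matrix sides do not match pair ", side_row, " / ",
         side_col, call. = FALSE)
  }
}

# name a list of closeness matrices by their pair keys
key_matrices <- function(matrices) {
  stats::setNames(matrices,
                  vapply(matrices, function(cl) pair_key(cl$side_a, cl$side_b),
                         character(1)))
}
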
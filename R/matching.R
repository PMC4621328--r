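#' Weighted bipartite matching kernels
#'
#' The subtree-pairing step of the integration recurrence is a weighted
#' bipartite matching over child forests. Three interchangeable kernels are
#' provided:
#'
#' * [greedy_maximal_matching()] — scans edges heaviest first (ties broken
#'   by left then right item order) and takes an edge whenever both
#'   endpoints are free. This is the maximal-matching kernel that gives the
#'   overall integration its 1/2-approximation guarantee and its
#'   O(n^2 log n) running time.
#' * [optimal_matching()] — the maximum weighted matching (assignment
#'   problem), delegated to [igraph::max_bipartite_match()].
#' * [exhaustive_matching()] — brute-force enumeration over all matchings;
#'   a test oracle, guarded to small instances.
#'
#' Zero-weight edges are never taken: pairing two terms with closeness 0
#' adds nothing to the objective while constraining their descendants, so
#' skipping them keeps integrated trees minimal without lowering any score.
#'
#' @param edges A data frame whose first three columns are `left`, `right`
#'   and `weight` (finite, `>= 0`); zero rows allowed. `(left, right)` pairs
#'   must be unique.
#' @return A list of class `matching_result` with `pairs` (tibble `left`,
#'   `right`, `weight`, each item used at most once) and `total` (sum of
#'   matched weights).
#' @examples
#' e <- data.frame(left = c("a1", "a1", "a2"), right = c("b1", "b2", "b2"),
#'                 weight = c(2, 4, 3))
#' greedy_maximal_matching(e)$total # 4: takes (a1,b2), blocking both items
#' optimal_matching(e)$total        # 5: (a1,b1) + (a2,b2)
#' @name matching-kernels
NULL

as_edge_cols <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    return(list(left = character(0), right = character(0), weight = numeric(0)))
  }
  if (ncol(edges) < 3L) stop("edges need left, right, weight columns", call. = FALSE)
  w <- as.numeric(edges[[3L]])
  if (anyNA(w) || any(!is.finite(w))) stop("non-finite edge weight", call. = FALSE)
  if (any(w < 0)) stop("negative edge weight", call. = FALSE)
  l <- edges[[1L]]
  r <- edges[[2L]]
  if (anyDuplicated(paste(l, r, sep = "\r"))) {
    stop("duplicate (left, right) edge", call. = FALSE)
  }
  list(left = l, right = r, weight = w)
}

matching_result <- function(left, right, weight) {
  structure(
    list(pairs = tibble::tibble(left = left, right = right, weight = weight),
         total = sum(weight)),
    class = "matching_result"
  )
}

#' @rdname matching-kernels
#' @export
greedy_maximal_matching <- function(edges) {
  e <- as_edge_cols(edges)
  keep <- e$weight > 0
  l <- e$left[keep]; r <- e$right[keep]; w <- e$weight[keep]
  if (!length(w)) return(matching_result(l, r, w))
  ord <- order(-w, l, r)
  used_l <- character(0); used_r <- character(0)
  take <- integer(0)
  for (i in ord) {
    if (!(l[i] %in% used_l) && !(r[i] %in% used_r)) {
      take <- c(take, i)
      used_l <- c(used_l, l[i])
      used_r <- c(used_r, r[i])
    }
  }
  matching_result(l[take], r[take], w[take])
}

#' @rdname matching-kernels
#' @export
optimal_matching <- function(edges) {
  e <- as_edge_cols(edges)
  keep <- e$weight > 0
  l <- as.character(e$left[keep]); r <- as.character(e$right[keep])
  w <- e$weight[keep]
  if (!length(w)) return(matching_result(l, r, w))
  lu <- sort(unique(l)); ru <- sort(unique(r))
  if (length(lu) == 1L || length(ru) == 1L) {
    # a single item on one side: the heaviest incident edge wins
    i <- order(-w, l, r)[1L]
    return(matching_result(l[i], r[i], w[i]))
  }
  sel <- igraph_assignment(l, r, w, lu, ru)
  matching_result(l[sel], r[sel], w[sel])
}

# maximum weighted bipartite matching via igraph; returns selected edge rows
igraph_assignment <- function(l, r, w, lu, ru) {
  nv <- length(lu) + length(ru)
  li <- match(l, lu)
  ri <- length(lu) + match(r, ru)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(lu)), rep(TRUE, length(ru))),
    edges = as.vector(rbind(li, ri))
  )
  res <- igraph::max_bipartite_match(g, weights = w, eps = 1e-10)
  mate <- res$matching # mate[v] over all vertices, NA when unmatched
  sel <- which(mate[li] == ri)
  # defensively drop anything the solver matched at zero gain (cannot occur
  # with positive weights, but keeps the contract explicit)
  sel[w[sel] > 0]
}

#' @rdname matching-kernels
#' @param max_items Size guard: maximum number of distinct items allowed on
#'   each side of the exhaustive search.
#' @export
exhaustive_matching <- function(edges, max_items = 10L) {
  e <- as_edge_cols(edges)
  keep <- e$weight > 0
  l <- as.character(e$left[keep]); r <- as.character(e$right[keep])
  w <- e$weight[keep]
  if (!length(w)) return(matching_result(l, r, w))
  lu <- sort(unique(l)); ru <- sort(unique(r))
  if (length(lu) > max_items || length(ru) > max_items) {
    stop("exhaustive_matching size guard exceeded (", max_items,
         " items per side)", call. = FALSE)
  }
  li <- match(l, lu); ri <- match(r, ru)
  # best assignment for lefts i..end given a bitmask of used rights
  memo <- new.env(parent = emptyenv())
  best <- function(i, mask) {
    if (i > length(lu)) return(list(total = 0, take = integer(0)))
    key <- paste0(i, ":", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- best(i + 1L, mask) # leave left item i unmatched
    for (eidx in which(li == i)) {
      bit <- bitwShiftL(1L, ri[eidx] - 1L)
      if (bitwAnd(mask, bit) == 0L) {
        sub <- best(i + 1L, bitwOr(mask, bit))
        if (sub$total + w[eidx] > out$total) {
          out <- list(total = sub$total + w[eidx], take = c(eidx, sub$take))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  sol <- best(1L, 0L)
  matching_result(l[sol$take], r[sol$take], w[sol$take])
}

#' @export
print.matching_result <- function(x, ...) {
  cat(sprintf("<matching_result: %d pairs, total weight %.6g>\n",
              nrow(x$pairs), x$total))
  invisible(x)
}
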
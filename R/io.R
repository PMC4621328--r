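#' Read an ontology tree from a child-parent TSV
#'
#' Two tab-separated columns, child then parent; a `child<TAB>parent`
#' header row is detected and skipped. Identifiers are opaque strings
#' (CUI-like or GO-like ids are equally fine).
#'
#' @param path File path.
#' @param id Ontology identifier to assign.
#' @return An [ontology_tree()].
#' @export
read_tree_tsv <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty tree file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop("malformed line ", bad[1L], " in ", path,
         " (expected 2 tab-separated fields)", call. = FALSE)
  }
  child <- vapply(fields, `[[`, character(1), 1L)
  parent <- vapply(fields, `[[`, character(1), 2L)
  if (tolower(child[1L]) == "child" && tolower(parent[1L]) == "parent") {
    child <- child[-1L]
    parent <- parent[-1L]
  }
  if (!length(child)) stop("empty tree file: ", path, call. = FALSE)
  ontology_tree(data.frame(child = child, parent = parent), id = id)
}

#' Read an ontology tree from hierarchy path lines
#'
#' MRHIER-style input: one root-to-term path per line, components joined by
#' `delimiter`. The tree is rebuilt by merging common prefixes from the
#' root. Duplicate paths are idempotent; a term appearing under two
#' different parents is rejected as DAG-shaped input (expand duplicates
#' into independent concepts before loading).
#'
#' @param path File path.
#' @param delimiter Path component separator (UMLS releases vary; default
#'   `"."`).
#' @param id Ontology identifier to assign.
#' @return An [ontology_tree()].
#' @export
read_mrhier_paths <- function(path, delimiter = ".",
                              id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty path file: ", path, call. = FALSE)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  roots <- unique(vapply(parts, `[[`, character(1), 1L))
  if (length(roots) > 1L) {
    stop("multiple roots in path file: ", paste(roots, collapse = ", "),
         call. = FALSE)
  }
  parent_of <- new.env(parent = emptyenv())
  for (li in seq_along(parts)) {
    p <- parts[[li]]
    if (length(p) < 2L) next
    for (i in seq(2L, length(p))) {
      known <- parent_of[[p[i]]]
      if (is.null(known)) {
        parent_of[[p[i]]] <- p[i - 1L]
      } else if (known != p[i - 1L]) {
        stop("DAG input: term '", p[i], "' has parents '", known, "' and '",
             p[i - 1L], "' (line ", li, ")", call. = FALSE)
      }
    }
  }
  child <- ls(parent_of)
  if (!length(child)) {
    return(ontology_tree(data.frame(child = character(0),
                                    parent = character(0)),
                         id = id, root = roots))
  }
  parent <- vapply(child, function(ch) parent_of[[ch]], character(1))
  ontology_tree(data.frame(child = child, parent = unname(parent)), id = id)
}

#' Read a sparse closeness matrix from a TSV of triples
#'
#' Three tab-separated columns: `term_a`, `term_b`, `score` (a header row
#' is detected and skipped). Pairs not listed score 0; negative or
#' non-finite scores and duplicate pairs are rejected.
#'
#' @param path File path.
#' @param tree_a,tree_b The [ontology_tree()]s the terms belong to.
#' @return A [closeness_matrix()].
#' @export
read_closeness_tsv <- function(path, tree_a, tree_b) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(closeness_matrix(data.frame(term_a = character(0),
                                       term_b = character(0),
                                       score = numeric(0)),
                            tree_a, tree_b))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop("malformed line ", bad[1L], " in ", path,
         " (expected 3 tab-separated fields)", call. = FALSE)
  }
  ta <- vapply(fields, `[[`, character(1), 1L)
  tb <- vapply(fields, `[[`, character(1), 2L)
  sc <- vapply(fields, `[[`, character(1), 3L)
  if (is.na(suppressWarnings(as.numeric(sc[1L])))) { # header row
    ta <- ta[-1L]; tb <- tb[-1L]; sc <- sc[-1L]
  }
  closeness_matrix(data.frame(term_a = ta, term_b = tb,
                              score = as.numeric(sc)),
                   tree_a, tree_b)
}

#' Write / read an integrated ontology as a merged-node TSV
#'
#' One record per merged node in BFS order: `node_id`, `parent_id` (empty
#' for the root), `members` (comma-separated `ontology:term`, empty for the
#' virtual root) and `weight`. `read_merged_tsv()` restores the full
#' object; a write/read round trip reproduces the node set, parent
#' structure, membership and weights.
#'
#' @param onto An [integrated_ontology].
#' @param path File path.
#' @return `write_merged_tsv()` returns `path` invisibly;
#'   `read_merged_tsv()` returns an [integrated_ontology].
#' @export
write_merged_tsv <- function(onto, path) {
  stopifnot(inherits(onto, "integrated_ontology"))
  td <- tidy(onto)
  rec <- data.frame(node_id = td$node,
                    parent_id = ifelse(is.na(td$parent), "", td$parent),
                    members = td$members,
                    weight = format(td$weight, digits = 17, trim = TRUE,
                                    scientific = FALSE))
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_merged_tsv
#' @export
read_merged_tsv <- function(path) {
  rec <- utils::read.delim(path, colClasses = c("character", "character",
                                                "character", "numeric"))
  if (!nrow(rec)) stop("empty merged-ontology file: ", path, call. = FALSE)
  root <- rec$node_id[rec$parent_id == ""]
  if (length(root) != 1L) stop("merged file must have exactly one root",
                               call. = FALSE)
  has_par <- rec$parent_id != ""
  tr <- ontology_tree(data.frame(child = rec$node_id[has_par],
                                 parent = rec$parent_id[has_par]),
                      id = "merged", root = if (all(!has_par)) root else NULL)
  mem <- rec[rec$members != "", c("node_id", "members")]
  if (!nrow(mem)) stop("merged file has no member records", call. = FALSE)
  mem_long <- do.call(rbind, lapply(seq_len(nrow(mem)), function(i) {
    parts <- strsplit(strsplit(mem$members[i], ",", fixed = TRUE)[[1L]],
                      ":", fixed = TRUE)
    data.frame(node = mem$node_id[i],
               ontology = vapply(parts, `[[`, character(1), 1L),
               term = vapply(parts, `[[`, character(1), 2L))
  }))
  members <- tibble::as_tibble(mem_long)
  new_integrated_ontology(
    tree = tr, members = members,
    node_weight = stats::setNames(rec$weight, rec$node_id)[tr$term],
    sources = sort(unique(members$ontology)),
    total_cohesion = sum(rec$weight)
  )
}

#' Write an integrated ontology in DOT format
#'
#' Each node is labelled with its members and a `[closeness | cohesion]`
#' bracket: the left value is the node's own closeness weight, the right
#' the total cohesion of the subtree below it (itself included).
#'
#' @param onto An [integrated_ontology].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(onto, path) {
  stopifnot(inherits(onto, "integrated_ontology"))
  tr <- onto$tree
  w <- unname(onto$node_weight)
  sub <- w
  for (v in rev(seq_along(tr$term))) { # children have larger BFS index
    p <- tr$parent[v]
    if (p > 0L) sub[p] <- sub[p] + sub[v]
  }
  td <- tidy(onto)
  lab <- ifelse(td$members == "", "(root)", gsub(",", "\\\\n", td$members))
  lines <- c(
    "digraph integrated_ontology {",
    "  node [shape=box];",
    sprintf("  \"%s\" [label=\"%s\\n[%.4g | %.4g]\"];",
            tr$term, lab, w, sub),
    sprintf("  \"%s\" -> \"%s\";",
            tr$term[tr$parent[tr$parent > 0L]],
            tr$term[tr$parent > 0L]),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
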
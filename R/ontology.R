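#' Label hierarchies for function prediction
#'
#' A `label_graph` is a rooted acyclic hierarchy of function labels joined by
#' *is_a* edges: an EC-style tree (every non-root has exactly one parent) or a
#' GO-style DAG (multiple parents allowed).  Edges point from child to parent.
#' Annotations are given on leaves and expanded to all ancestors with
#' [propagate()] so that multi-label training targets are hierarchy-consistent.
#'
#' @param edges a two-column data frame (`child`, `parent`) of label ids, or
#'   the path of a headerless two-column TSV file.
#' @param namespace one of `"synthetic"`, `"EC-like"`, `"GO-like"`.  EC-like
#'   graphs must be trees; GO-like and synthetic graphs may be DAGs (synthetic
#'   trees are produced by [make_ontology()]).
#' @return an object of class `label_graph` with elements `labels` (character
#'   vector of all ids), `edges` (child/parent data frame), `namespace`, and
#'   `graph` (an igraph object with child -> parent arcs).
#' @examples
#' g <- parse_ontology(data.frame(
#'   child  = c("EC:3.2.1.2", "EC:3.2.1.-", "EC:3.2.-.-"),
#'   parent = c("EC:3.2.1.-", "EC:3.2.-.-", "EC:3.-.-.-")), "EC-like")
#' ancestors(g, "EC:3.2.1.2")
#' @export
parse_ontology <- function(edges, namespace = c("synthetic", "EC-like", "GO-like")) {
  namespace <- match.arg(namespace)
  if (is.character(edges) && length(edges) == 1L) {
    edges <- utils::read.table(edges, sep = "\t", header = FALSE,
                               col.names = c("child", "parent"),
                               colClasses = "character", quote = "",
                               comment.char = "")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge table must have two columns (child, parent)")
  edges <- data.frame(child = as.character(edges[[1L]]),
                      parent = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    if (any(!nzchar(edges$child)) || any(!nzchar(edges$parent)) ||
        anyNA(edges$child) || anyNA(edges$parent))
      stop("edge table contains empty or missing label ids")
    if (any(edges$child == edges$parent))
      stop("self-loop edge(s): ",
           paste(unique(edges$child[edges$child == edges$parent]), collapse = ", "))
    edges <- unique(edges)
  }
  labels <- sort(unique(c(edges$child, edges$parent)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = if (length(labels)) labels else NULL)
  if (nrow(edges) > 0L && !igraph::is_dag(g)) {
    stop("cycle detected among labels: ", paste(cyclic_ids(g), collapse = ", "))
  }
  if (namespace == "EC-like" && nrow(edges) > 0L) {
    npar <- table(edges$child)
    multi <- names(npar)[npar > 1L]
    if (length(multi))
      stop("EC-like graphs must be trees; labels with multiple parents: ",
           paste(multi, collapse = ", "))
  }
  structure(list(labels = labels, edges = edges,
                 namespace = namespace, graph = g),
            class = "label_graph")
}

# ids that sit on a cycle: iteratively peel vertices with no out-edges
cyclic_ids <- function(g) {
  repeat {
    sinks <- igraph::V(g)[igraph::degree(g, mode = "out") == 0]
    if (length(sinks) == 0L) break
    g <- igraph::delete_vertices(g, sinks)
  }
  sort(igraph::V(g)$name)
}

#' @export
print.label_graph <- function(x, ...) {
  cat(sprintf("<label_graph> %s: %d labels, %d is_a edges, %d root(s), %d leaf/leaves\n",
              x$namespace, length(x$labels), nrow(x$edges),
              length(graph_roots(x)), length(graph_leaves(x))))
  invisible(x)
}

check_labels_known <- function(graph, labels) {
  unknown <- setdiff(labels, graph$labels)
  if (length(unknown))
    stop("unknown label(s): ", paste(sort(unknown), collapse = ", "))
}

#' Ancestors of a label
#'
#' Transitive closure over *is_a* edges, excluding the label itself.  On a
#' tree the number of ancestors equals the label's depth below the root.
#'
#' @param graph a [label_graph][parse_ontology].
#' @param label a single label id present in the graph.
#' @return character vector of ancestor ids (sorted; empty for a root).
#' @export
ancestors <- function(graph, label) {
  stopifnot(inherits(graph, "label_graph"), length(label) == 1L)
  check_labels_known(graph, label)
  if (nrow(graph$edges) == 0L) return(character(0))
  reach <- igraph::subcomponent(graph$graph, label, mode = "out")$name
  sort(setdiff(reach, label))
}

#' Ancestor closure of a label set
#'
#' Expands a set of (typically leaf) labels to include every ancestor, the
#' closure applied to all annotations before model training so that a
#' specific annotation implies its broader classes.  Idempotent.
#'
#' @inheritParams ancestors
#' @param leaf_labels character vector of label ids (may be empty).
#' @return sorted character vector: `leaf_labels` plus all ancestors.
#' @export
propagate <- function(graph, leaf_labels) {
  stopifnot(inherits(graph, "label_graph"))
  leaf_labels <- unique(as.character(leaf_labels))
  if (length(leaf_labels) == 0L) return(character(0))
  check_labels_known(graph, leaf_labels)
  if (nrow(graph$edges) == 0L) return(sort(leaf_labels))
  reach <- unique(unlist(lapply(
    leaf_labels,
    function(l) igraph::subcomponent(graph$graph, l, mode = "out")$name)))
  sort(reach)
}

#' Roots and leaves of a label graph
#'
#' Roots have no parent; leaves have no child.
#' @inheritParams ancestors
#' @return character vector of label ids.
#' @export
graph_roots <- function(graph) {
  stopifnot(inherits(graph, "label_graph"))
  sort(setdiff(graph$labels, graph$edges$child))
}

#' @rdname graph_roots
#' @export
graph_leaves <- function(graph) {
  stopifnot(inherits(graph, "label_graph"))
  sort(setdiff(graph$labels, graph$edges$parent))
}

#' Write a label graph as a two-column TSV edge list
#'
#' @inheritParams ancestors
#' @param path output file path.
#' @export
write_ontology <- function(graph, path) {
  stopifnot(inherits(graph, "label_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
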
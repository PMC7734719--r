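# Depth-indexed neighborhood extraction by iterated frontier expansion.

.adjacency_list <- function(graph) {
  adj <- igraph::as_adj_list(graph@graph, mode = "out")
  lapply(adj, as.integer)
}

.extract_one <- function(adj, labels, root_idx, depth) {
  levels <- vector("list", depth)
  frontier <- root_idx
  for (i in seq_len(depth)) {
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
    levels[[i]] <- if (length(frontier))
      sort(unique(labels[frontier]), method = "radix") else character(0)
  }
  levels
}

#' Extract depth-indexed neighborhood label sets
#'
#' For each root, computes the sets of vertex labels reachable in exactly
#' i = 1, ..., d directed hops by iterated frontier expansion
#' (frontier_0 = \{root\}, frontier_(i+1) = successors(frontier_i)).
#' Walks may revisit vertices, so on a cycle a label recurs at every depth
#' of the same parity. The resulting structure makes walk containment a
#' constant-time set-membership test ([containsWalk()]).
#'
#' @param graph a [LabeledGraph-class].
#' @param root a vertex name present in the graph.
#' @param roots character vector of vertex names.
#' @param depth extraction depth d >= 1. For converted KGs, k entity hops
#'   require `depth = 2 * k` (odd depths land on predicate vertices).
#' @return `extractNeighborhood`: a [Neighborhood-class];
#'   `extractNeighborhoods`: a named list of them (attribute `converted`
#'   records whether the graph came from triple conversion, which selects
#'   the default odd-depth-skipping behavior downstream).
#' @examples
#' g <- labeledGraph(data.frame(from = c("a", "b"), to = c("b", "c")),
#'                   c(a = "A", b = "B", c = "C"))
#' nb <- extractNeighborhood(g, "a", 2)
#' levelLabels(nb, 2)
#' @export
extractNeighborhood <- function(graph, root, depth) {
  extractNeighborhoods(graph, root, depth)[[1L]]
}

#' @rdname extractNeighborhood
#' @export
extractNeighborhoods <- function(graph, roots, depth) {
  stopifnot(is(graph, "LabeledGraph"))
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 1L)
    stop("depth must be a single integer >= 1")
  vn <- igraph::V(graph@graph)$name
  idx <- match(roots, vn)
  if (anyNA(idx))
    stop("root vertices not in graph: ",
         paste(roots[is.na(idx)], collapse = ", "))
  adj <- .adjacency_list(graph)
  labels <- igraph::V(graph@graph)$label
  out <- lapply(seq_along(roots), function(k) {
    new("Neighborhood", root = roots[[k]], maxDepth = depth,
        levelLabels = .extract_one(adj, labels, idx[[k]], depth))
  })
  names(out) <- roots
  attr(out, "converted") <- graph@converted
  out
}

#' @rdname containsWalk
#' @export
setMethod("containsWalk", signature(nbh = "Neighborhood", walk = "Walk"),
  function(nbh, walk, ...) {
    containsWalk(nbh, walk@endLabel, depth = walk@depth)
  })

#' @rdname containsWalk
#' @param depth walk depth (character method).
#' @export
setMethod("containsWalk", signature(nbh = "Neighborhood", walk = "character"),
  function(nbh, walk, depth, ...) {
    depth <- as.integer(depth)
    if (depth > nbh@maxDepth)
      stop(sprintf(
        "walk depth %d exceeds neighborhood depth %d (too shallow)",
        depth, nbh@maxDepth))
    if (depth < 1L) stop("walk depth must be >= 1")
    walk %in% nbh@levelLabels[[depth]]
  })
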
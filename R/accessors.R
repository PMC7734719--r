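# Constructors, accessors and show methods for the core classes.

#' Build a plain labeled directed graph
#'
#' Constructor for graphs given directly as an edge list plus a node-label
#' map, as used for the artificial worked examples and random test graphs
#' (no knowledge-graph conversion involved; `converted` is `FALSE` so odd
#' walk depths are enumerated).
#'
#' @param edges data.frame with character columns `from` and `to`, each row
#'   a directed edge between vertex names.
#' @param labels named character vector mapping every vertex name to its
#'   label; vertices absent from `edges` are kept as isolated vertices.
#' @param kind optional named character vector (`"entity"`/`"predicate"`);
#'   defaults to `"entity"` for all vertices.
#' @return a [LabeledGraph-class].
#' @examples
#' g <- labeledGraph(data.frame(from = "a", to = "b"),
#'                   c(a = "A", b = "B"))
#' numVertices(g)
#' @export
labeledGraph <- function(edges, labels, kind = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (is.null(names(labels)) || anyNA(names(labels)))
    stop("labels must be a named character vector (names = vertex ids)")
  vnames <- names(labels)
  miss <- setdiff(unique(c(edges$from, edges$to)), vnames)
  if (length(miss))
    stop("edge endpoints missing from labels: ", paste(miss, collapse = ", "))
  g <- igraph::make_empty_graph(n = length(vnames), directed = TRUE)
  igraph::V(g)$name <- vnames
  igraph::V(g)$label <- unname(labels)
  if (is.null(kind)) kind <- setNames(rep("entity", length(vnames)), vnames)
  igraph::V(g)$kind <- unname(kind[vnames])
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$from, vnames),
                                    match(edges$to, vnames)))
  new("LabeledGraph", graph = g, converted = FALSE)
}

#' Construct an entity/label dataset
#'
#' @param entities character vector of vertex names.
#' @param labels character vector of class labels (recycled never; must
#'   match length).
#' @return an [EntityDataset-class].
#' @export
entityDataset <- function(entities, labels) {
  new("EntityDataset", entities = as.character(entities),
      labels = as.character(labels))
}

#' Construct a walk
#'
#' @param endLabel label string the walk ends in.
#' @param depth number of hops (>= 1).
#' @return a [Walk-class].
#' @export
walk <- function(endLabel, depth) {
  new("Walk", endLabel = as.character(endLabel), depth = as.integer(depth))
}

#' Render a walk as its wildcard pattern string
#'
#' @param x a [Walk-class], or an end label (with `depth` given).
#' @param depth depth when `x` is a label string.
#' @return `"root -> * -> ... -> label"` with `depth - 1` wildcards.
#' @export
walkString <- function(x, depth = NULL) {
  if (is(x, "Walk")) { depth <- x@depth; x <- x@endLabel }
  paste(c("root", rep("*", depth - 1L), x), collapse = " -> ")
}

#' @rdname LabeledGraph-class
#' @export
setMethod("asIgraph", "LabeledGraph", function(x) x@graph)

#' @rdname LabeledGraph-class
#' @export
setMethod("numVertices", "LabeledGraph",
          function(x) as.integer(igraph::vcount(x@graph)))

#' @rdname LabeledGraph-class
#' @export
setMethod("numEdges", "LabeledGraph",
          function(x) as.integer(igraph::ecount(x@graph)))

#' @rdname LabeledGraph-class
#' @export
setMethod("vertexLabels", "LabeledGraph",
          function(x) setNames(igraph::V(x@graph)$label,
                               igraph::V(x@graph)$name))

#' @rdname LabeledGraph-class
#' @export
setMethod("isConverted", "LabeledGraph", function(x) x@converted)

setMethod("show", "LabeledGraph", function(object) {
  cat(sprintf("LabeledGraph: %d vertices, %d edges (%s)\n",
              numVertices(object), numEdges(object),
              if (object@converted) "converted from triples" else "plain"))
  kinds <- table(igraph::V(object@graph)$kind)
  cat("  vertex kinds:",
      paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
})

#' @rdname EntityDataset-class
#' @param x an [EntityDataset-class].
#' @export
setMethod("entities", "EntityDataset", function(x) x@entities)

#' @rdname EntityDataset-class
#' @export
setMethod("classLabels", "EntityDataset", function(x) x@labels)

#' @rdname EntityDataset-class
#' @export
setMethod("classNames", "EntityDataset",
          function(x) sort(unique(x@labels), method = "radix"))

#' @rdname EntityDataset-class
#' @export
setMethod("length", "EntityDataset", function(x) length(x@entities))

#' @rdname EntityDataset-class
#' @param i index vector.
#' @export
setMethod("[", "EntityDataset", function(x, i) {
  entityDataset(x@entities[i], x@labels[i])
})

setMethod("show", "EntityDataset", function(object) {
  cls <- classNames(object)
  cat(sprintf("EntityDataset: %d entities, %d classes\n",
              length(object), length(cls)))
  tab <- table(factor(object@labels, levels = cls))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "; "), "\n")
})

#' @rdname Walk-class
#' @param x a [Walk-class].
#' @export
setMethod("endLabel", "Walk", function(x) x@endLabel)

#' @rdname Walk-class
#' @export
setMethod("walkDepth", "Walk", function(x) x@depth)

setMethod("show", "Walk", function(object) {
  cat("Walk:", walkString(object), "\n")
})

#' @rdname Neighborhood-class
#' @param x a [Neighborhood-class].
#' @export
setMethod("nbhDepth", "Neighborhood", function(x) x@maxDepth)

#' @rdname Neighborhood-class
#' @export
setMethod("levelLabels", "Neighborhood", function(x, i) {
  if (missing(i)) return(x@levelLabels)
  if (i < 1L || i > x@maxDepth)
    stop("depth ", i, " outside 1..", x@maxDepth)
  x@levelLabels[[i]]
})

setMethod("show", "Neighborhood", function(object) {
  cat(sprintf("Neighborhood of '%s' (depth %d)\n", object@root,
              object@maxDepth))
  for (i in seq_len(object@maxDepth)) {
    labs <- object@levelLabels[[i]]
    cat(sprintf("  depth %d: %d labels%s\n", i, length(labs),
                if (length(labs))
                  paste0(" {", paste(head(labs, 6), collapse = ", "),
                         if (length(labs) > 6) ", ..." else "", "}")
                else ""))
  }
})

setMethod("show", "WalkTree", function(object) {
  cat("WalkTree:\n")
  cat(serializeWalkTree(object), sep = "\n")
})

#' @rdname WalkForest-class
#' @export
setMethod("forestTrees", "WalkForest", function(x) x@trees)

#' @rdname WalkForest-class
#' @export
setMethod("length", "WalkForest", function(x) length(x@trees))

setMethod("show", "WalkForest", function(object) {
  p <- object@params
  cat(sprintf(
    "WalkForest: %d trees (bootstrap=%s, vertex_sample=%s, seed=%s)\n",
    length(object@trees), p$bootstrap, p$vertex_sample,
    if (is.null(p$seed)) "NULL" else p$seed))
})

#' @rdname WalkFeatureMatrix-class
#' @export
setMethod("featureWalks", "WalkFeatureMatrix", function(x) x@walks)

#' @rdname WalkFeatureMatrix-class
#' @export
setMethod("featureValues", "WalkFeatureMatrix", function(x) x@values)

#' @rdname WalkFeatureMatrix-class
#' @export
setMethod("droppedWalks", "WalkFeatureMatrix", function(x) x@dropped)

#' @rdname WalkFeatureMatrix-class
#' @export
setMethod("dim", "WalkFeatureMatrix", function(x) dim(x@values))

setMethod("show", "WalkFeatureMatrix", function(object) {
  cat(sprintf("WalkFeatureMatrix: %d entities x %d walks (%d dropped)\n",
              nrow(object@values), ncol(object@values),
              nrow(object@dropped)))
})
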
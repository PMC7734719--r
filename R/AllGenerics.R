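#' @rdname LabeledGraph-class
#' @param x an object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname LabeledGraph-class
#' @export
setGeneric("isConverted", function(x) standardGeneric("isConverted"))

#' @rdname EntityDataset-class
#' @export
setGeneric("entities", function(x) standardGeneric("entities"))

#' @rdname EntityDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname EntityDataset-class
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname Walk-class
#' @export
setGeneric("endLabel", function(x) standardGeneric("endLabel"))

#' @rdname Walk-class
#' @export
setGeneric("walkDepth", function(x) standardGeneric("walkDepth"))

#' @rdname Neighborhood-class
#' @export
setGeneric("nbhDepth", function(x) standardGeneric("nbhDepth"))

#' @rdname Neighborhood-class
#' @param i depth index.
#' @export
setGeneric("levelLabels", function(x, i) standardGeneric("levelLabels"))

#' Test whether a walk is contained in a neighborhood
#'
#' A single set-membership lookup: the walk (x, l) is contained iff label x
#' occurs in the depth-l label set of the neighborhood. No graph traversal
#' is performed.
#'
#' @param nbh a [Neighborhood-class].
#' @param walk a [Walk-class] (or see the character method).
#' @param ... for the character method, `depth` (integer).
#' @return logical scalar.
#' @examples
#' g <- labeledGraph(data.frame(from = c("a", "b"), to = c("b", "c")),
#'                   c(a = "A", b = "B", c = "C"))
#' nb <- extractNeighborhood(g, "a", 2)
#' containsWalk(nb, walk("C", 2))  # TRUE
#' containsWalk(nb, walk("C", 1))  # FALSE: fixed-depth semantics
#' @export
setGeneric("containsWalk", function(nbh, walk, ...)
  standardGeneric("containsWalk"))

#' @rdname WalkForest-class
#' @param x a [WalkForest-class].
#' @export
setGeneric("forestTrees", function(x) standardGeneric("forestTrees"))

#' Export a walk tree in DOT format
#'
#' Renders the tree as a Graphviz digraph: internal nodes show the walk
#' pattern `root -> * -> ... -> label` (depth - 1 wildcard hops) with its
#' information gain and sample count, edges are annotated `found` /
#' `not found`, leaves show class and sample count.
#'
#' @param x a [WalkTree-class].
#' @return a single character string of DOT source.
#' @export
setGeneric("exportDot", function(x) standardGeneric("exportDot"))

#' @rdname WalkFeatureMatrix-class
#' @param x a [WalkFeatureMatrix-class].
#' @export
setGeneric("featureWalks", function(x) standardGeneric("featureWalks"))

#' @rdname WalkFeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname WalkFeatureMatrix-class
#' @export
setGeneric("droppedWalks", function(x) standardGeneric("droppedWalks"))
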
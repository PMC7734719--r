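#' @import methods
#' @importFrom stats predict setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

setOldClass("igraph")

#' Label-only directed graph
#'
#' Container for the directed, vertex-labeled graph the walk miner operates
#' on: either a plain labeled digraph built programmatically, or the result
#' of converting a multi-relational knowledge graph, in which case every
#' triple (s, p, o) contributes a fresh predicate vertex labeled with the
#' predicate IRI and two unlabeled edges s -> p-vertex -> o.
#'
#' Vertices carry three attributes: `name` (an opaque unique id; the IRI,
#' blank-node id or namespaced literal key for entity vertices), `label`
#' (the string matched by walks -- multiple vertices may share a label) and
#' `kind` (`"entity"` or `"predicate"`).
#'
#' @slot graph an [igraph::igraph] directed graph with vertex attributes
#'   `name`, `label` and `kind`.
#' @slot converted logical; `TRUE` when the graph came from
#'   [convertToLabeledGraph()], which switches on the depth-doubling
#'   convention (odd depths land on predicate vertices and are skipped by
#'   default during candidate enumeration).
#'
#' @seealso [labeledGraph()], [convertToLabeledGraph()],
#'   [extractNeighborhood()]
#' @export
setClass("LabeledGraph",
  representation(graph = "igraph", converted = "logical"),
  validity = function(object) {
    g <- object@graph
    msg <- character()
    if (!igraph::is_directed(g))
      msg <- c(msg, "graph must be directed")
    va <- igraph::vertex_attr_names(g)
    for (a in c("name", "label", "kind"))
      if (!a %in% va) msg <- c(msg, sprintf("missing vertex attribute '%s'", a))
    if ("name" %in% va && anyDuplicated(igraph::V(g)$name))
      msg <- c(msg, "vertex names must be unique")
    if ("label" %in% va && anyNA(igraph::V(g)$label))
      msg <- c(msg, "every vertex must have exactly one label")
    if (length(object@converted) != 1L)
      msg <- c(msg, "converted must be a single logical")
    if (length(msg)) msg else TRUE
  }
)

#' Entity/label training data
#'
#' An ordered list of graph entities paired with their class labels.
#' Duplicated entities (with identical labels) are permitted so that
#' bootstrap resamples carry multiplicity into entropy counts.
#'
#' @slot entities character vector of vertex names.
#' @slot labels character vector of class labels, same length.
#'
#' @seealso [entityDataset()], [readEntityLabels()]
#' @export
setClass("EntityDataset",
  representation(entities = "character", labels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@entities) != length(object@labels))
      msg <- c(msg, "entities and labels must have equal length")
    if (length(object@entities) == 0L)
      msg <- c(msg, "dataset must be non-empty")
    if (anyNA(object@entities) || anyNA(object@labels))
      msg <- c(msg, "entities and labels must not contain NA")
    if (length(msg)) msg else TRUE
  }
)

#' Fixed-depth wildcard walk
#'
#' The walk pattern `root -> * -> ... -> x` with `depth - 1` wildcard hops,
#' written as the tuple (end label, depth). A walk is contained in an
#' entity's neighborhood iff some directed walk of exactly `depth` hops from
#' the entity ends at a vertex carrying `endLabel`.
#'
#' @slot endLabel the label the walk must end in.
#' @slot depth number of hops (>= 1).
#'
#' @seealso [walk()], [containsWalk()], [walkString()]
#' @export
setClass("Walk",
  representation(endLabel = "character", depth = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@endLabel) != 1L || is.na(object@endLabel))
      msg <- c(msg, "endLabel must be a single string")
    if (length(object@depth) != 1L || is.na(object@depth) || object@depth < 1L)
      msg <- c(msg, "depth must be a single integer >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' Depth-indexed neighborhood label sets
#'
#' For one root entity, the sets of labels reachable in exactly
#' i = 1, ..., d directed hops (frontier expansion; revisits allowed, so a
#' label may appear at several depths). This is the data structure that
#' makes walk containment a single set-membership test.
#'
#' @slot root vertex name of the root entity.
#' @slot maxDepth extraction depth d.
#' @slot levelLabels list of length d; element i is the character vector of
#'   labels reachable in exactly i hops (possibly empty).
#'
#' @seealso [extractNeighborhood()], [containsWalk()]
#' @export
setClass("Neighborhood",
  representation(root = "character", maxDepth = "integer",
                 levelLabels = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@root) != 1L)
      msg <- c(msg, "root must be a single vertex name")
    if (length(object@maxDepth) != 1L || object@maxDepth < 1L)
      msg <- c(msg, "maxDepth must be a single integer >= 1")
    if (length(object@levelLabels) != object@maxDepth)
      msg <- c(msg, "levelLabels must have one element per depth 1..maxDepth")
    if (!all(vapply(object@levelLabels, is.character, logical(1))))
      msg <- c(msg, "levelLabels elements must be character vectors")
    if (length(msg)) msg else TRUE
  }
)

#' Walk-based decision tree
#'
#' A binary decision tree whose internal nodes test the presence of a mined
#' walk in an entity's neighborhood: the found branch is the left child, the
#' not-found branch the right child. Stored as a nested record: internal
#' nodes are `list(type = "split", end_label, depth, ig, n_samples, found,
#' not_found)`, leaves `list(type = "leaf", class, n_samples)`.
#'
#' @slot root the nested node record.
#' @slot params list of induction parameters (maxWalkDepth, maxTreeDepth,
#'   minSamples, vertexSample, skipOdd).
#'
#' @seealso [buildWalkTree()], [predict,WalkTree-method], [exportDot()]
#' @export
setClass("WalkTree",
  representation(root = "list", params = "list"),
  validity = function(object) {
    ok <- function(nd) {
      if (!is.list(nd) || is.null(nd$type)) return(FALSE)
      if (nd$type == "leaf")
        return(is.character(nd$class) && is.numeric(nd$n_samples))
      if (nd$type == "split")
        return(!is.null(nd$found) && !is.null(nd$not_found) &&
               ok(nd$found) && ok(nd$not_found))
      FALSE
    }
    if (ok(object@root)) TRUE else "malformed tree node structure"
  }
)

#' Ensemble of walk trees
#'
#' @slot trees list of [WalkTree-class] objects.
#' @slot params list with n_trees, bootstrap, vertex_sample, max_tree_depth,
#'   min_samples, max_walk_depth, skip_odd and seed; each tree is
#'   reproducible from the seed and its index.
#'
#' @seealso [buildWalkForest()], [walkImportances()]
#' @export
setClass("WalkForest",
  representation(trees = "list", params = "list"),
  validity = function(object) {
    if (!all(vapply(object@trees, is, logical(1), "WalkTree")))
      return("trees must all be WalkTree objects")
    if (!is.null(object@params$n_trees) &&
        length(object@trees) != object@params$n_trees)
      return("number of trees must equal params$n_trees")
    TRUE
  }
)

#' Binary walk-presence feature matrix
#'
#' Rows are entities, columns are mined walks; entry (i, j) is 1 iff walk j
#' is found in entity i's neighborhood. Backed by a sparse matrix.
#'
#' @slot walks data.frame with columns `end_label`, `depth`, `ig_bits`
#'   (column metadata, in column order).
#' @slot entities character vector of row entities.
#' @slot values sparse numeric 0/1 matrix (Matrix::dgCMatrix).
#' @slot dropped data.frame of walks removed by [pruneColumns()] (same
#'   columns as `walks` plus `column_sum`).
#'
#' @seealso [featurize()], [pruneColumns()], [writeFeatureMatrix()]
#' @export
setClass("WalkFeatureMatrix",
  representation(walks = "data.frame", entities = "character",
                 values = "ANY", dropped = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!methods::is(object@values, "Matrix") && !is.matrix(object@values))
      msg <- c(msg, "values must be a matrix or Matrix")
    if (nrow(object@values) != length(object@entities))
      msg <- c(msg, "row count must equal number of entities")
    if (ncol(object@values) != nrow(object@walks))
      msg <- c(msg, "column count must equal number of walks")
    if (length(msg)) msg else TRUE
  }
)
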
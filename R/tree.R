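# Decision tree induction by recursive walk mining.

.majority_class <- function(y) {
  tab <- table(y)
  winners <- names(tab)[tab == max(tab)]
  sort(winners, method = "radix")[1L]   # deterministic tie: smallest label
}

.leaf <- function(y) list(type = "leaf", class = .majority_class(y),
                          n_samples = length(y))

#' Induce a walk-based decision tree
#'
#' Recursively mines the maximum-information-gain walk on the data reaching
#' a node and splits on its presence: entities containing the walk go to
#' the found (left) child, the rest to the not-found (right) child. A node
#' becomes a leaf when its labels are pure, when `maxTreeDepth` is reached,
#' when fewer than `minSamples` entities reach it (pre-pruning), or when no
#' candidate achieves positive gain (unsplittable impure node); leaf class
#' is the majority class, ties resolved to the lexicographically smallest
#' label.
#'
#' @inheritParams mineWalks
#' @param maxWalkDepth maximum depth of mined walks (graph hops; use
#'   `2 * k` for k entity hops on a converted KG).
#' @param maxTreeDepth maximum tree depth, or `NULL` for unbounded growth
#'   (grow until pure).
#' @param minSamples nodes with fewer entities than this become leaves.
#' @param vertexSample fraction in (0, 1] of walk candidates scored at each
#'   internal node (1 = all; < 1 is the forest's per-node sampling).
#' @param seed optional seed making candidate subsampling reproducible.
#' @return a [WalkTree-class].
#' @examples
#' fx <- makeImbalancedToyGraph()
#' nb <- extractNeighborhoods(fx$graph, entities(fx$data), 1)
#' tr <- buildWalkTree(fx$data, nb, maxWalkDepth = 1)
#' numInternalNodes(tr)  # 2
#' @export
buildWalkTree <- function(data, nbhs, maxWalkDepth, maxTreeDepth = NULL,
                          minSamples = 1, vertexSample = 1,
                          skipOdd = NULL, seed = NULL) {
  stopifnot(is(data, "EntityDataset"))
  if (length(data) < 1L) stop("cannot build a tree from an empty dataset")
  if (vertexSample <= 0 || vertexSample > 1)
    stop("vertexSample must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(skipOdd)) skipOdd <- isTRUE(attr(nbhs, "converted"))
  nb_all <- .aligned_nbhs(data, nbhs)
  .check_nbh_depth(nb_all, maxWalkDepth)

  grow <- function(idx, depth) {
    y <- data@labels[idx]
    if (length(unique(y)) == 1L)
      return(list(type = "leaf", class = y[[1L]], n_samples = length(y)))
    if (!is.null(maxTreeDepth) && depth >= maxTreeDepth) return(.leaf(y))
    if (length(idx) < minSamples) return(.leaf(y))
    sub <- data[idx]
    best <- mineWalks(sub, nbhs, n = 1, maxDepth = maxWalkDepth,
                      skipOdd = skipOdd, candidateFraction = vertexSample)
    if (!nrow(best) || best$ig_bits[[1L]] <= 0) return(.leaf(y))
    w <- walk(best$end_label[[1L]], best$depth[[1L]])
    inwalk <- vapply(nb_all[idx], function(nb)
      w@endLabel %in% nb@levelLabels[[w@depth]], logical(1))
    list(type = "split",
         end_label = w@endLabel, depth = w@depth,
         ig = best$ig_bits[[1L]], n_samples = length(idx),
         found = grow(idx[inwalk], depth + 1L),
         not_found = grow(idx[!inwalk], depth + 1L))
  }

  new("WalkTree", root = grow(seq_along(data@entities), 0L),
      params = list(max_walk_depth = as.integer(maxWalkDepth),
                    max_tree_depth = maxTreeDepth,
                    min_samples = minSamples,
                    vertex_sample = vertexSample,
                    skip_odd = skipOdd))
}

#' Number of internal (walk-testing) nodes of a tree
#'
#' @param x a [WalkTree-class].
#' @return integer count of internal nodes.
#' @export
numInternalNodes <- function(x) {
  count <- function(nd) {
    if (nd$type == "leaf") return(0L)
    1L + count(nd$found) + count(nd$not_found)
  }
  count(x@root)
}

#' Distinct walks used by a tree
#'
#' @param x a [WalkTree-class].
#' @param nodeDepth include the tree depth of each occurrence.
#' @return data.frame with columns `end_label`, `depth` (walk depth) and,
#'   if requested, `node_depth`; one row per internal node occurrence.
#' @export
treeWalks <- function(x, nodeDepth = FALSE) {
  rows <- list()
  visit <- function(nd, d) {
    if (nd$type == "leaf") return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      end_label = nd$end_label, depth = nd$depth, node_depth = d,
      stringsAsFactors = FALSE)
    visit(nd$found, d + 1L)
    visit(nd$not_found, d + 1L)
  }
  visit(x@root, 0L)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(end_label = character(), depth = integer(),
               node_depth = integer())
  if (!nodeDepth) out$node_depth <- NULL
  out
}

.route <- function(node, nbh) {
  path <- list()
  while (node$type == "split") {
    if (node$depth > nbh@maxDepth)
      stop(sprintf(
        "neighborhood depth %d too shallow for tree walk of depth %d",
        nbh@maxDepth, node$depth))
    f <- node$end_label %in% nbh@levelLabels[[node$depth]]
    path[[length(path) + 1L]] <- list(end_label = node$end_label,
                                      depth = node$depth, found = f)
    node <- if (f) node$found else node$not_found
  }
  list(class = node$class, path = path)
}

#' Predict classes with a walk tree
#'
#' Routes each entity's neighborhood through the tree: at every internal
#' node the walk-presence test decides the branch (found = left). The
#' root-to-leaf sequence of decisions is available as a local explanation
#' via [explainPrediction()].
#'
#' @param object a [WalkTree-class].
#' @param nbhs a [Neighborhood-class] or (named) list of them.
#' @param ... unused.
#' @return character vector of predicted class labels (named when `nbhs`
#'   is a named list).
#' @export
setMethod("predict", "WalkTree", function(object, nbhs, ...) {
  if (is(nbhs, "Neighborhood")) nbhs <- list(nbhs)
  vapply(nbhs, function(nb) .route(object@root, nb)$class, character(1))
})

#' Explain a single tree prediction
#'
#' @param tree a [WalkTree-class].
#' @param nbh one [Neighborhood-class].
#' @return list with `class` (predicted label) and `path`, a data.frame of
#'   the root-to-leaf decisions (`walk` pattern string, `depth`, `found`).
#' @export
explainPrediction <- function(tree, nbh) {
  r <- .route(tree@root, nbh)
  path <- if (length(r$path)) do.call(rbind, lapply(r$path, function(p)
    data.frame(walk = walkString(p$end_label, p$depth), depth = p$depth,
               found = p$found, stringsAsFactors = FALSE)))
  else data.frame(walk = character(), depth = integer(), found = logical())
  list(class = r$class, path = path)
}

#' Serialize a walk tree as indented text
#'
#' Stable nested-record rendering (one node per line); identical trees
#' serialize byte-identically, which the induction's determinism tests
#' rely on.
#'
#' @param tree a [WalkTree-class].
#' @return character vector of lines.
#' @export
serializeWalkTree <- function(tree) {
  lines <- character(0)
  visit <- function(nd, indent, tag) {
    pad <- strrep("  ", indent)
    if (nd$type == "leaf") {
      lines[[length(lines) + 1L]] <<- sprintf(
        "%s%sleaf class=%s n=%d", pad, tag, nd$class, nd$n_samples)
    } else {
      lines[[length(lines) + 1L]] <<- sprintf(
        "%s%ssplit walk=(%s, %d) ig=%.6f n=%d", pad, tag, nd$end_label,
        nd$depth, nd$ig, nd$n_samples)
      visit(nd$found, indent + 1L, "found: ")
      visit(nd$not_found, indent + 1L, "not_found: ")
    }
  }
  visit(tree@root, 0L, "")
  lines
}

.dot_quote <- function(x) {
  paste0("\"", gsub("\"", "\\\"", x, fixed = TRUE), "\"")
}

#' @rdname exportDot
#' @export
setMethod("exportDot", "WalkTree", function(x) {
  lines <- c("digraph WalkTree {", "  node [shape=box];")
  counter <- 0L
  visit <- function(nd) {
    counter <<- counter + 1L
    id <- sprintf("n%d", counter)
    if (nd$type == "leaf") {
      lines[[length(lines) + 1L]] <<- sprintf(
        "  %s [label=%s, shape=ellipse];", id,
        .dot_quote(sprintf("%s\\nn=%d", nd$class, nd$n_samples)))
    } else {
      lines[[length(lines) + 1L]] <<- sprintf(
        "  %s [label=%s];", id,
        .dot_quote(sprintf("%s\\nIG=%.4f, n=%d",
                           walkString(nd$end_label, nd$depth),
                           nd$ig, nd$n_samples)))
      fid <- visit(nd$found)
      nid <- visit(nd$not_found)
      lines[[length(lines) + 1L]] <<- sprintf(
        "  %s -> %s [label=\"found\"];", id, fid)
      lines[[length(lines) + 1L]] <<- sprintf(
        "  %s -> %s [label=\"not found\"];", id, nid)
    }
    id
  }
  visit(x@root)
  paste(c(lines, "}"), collapse = "\n")
})
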
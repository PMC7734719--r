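# Ensemble of walk trees: bootstrap resampling of entities plus per-node
# candidate sampling, and global walk importances.

#' Build a forest of walk trees
#'
#' Variance reduction over [buildWalkTree()]: each tree is grown on a
#' bootstrap resample of the entities (sampling `|D|` times with
#' replacement; duplicates carry multiplicity into the entropy counts) and
#' each internal node scores only `ceiling(vertexSample * n_candidates)`
#' uniformly sampled walk candidates. Per-tree seeds are derived
#' deterministically from the master seed, so each tree is independently
#' reproducible; `nTrees = 1, bootstrap = FALSE, vertexSample = 1`
#' degenerates to the single tree exactly.
#'
#' @inheritParams buildWalkTree
#' @param nTrees number of trees (>= 1).
#' @param bootstrap resample entities with replacement per tree.
#' @param vertexSample fraction in (0, 1] of candidates scored per node.
#' @param seed master seed for reproducibility.
#' @return a [WalkForest-class].
#' @export
buildWalkForest <- function(data, nbhs, maxWalkDepth, nTrees = 10,
                            bootstrap = TRUE, vertexSample = 1,
                            maxTreeDepth = NULL, minSamples = 1,
                            skipOdd = NULL, seed = NULL) {
  stopifnot(is(data, "EntityDataset"))
  if (nTrees < 1) stop("nTrees must be >= 1")
  if (!is.numeric(vertexSample) || vertexSample <= 0 || vertexSample > 1)
    stop("vertexSample must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max, nTrees)
  n <- length(data)
  trees <- lapply(seq_len(nTrees), function(i) {
    set.seed(tree_seeds[[i]])
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    buildWalkTree(data[idx], nbhs, maxWalkDepth = maxWalkDepth,
                  maxTreeDepth = maxTreeDepth, minSamples = minSamples,
                  vertexSample = vertexSample, skipOdd = skipOdd)
  })
  new("WalkForest", trees = trees,
      params = list(n_trees = as.integer(nTrees), bootstrap = bootstrap,
                    vertex_sample = vertexSample,
                    max_tree_depth = maxTreeDepth,
                    min_samples = minSamples,
                    max_walk_depth = as.integer(maxWalkDepth),
                    skip_odd = skipOdd, seed = seed))
}

#' Predict classes with a walk forest
#'
#' Majority vote over the per-tree predictions; vote ties resolve to the
#' lexicographically smallest class label.
#'
#' @param object a [WalkForest-class].
#' @param nbhs a [Neighborhood-class] or (named) list of them.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
setMethod("predict", "WalkForest", function(object, nbhs, ...) {
  if (is(nbhs, "Neighborhood")) nbhs <- list(nbhs)
  votes <- vapply(object@trees, function(tr) predict(tr, nbhs),
                  character(length(nbhs)))
  if (length(nbhs) == 1L) votes <- matrix(votes, nrow = 1L)
  apply(votes, 1L, .majority_class)
})

#' Walk importances of a forest
#'
#' Global interpretability summary: every internal-node occurrence of a
#' walk contributes `1 / (1 + node_depth)` to its score (a strictly
#' decreasing position weight -- a walk at a root carries more of the
#' ensemble's decisions than one deep in a tree); `count` is the raw number
#' of occurrences and `root_count` the number of trees using the walk at
#' their root (the root-census style of reporting).
#'
#' @param forest a [WalkForest-class].
#' @return data.frame with columns `end_label`, `depth`, `score`, `count`,
#'   `root_count`, sorted by score (desc), then walk depth and label.
#' @export
walkImportances <- function(forest) {
  occ <- lapply(forest@trees, treeWalks, nodeDepth = TRUE)
  occ <- do.call(rbind, occ)
  if (is.null(occ) || !nrow(occ))
    return(data.frame(end_label = character(), depth = integer(),
                      score = numeric(), count = integer(),
                      root_count = integer()))
  key <- .walk_key(occ$end_label, occ$depth)
  score <- tapply(1 / (1 + occ$node_depth), key, sum)
  count <- tapply(rep(1L, nrow(occ)), key, sum)
  roots <- tapply(occ$node_depth == 0L, key, sum)
  keys <- names(score)
  sp <- regexpr("\x1f", keys, fixed = TRUE)
  out <- data.frame(
    end_label = substr(keys, sp + 1L, nchar(keys)),
    depth = as.integer(substr(keys, 1L, sp - 1L)),
    score = as.vector(score),
    count = as.integer(count[keys]),
    root_count = as.integer(roots[keys]),
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$depth, out$end_label,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write forest walk importances to TSV
#'
#' @param importances data.frame from [walkImportances()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImportances <- function(importances, path) {
  write.table(importances, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
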
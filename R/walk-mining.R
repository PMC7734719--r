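# Information-gain scoring and mining of wildcard walks.

.walk_key <- function(label, depth) paste0(depth, "\x1f", label)

# canonical candidate order: depth asc, then label asc in C locale
.order_candidates <- function(df) {
  df[order(df$depth, df$end_label, method = "radix"), , drop = FALSE]
}

# ranking order for mined walks: IG desc, depth asc, label asc
.rank_walks <- function(df) {
  df[order(-df$ig_bits, df$depth, df$end_label, method = "radix"), ,
     drop = FALSE]
}

#' Shannon entropy of a label vector
#'
#' `H(y) = -sum_k p_k log2 p_k` over the distinct classes of `y`, with
#' `0 * log 0 = 0`. Reported in bits (base-2 logarithm); information-gain
#' rankings are invariant to the base.
#'
#' @param y non-empty vector of class labels.
#' @return entropy in bits.
#' @examples
#' labelEntropy(c("a", "a", "a"))              # 0
#' labelEntropy(c("a", "b"))                   # 1
#' labelEntropy(rep(c("A", "B", "C"), c(8, 2, 2)))  # ~1.2516
#' @export
labelEntropy <- function(y) {
  if (length(y) == 0L) stop("cannot compute entropy of an empty vector")
  p <- tabulate(factor(y))
  p <- p[p > 0] / length(y)
  -sum(p * log2(p))
}

# neighborhoods aligned to a dataset's entities (duplicates allowed so
# bootstrap multiplicity enters the counts)
.aligned_nbhs <- function(data, nbhs) {
  if (is.null(names(nbhs)))
    stop("neighborhoods must be a named list keyed by entity")
  miss <- setdiff(unique(data@entities), names(nbhs))
  if (length(miss))
    stop("missing neighborhoods for entities: ",
         paste(miss, collapse = ", "))
  nbhs[data@entities]
}

.check_nbh_depth <- function(nbhs, depth) {
  d <- vapply(nbhs, function(nb) nb@maxDepth, integer(1))
  if (any(d < depth))
    stop(sprintf("neighborhood depth %d < required walk depth %d",
                 min(d), depth))
}

#' Partition a dataset on walk presence
#'
#' Splits the dataset into the entities whose neighborhood contains the
#' walk (`found`) and those whose neighborhood does not (`not_found`),
#' preserving dataset order. Membership is decided solely through
#' [containsWalk()].
#'
#' @param data an [EntityDataset-class].
#' @param walk a [Walk-class].
#' @param nbhs named list of [Neighborhood-class] objects keyed by entity,
#'   as returned by [extractNeighborhoods()].
#' @return list with elements `found` and `not_found` (each an
#'   [EntityDataset-class] or `NULL` when empty).
#' @export
partitionByWalk <- function(data, walk, nbhs) {
  nb <- .aligned_nbhs(data, nbhs)
  .check_nbh_depth(nb, walk@depth)
  f <- vapply(nb, function(x) walk@endLabel %in% x@levelLabels[[walk@depth]],
              logical(1))
  list(found = if (any(f)) data[which(f)] else NULL,
       not_found = if (any(!f)) data[which(!f)] else NULL)
}

#' Information gain of a walk
#'
#' `IG(D, w) = H(D) - (|Df|/|D|) H(Df) - (|Dnf|/|D|) H(Dnf)` where `Df` /
#' `Dnf` are the found / not-found partitions induced by the walk.
#' Degenerate partitions (walk found for all or no entities) give 0.
#'
#' @inheritParams partitionByWalk
#' @return information gain in bits (non-negative, bounded by `H(D)`).
#' @export
infoGain <- function(data, walk, nbhs) {
  part <- partitionByWalk(data, walk, nbhs)
  if (is.null(part$found) || is.null(part$not_found)) return(0)
  n <- length(data)
  nf <- length(part$found)
  ig <- labelEntropy(data@labels) -
    (nf / n) * labelEntropy(part$found@labels) -
    ((n - nf) / n) * labelEntropy(part$not_found@labels)
  max(ig, 0)
}

#' Enumerate candidate walks from neighborhoods
#'
#' The candidate space is the union over the supplied neighborhoods of the
#' (label, depth) pairs actually present. This is equivalent, for the
#' purposes of maximizing information gain, to sweeping all graph vertices
#' times depths: a walk found in no training neighborhood induces the
#' degenerate partition and has zero gain.
#'
#' @param nbhs named list of [Neighborhood-class] objects.
#' @param maxDepth maximum walk depth to enumerate (defaults to the
#'   smallest neighborhood depth).
#' @param skipOdd if `TRUE`, only even depths are enumerated: in a
#'   converted KG odd depths land on predicate vertices, whose presence
#'   usually carries little information (k entity hops = depth 2k). Default
#'   is taken from the `converted` attribute of `nbhs` (`TRUE` for
#'   converted KGs, `FALSE` for plain graphs).
#' @return data.frame with columns `end_label`, `depth`, ordered by depth
#'   then label.
#' @export
enumerateCandidates <- function(nbhs, maxDepth = NULL, skipOdd = NULL) {
  if (is.null(skipOdd)) skipOdd <- isTRUE(attr(nbhs, "converted"))
  depths_avail <- vapply(nbhs, function(nb) nb@maxDepth, integer(1))
  if (is.null(maxDepth)) maxDepth <- min(depths_avail)
  maxDepth <- as.integer(maxDepth)
  if (maxDepth < 1L) stop("maxDepth must be >= 1")
  lab <- character(0); dep <- integer(0)
  for (nb in nbhs) {
    for (i in seq_len(min(maxDepth, nb@maxDepth))) {
      if (skipOdd && i %% 2L == 1L) next
      ls <- nb@levelLabels[[i]]
      if (length(ls)) { lab <- c(lab, ls); dep <- c(dep, rep(i, length(ls))) }
    }
  }
  df <- unique(data.frame(end_label = lab, depth = dep,
                          stringsAsFactors = FALSE))
  .order_candidates(df)
}

# sparse entity x candidate presence matrix
.presence_matrix <- function(nbhs, candidates) {
  cand_keys <- .walk_key(candidates$end_label, candidates$depth)
  n <- length(nbhs)
  ii <- vector("list", n); jj <- vector("list", n)
  for (e in seq_len(n)) {
    lv <- nbhs[[e]]@levelLabels
    keys <- unlist(lapply(seq_along(lv), function(i)
      if (length(lv[[i]])) .walk_key(lv[[i]], i) else character(0)),
      use.names = FALSE)
    j <- match(keys, cand_keys)
    j <- j[!is.na(j)]
    ii[[e]] <- rep.int(e, length(j)); jj[[e]] <- j
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                       x = 1, dims = c(n, nrow(candidates)))
}

# vectorized IG for all candidate columns of presence matrix P
.score_candidates <- function(y, P) {
  yf <- factor(y)
  n <- length(y)
  Y <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(yf), x = 1,
                            dims = c(n, nlevels(yf)))
  Cf <- as.matrix(Matrix::crossprod(P, Y))      # candidates x classes
  nf <- rowSums(Cf)
  tot <- tabulate(yf, nbins = nlevels(yf))
  Cnf <- sweep(-Cf, 2, tot, "+")
  row_entropy <- function(M, s) {
    p <- M / ifelse(s > 0, s, 1)
    t <- p * log2(p)
    t[M == 0] <- 0
    -rowSums(t)
  }
  H0 <- labelEntropy(y)
  ig <- H0 - (nf / n) * row_entropy(Cf, nf) -
    ((n - nf) / n) * row_entropy(Cnf, n - nf)
  list(ig = pmax(ig, 0), n_found = nf)
}

# shared scoring core; returns full ranked candidate table
.mine_scored <- function(data, nbhs, maxDepth, skipOdd, candidateFraction) {
  nb <- .aligned_nbhs(data, nbhs)
  if (is.null(skipOdd)) skipOdd <- isTRUE(attr(nbhs, "converted"))
  if (is.null(maxDepth))
    maxDepth <- min(vapply(nb, function(x) x@maxDepth, integer(1)))
  .check_nbh_depth(nb, maxDepth)
  cands <- enumerateCandidates(nb, maxDepth, skipOdd)
  if (!nrow(cands))
    return(data.frame(end_label = character(), depth = integer(),
                      ig_bits = numeric(), n_found = numeric()))
  if (candidateFraction < 1) {
    m <- nrow(cands)
    take <- sort(sample.int(m, ceiling(candidateFraction * m)))
    cands <- cands[take, , drop = FALSE]
  }
  P <- .presence_matrix(nb, cands)
  sc <- .score_candidates(data@labels, P)
  out <- data.frame(end_label = cands$end_label, depth = cands$depth,
                    ig_bits = sc$ig, n_found = sc$n_found,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  .rank_walks(out)
}

#' Mine the most informative walks
#'
#' Scores every candidate walk (label, depth) by information gain over the
#' dataset and returns the top `n`, ranked by gain (descending) with
#' deterministic tie-breaking: smaller depth first, then lexicographically
#' smaller end label. Scoring touches each (neighborhood, candidate) pair
#' once, i.e. `O(d |V_train| |V|)` for the full candidate sweep.
#'
#' @inheritParams partitionByWalk
#' @param n number of walks to return (fewer if fewer candidates exist).
#' @param maxDepth maximum walk depth (default: neighborhood depth).
#' @param skipOdd skip odd depths; see [enumerateCandidates()].
#' @param candidateFraction fraction in (0, 1] of candidates scored; when
#'   < 1 a uniform sample without replacement is drawn (the forest's
#'   per-node `vertex_sample`). Uses the current RNG state unless `seed`
#'   is given.
#' @param seed optional integer seed for the candidate subsample.
#' @return data.frame with columns `end_label`, `depth`, `ig_bits`,
#'   `n_found` (number of training entities containing the walk); zero
#'   rows when there are no candidates.
#' @examples
#' fx <- makeImbalancedToyGraph()
#' nb <- extractNeighborhoods(fx$graph, entities(fx$data), 1)
#' mineWalks(fx$data, nb, n = 3)
#' @export
mineWalks <- function(data, nbhs, n = 1, maxDepth = NULL, skipOdd = NULL,
                      candidateFraction = 1, seed = NULL) {
  stopifnot(is(data, "EntityDataset"))
  if (n < 1) stop("n must be >= 1")
  if (!is.numeric(candidateFraction) || candidateFraction <= 0 ||
      candidateFraction > 1)
    stop("candidateFraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  scored <- .mine_scored(data, nbhs, maxDepth, skipOdd, candidateFraction)
  head(scored, n)
}

#' Write mined walks to TSV
#'
#' @param walks data.frame as returned by [mineWalks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWalks <- function(walks, path) {
  write.table(walks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
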
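# Single-pass top-K walk mining and binary feature matrices.

#' Mine the top-K walks in a single pass
#'
#' Decouples walk mining from model induction: one sweep over all
#' candidates keeps the K highest-gain walks, which then define binary
#' feature vectors for any downstream classifier.
#'
#' Global mode ranks all candidates by information gain on the full
#' dataset. On imbalanced multi-class data this can spend the whole budget
#' on walks separating the majority class from the rest; per-class mode
#' instead makes C passes, binarizing the labels one-vs-rest per class and
#' mining `floor(K / C)` walks per pass, then deduplicates keeping the
#' first occurrence (the result is not topped back up to K).
#'
#' @inheritParams mineWalks
#' @param K total number of walks to keep (`K >= C` in per-class mode).
#' @param mode `"global"` or `"per_class"`.
#' @return data.frame of walks (`end_label`, `depth`, `ig_bits`,
#'   `n_found`); in per-class mode `ig_bits`/`n_found` refer to the
#'   binarized pass that mined the walk. Warns and returns everything
#'   available when fewer candidates than requested exist.
#' @examples
#' fx <- makeImbalancedToyGraph()
#' nb <- extractNeighborhoods(fx$graph, entities(fx$data), 1)
#' mineTopK(fx$data, nb, K = 6)             # the 5 majority walks + one more
#' @export
mineTopK <- function(data, nbhs, K, maxDepth = NULL,
                     mode = c("global", "per_class"), skipOdd = NULL,
                     seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(data, "EntityDataset"))
  if (K < 1) stop("K must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cls <- classNames(data)
  if (mode == "global") {
    scored <- .mine_scored(data, nbhs, maxDepth, skipOdd, 1)
    if (nrow(scored) < K)
      warning(sprintf("only %d candidate walks available (K = %d)",
                      nrow(scored), K))
    return(head(scored, K))
  }
  C <- length(cls)
  if (K < C)
    stop(sprintf("per-class mode needs K >= number of classes (%d)", C))
  kc <- K %/% C
  per <- lapply(cls, function(k) {
    bin <- entityDataset(data@entities,
                         ifelse(data@labels == k, "1", "0"))
    head(.mine_scored(bin, nbhs, maxDepth, skipOdd, 1), kc)
  })
  out <- do.call(rbind, per)
  dup <- duplicated(.walk_key(out$end_label, out$depth))
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < K && all(vapply(per, nrow, integer(1)) < kc))
    warning(sprintf("only %d candidate walks available (K = %d)",
                    nrow(out), K))
  out
}

#' Build a binary walk-presence feature matrix
#'
#' Evaluates each walk against each entity's neighborhood; entry (i, j) is
#' 1 iff walk j is contained in entity i's neighborhood. Test entities are
#' featurized with the same walk columns mined on training data.
#'
#' @param walks data.frame of walks (`end_label`, `depth`, optionally
#'   `ig_bits`) as produced by [mineTopK()] or [mineWalks()].
#' @param entities character vector of entities (matrix rows).
#' @param nbhs named list of [Neighborhood-class] covering all `entities`
#'   at depth >= the deepest walk.
#' @return a [WalkFeatureMatrix-class].
#' @export
featurize <- function(walks, entities, nbhs) {
  miss <- setdiff(entities, names(nbhs))
  if (length(miss))
    stop("missing neighborhoods for entities: ",
         paste(miss, collapse = ", "))
  nb <- nbhs[entities]
  if (nrow(walks)) .check_nbh_depth(nb, max(walks$depth))
  meta <- data.frame(
    end_label = as.character(walks$end_label),
    depth = as.integer(walks$depth),
    ig_bits = if ("ig_bits" %in% names(walks)) walks$ig_bits
              else rep(NA_real_, nrow(walks)),
    stringsAsFactors = FALSE)
  vals <- if (nrow(meta)) .presence_matrix(nb, meta) else
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(entities), 0L))
  new("WalkFeatureMatrix", walks = meta, entities = as.character(entities),
      values = vals, dropped = data.frame())
}

#' Drop uninformative feature columns
#'
#' Removes walks found in exactly one training entity or in all of them
#' (column sum 1 or `|entities|`); such columns cannot support a useful
#' split and typically reflect idiosyncratic or ubiquitous substructures.
#' Dropped walks are recorded in the `dropped` slot.
#'
#' @param matrix a [WalkFeatureMatrix-class] built on training entities.
#' @return the pruned [WalkFeatureMatrix-class].
#' @export
pruneColumns <- function(matrix) {
  cs <- Matrix::colSums(matrix@values)
  n <- length(matrix@entities)
  drop <- cs == 1 | cs == n
  dropped <- matrix@walks[drop, , drop = FALSE]
  if (nrow(dropped)) dropped$column_sum <- cs[drop]
  new("WalkFeatureMatrix",
      walks = matrix@walks[!drop, , drop = FALSE],
      entities = matrix@entities,
      values = matrix@values[, !drop, drop = FALSE],
      dropped = rbind(matrix@dropped, dropped))
}

#' Write a feature matrix to MTX + metadata TSV
#'
#' Writes the sparse binary matrix in MatrixMarket format plus two TSVs:
#' column metadata (`end_label`, `depth`, `ig_bits`) and row entities.
#'
#' @param matrix a [WalkFeatureMatrix-class].
#' @param prefix output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>_walks.tsv`, `<prefix>_entities.tsv`.
#' @return the MTX path, invisibly.
#' @export
writeFeatureMatrix <- function(matrix, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(methods::as(matrix@values, "CsparseMatrix"),
                              "generalMatrix"), mtx)
  write.table(matrix@walks, paste0(prefix, "_walks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(entity = matrix@entities),
              paste0(prefix, "_entities.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(mtx)
}

#' Test linear separability of labeled feature vectors
#'
#' Certificate-style check used to ask how many top-gain walks are needed
#' before a linear model can split the classes perfectly. Two entities with
#' identical feature rows but different labels are proof of inseparability;
#' otherwise a multinomial logistic regression (argmax of linear scores) is
#' fit and perfect training accuracy certifies separability.
#'
#' @param X numeric matrix (rows = entities); a sparse Matrix is accepted.
#' @param y class labels, length `nrow(X)`.
#' @return logical scalar.
#' @export
isLinearlySeparable <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) return(TRUE)
  rowkey <- apply(X, 1L, paste, collapse = "\x1f")
  conflicts <- tapply(y, rowkey, function(v) length(unique(v)))
  if (any(conflicts > 1L)) return(FALSE)
  if (ncol(X) == 0L) return(FALSE)
  df <- data.frame(.y = factor(y), X)
  fit <- nnet::multinom(.y ~ ., data = df, maxit = 500, trace = FALSE,
                        MaxNWts = 100000)
  all(as.character(predict(fit, df)) == y)
}

#' Coefficient inspection for walk features
#'
#' Thin adapter around a user-fit linear model: pairs each walk column with
#' its coefficient so the most positive / negative walks can be read off,
#' mirroring the usual L1-logistic-regression inspection workflow.
#' No classifier is implemented here; pass coefficients from e.g.
#' `glmnet::glmnet(x = featureValues(m), y, family = "binomial")`.
#'
#' @param matrix a [WalkFeatureMatrix-class].
#' @param coefficients numeric vector, one per walk column (intercept
#'   excluded).
#' @return data.frame `walk` (pattern string), `end_label`, `depth`,
#'   `coefficient`, sorted by coefficient descending.
#' @export
walkCoefficients <- function(matrix, coefficients) {
  w <- matrix@walks
  if (length(coefficients) != nrow(w))
    stop("need exactly one coefficient per walk column")
  out <- data.frame(
    walk = vapply(seq_len(nrow(w)), function(i)
      walkString(w$end_label[i], w$depth[i]), character(1)),
    end_label = w$end_label, depth = w$depth,
    coefficient = as.numeric(coefficients), stringsAsFactors = FALSE)
  out[order(-out$coefficient), , drop = FALSE]
}
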
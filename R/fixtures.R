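# Deterministic generators: the imbalanced three-class worked example,
# random labeled digraphs, and knowledge graphs with planted
# class-discriminative walks.

#' The imbalanced three-class toy graph
#'
#' Builds the small artificial graph that motivates per-class mining: a
#' plain directed graph with 12 labeled training entities -- 8 of class A,
#' each linked to every one of the shared nodes "1".."5"; 2 of class B,
#' each linked to node "6"; and 2 of class C, each linked to node "7" --
#' and no other edges. Two walks suffice for perfect separation (one of
#' ("1".."5", 1) plus one of ("6"/"7", 1)), and an unpruned decision tree
#' finds exactly those two; a global single-pass top-K ranking instead
#' needs K = 6 because all five majority-class walks outscore ("6", 1) and
#' ("7", 1) on the full dataset (0.9183 vs 0.6500 bits).
#'
#' @return list with `graph` (a plain [LabeledGraph-class]; odd depths are
#'   meaningful, so candidate enumeration keeps them) and `data` (the
#'   12-entity [EntityDataset-class] with classes A, B, C).
#' @examples
#' fx <- makeImbalancedToyGraph()
#' fx$data
#' @export
makeImbalancedToyGraph <- function() {
  a <- paste0("A", 1:8); b <- paste0("B", 1:2); c_ <- paste0("C", 1:2)
  shared <- as.character(1:7)
  labels <- setNames(c(a, b, c_, shared), c(a, b, c_, shared))
  edges <- rbind(
    expand.grid(from = a, to = as.character(1:5),
                stringsAsFactors = FALSE),
    data.frame(from = b, to = "6", stringsAsFactors = FALSE),
    data.frame(from = c_, to = "7", stringsAsFactors = FALSE))
  list(graph = labeledGraph(edges, labels),
       data = entityDataset(c(a, b, c_),
                            rep(c("A", "B", "C"), c(8, 2, 2))))
}

#' Random labeled directed graph
#'
#' Erdos-Renyi style G(n, p) digraph with labels drawn uniformly from a
#' small alphabet; substrate for oracle-equivalence testing.
#'
#' @param nVertices number of vertices.
#' @param nLabels size of the label alphabet (`"L1"`, `"L2"`, ...).
#' @param edgeProb directed edge probability in (0, 1] (0 allowed: edgeless).
#' @param seed integer seed; the graph is fully determined by it.
#' @return a plain [LabeledGraph-class] with vertices `v1..vn`.
#' @export
makeRandomGraph <- function(nVertices, nLabels, edgeProb, seed) {
  if (edgeProb < 0 || edgeProb > 1) stop("edgeProb must be in [0, 1]")
  set.seed(seed)
  g <- igraph::sample_gnp(nVertices, edgeProb, directed = TRUE)
  igraph::V(g)$name <- paste0("v", seq_len(nVertices))
  igraph::V(g)$label <- sample(paste0("L", seq_len(nLabels)), nVertices,
                               replace = TRUE)
  igraph::V(g)$kind <- "entity"
  new("LabeledGraph", graph = g, converted = FALSE)
}

#' Specification for a planted-walk knowledge graph
#'
#' Describes a synthetic KG in which chosen classes carry a
#' class-discriminative walk: after conversion, each planted (class,
#' depth 2k, label) walk is present in exactly
#' `ceiling(penetrance * n_class)` entities of that class and in no entity
#' of any other class, on top of class-independent background noise.
#'
#' @param nPerClass entities per class (scalar or one per class).
#' @param nClasses number of classes C.
#' @param planted list of plantings, each
#'   `list(class = <1..C>, depth = <even 2k>, label = <signal IRI>,
#'   penetrance = <(0,1]>)`.
#' @param nNoisePredicates,nNoiseObjects size of the background predicate /
#'   object pools.
#' @param edgesPerEntity background triples emitted per entity.
#' @param seed integer seed.
#' @return validated spec (class `PlantedKGSpec`).
#' @seealso [makePlantedKG()]
#' @export
plantedKGSpec <- function(nPerClass, nClasses, planted,
                          nNoisePredicates = 3, nNoiseObjects = 10,
                          edgesPerEntity = 3, seed = 1) {
  nPerClass <- rep_len(as.integer(nPerClass), nClasses)
  noise_labels <- c(paste0("noise:p", seq_len(nNoisePredicates)),
                    paste0("noise:o", seq_len(nNoiseObjects)))
  for (p in planted) {
    if (!all(c("class", "depth", "label", "penetrance") %in% names(p)))
      stop("each planting needs class, depth, label, penetrance")
    if (p$depth %% 2L != 0L || p$depth < 2L)
      stop("planted depths must be even (entity positions after conversion)")
    if (p$penetrance <= 0 || p$penetrance > 1)
      stop("penetrance must be in (0, 1]")
    if (p$class < 1L || p$class > nClasses)
      stop("planted class index out of range")
    if (p$label %in% noise_labels)
      stop("signal label '", p$label, "' collides with noise labels")
  }
  structure(list(nPerClass = nPerClass, nClasses = as.integer(nClasses),
                 planted = planted,
                 nNoisePredicates = as.integer(nNoisePredicates),
                 nNoiseObjects = as.integer(nNoiseObjects),
                 edgesPerEntity = as.integer(edgesPerEntity),
                 seed = as.integer(seed)),
            class = "PlantedKGSpec")
}

#' Generate a knowledge graph with planted discriminative walks
#'
#' Emits a triple table realizing a [plantedKGSpec()]: per planted walk of
#' depth 2k, a k-entity-hop chain from each carrier entity ends in the
#' signal node (intermediate nodes are private to the carrier, so the walk
#' can never leak into another entity's neighborhood); background noise
#' consists of class-independent entity -> noise-object triples, and noise
#' objects are chained among themselves so deeper levels are populated for
#' every class. Fully determined by the spec's seed.
#'
#' @param spec a `PlantedKGSpec`.
#' @return list with `triples` (data.frame in [readTriples()] layout),
#'   `data` (the [EntityDataset-class] of all entities) and `planted`
#'   (data.frame of walk `end_label`/`depth`/`class` actually planted).
#' @examples
#' sp <- plantedKGSpec(6, 2, list(list(class = 1, depth = 2,
#'                                     label = "sig:T", penetrance = 1)))
#' kg <- makePlantedKG(sp)
#' g <- convertToLabeledGraph(kg$triples)
#' @export
makePlantedKG <- function(spec) {
  stopifnot(inherits(spec, "PlantedKGSpec"))
  set.seed(spec$seed)
  classes <- paste0("c", seq_len(spec$nClasses))
  ents <- unlist(lapply(seq_len(spec$nClasses), function(k)
    paste0("ent:", classes[k], "e", seq_len(spec$nPerClass[k]))))
  ecls <- rep(classes, spec$nPerClass)
  rows <- list()
  add <- function(s, p, o) rows[[length(rows) + 1L]] <<-
    .triple_row(s, "iri", p, o, "iri")
  # every entity carries a class-independent type triple, so each one is a
  # graph vertex even under a no-noise spec (the shared type has zero gain)
  for (e in ents) add(e, RDF_TYPE_IRI, "ont:Entity")
  # planted signal chains
  planted_df <- list()
  for (j in seq_along(spec$planted)) {
    pl <- spec$planted[[j]]
    cls_ents <- ents[ecls == classes[pl$class]]
    m <- ceiling(pl$penetrance * length(cls_ents))
    carriers <- sort(sample(cls_ents, m))
    k <- pl$depth %/% 2L
    for (e in carriers) {
      prev <- e
      if (k > 1L) for (h in seq_len(k - 1L)) {
        mid <- paste0("mid:", e, "_w", j, "_", h)
        add(prev, paste0("sig:p", j, "_", h), mid)
        prev <- mid
      }
      add(prev, paste0("sig:p", j, "_", k), pl$label)
    }
    planted_df[[j]] <- data.frame(end_label = pl$label,
                                  depth = as.integer(pl$depth),
                                  class = classes[pl$class],
                                  stringsAsFactors = FALSE)
  }
  # class-independent background noise
  if (spec$edgesPerEntity > 0L && spec$nNoiseObjects > 0L) {
    preds <- paste0("noise:p", seq_len(spec$nNoisePredicates))
    objs <- paste0("noise:o", seq_len(spec$nNoiseObjects))
    for (e in ents) {
      for (t in seq_len(spec$edgesPerEntity))
        add(e, sample(preds, 1L), sample(objs, 1L))
    }
    # chain noise objects so depths > 2 are populated for every class
    for (o in objs)
      add(o, sample(preds, 1L), sample(objs, 1L))
  }
  triples <- if (length(rows))
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  else .empty_triples()
  rownames(triples) <- NULL
  list(triples = triples, data = entityDataset(ents, ecls),
       planted = do.call(rbind, planted_df))
}

#' Write the toy graph as plain-text fixtures
#'
#' Writes the graph of [makeImbalancedToyGraph()] as an edge TSV
#' (`edges.tsv`: from, to), a node-label TSV (`nodes.tsv`: node, label)
#' and an entity-label TSV (`labels.tsv`: entity, label).
#'
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeToyGraphFixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- makeImbalancedToyGraph()
  g <- fx$graph@graph
  el <- igraph::as_edgelist(g)
  write.table(data.frame(from = el[, 1], to = el[, 2]),
              file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(node = igraph::V(g)$name,
                         label = igraph::V(g)$label),
              file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(entity = entities(fx$data),
                         label = classLabels(fx$data)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
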
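# Conversion of a multi-relational KG (triple table) into the label-only
# directed graph the walk miner operates on.

# Internal vertex keys: IRIs and blank nodes use their own string; literals
# are namespaced so a literal "x" never collides with an IRI x. The visible
# vertex label is the IRI string / blank node id / literal lexical form.
.term_key <- function(value, type) {
  ifelse(type == "literal", paste0("\x1eL\x1e", value), value)
}

#' Convert triples to a label-only directed graph
#'
#' Each kept triple (s, p, o) becomes three labeled vertices and two
#' unlabeled directed edges `s -> p-vertex -> o`. The predicate vertex is
#' fresh per triple occurrence (its label, the predicate IRI, is shared but
#' its identity is not): sharing one predicate vertex across triples would
#' merge unrelated triples and create spurious walks such as `a -> p -> c`
#' from the triples (a, p, b) and (x, p, c). Subject/object vertices are
#' shared across triples by term identity; identical literal lexical forms
#' map to one vertex.
#'
#' After converting `T` triples over `E` distinct entity terms with no
#' exclusions, the graph has `E + T` vertices and `2 * T` edges.
#'
#' @param triples triple table as returned by [readTriples()].
#' @param excludePredicates character vector of predicate IRIs to drop
#'   before conversion (label-leaking predicates).
#' @return a [LabeledGraph-class] with `converted = TRUE`, which makes
#'   depth-doubling the default downstream (entities sit at even depths;
#'   odd depths are predicate vertices).
#' @examples
#' tr <- data.frame(subject = c("a", "a"), subject_type = "iri",
#'                  predicate = "p",
#'                  object = c("b", "c"), object_type = "iri",
#'                  object_lang = NA, object_datatype = NA)
#' g <- convertToLabeledGraph(tr)
#' numVertices(g)  # 3 entities + 2 predicate vertices
#' numEdges(g)     # 4
#' @export
convertToLabeledGraph <- function(triples, excludePredicates = character()) {
  keep <- !(triples$predicate %in% excludePredicates)
  tr <- triples[keep, , drop = FALSE]
  nT <- nrow(tr)
  skey <- .term_key(tr$subject, tr$subject_type)
  okey <- .term_key(tr$object, tr$object_type)
  ekeys <- unique(c(skey, okey))
  nE <- length(ekeys)
  # display labels for entity vertices: first-seen term value per key
  allkeys <- c(skey, okey)
  allvals <- c(tr$subject, tr$object)
  elabels <- allvals[match(ekeys, allkeys)]
  pnames <- if (nT) paste0("\x1eP\x1e", seq_len(nT)) else character(0)
  g <- igraph::make_empty_graph(n = nE + nT, directed = TRUE)
  igraph::V(g)$name <- c(ekeys, pnames)
  igraph::V(g)$label <- c(elabels, tr$predicate)
  igraph::V(g)$kind <- c(rep("entity", nE), rep("predicate", nT))
  if (nT) {
    si <- match(skey, ekeys)
    oi <- match(okey, ekeys)
    pv <- nE + seq_len(nT)
    g <- igraph::add_edges(g, as.vector(rbind(si, pv, pv, oi)))
  }
  new("LabeledGraph", graph = g, converted = TRUE)
}

#' Look up entity vertices by term
#'
#' Maps entity terms (IRIs, blank node ids or literal lexical forms) to the
#' vertex names used inside a converted [LabeledGraph-class].
#'
#' @param graph a [LabeledGraph-class].
#' @param terms character vector of entity terms.
#' @return character vector of vertex names (`NA` where unresolvable).
#' @export
resolveEntities <- function(graph, terms) {
  vn <- igraph::V(graph@graph)$name
  kind <- igraph::V(graph@graph)$kind
  ent <- vn[kind == "entity"]
  out <- ifelse(terms %in% ent, terms, NA_character_)
  # literals are stored under a namespaced key
  litkey <- .term_key(terms, "literal")
  miss <- is.na(out) & litkey %in% ent
  out[miss] <- litkey[miss]
  out
}

#' Read an entity-label table
#'
#' Reads a UTF-8 TSV with header columns `entity` and `label` (entity IRI
#' and class label) and resolves each entity against the graph's entity
#' vertices. Rows duplicated with an identical label are collapsed with a
#' warning; duplicates with conflicting labels are an error.
#'
#' @param path TSV file path.
#' @param graph the [LabeledGraph-class] the entities must live in.
#' @return an [EntityDataset-class] in file order.
#' @export
readEntityLabels <- function(path, graph) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("entity", "label") %in% names(df)))
    stop("entity label file must have header columns 'entity' and 'label'")
  if (!nrow(df)) stop("entity label file has no rows")
  if (anyDuplicated(df$entity)) {
    agg <- tapply(df$label, df$entity, function(x) length(unique(x)))
    bad <- names(agg)[agg > 1L]
    if (length(bad))
      stop("conflicting labels for entities: ", paste(bad, collapse = ", "))
    warning("collapsing duplicated entity rows with identical labels")
    df <- df[!duplicated(df$entity), , drop = FALSE]
  }
  resolved <- resolveEntities(graph, df$entity)
  if (anyNA(resolved))
    stop("entities not found in graph: ",
         paste(df$entity[is.na(resolved)], collapse = ", "))
  entityDataset(resolved, df$label)
}
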
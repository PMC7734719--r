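# Independent oracles: explicit enumeration of individual walks by
# recursive descent (no frontier sets), and a direct information-gain
# sweep on top of it.

oracle_level_labels <- function(graph, root, d) {
  g <- asIgraph(graph)
  adj <- lapply(igraph::as_adj_list(g, mode = "out"), as.integer)
  labels <- igraph::V(g)$label
  res <- replicate(d, character(0), simplify = FALSE)
  rec <- function(v, depth) {
    if (depth == d) return(invisible())
    for (u in adj[[v]]) {
      res[[depth + 1L]] <<- c(res[[depth + 1L]], labels[[u]])
      rec(u, depth + 1L)
    }
  }
  rec(match(root, igraph::V(g)$name), 0L)
  lapply(res, function(x) sort(unique(x), method = "radix"))
}

oracle_entropy <- function(y) {
  p <- as.numeric(table(y)) / length(y)
  -sum(p * log2(p))
}

oracle_ig <- function(y, found) {
  if (all(found) || !any(found)) return(0)
  n <- length(y)
  oracle_entropy(y) -
    (sum(found) / n) * oracle_entropy(y[found]) -
    (sum(!found) / n) * oracle_entropy(y[!found])
}

# max IG over ALL (graph label, depth <= d) pairs, by explicit enumeration
oracle_best_ig <- function(graph, data, d) {
  levels <- lapply(entities(data), function(e)
    oracle_level_labels(graph, e, d))
  y <- classLabels(data)
  all_labels <- unique(igraph::V(asIgraph(graph))$label)
  best <- 0
  for (l in seq_len(d)) {
    for (lab in all_labels) {
      found <- vapply(levels, function(lv) lab %in% lv[[l]], logical(1))
      best <- max(best, oracle_ig(y, found))
    }
  }
  best
}
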
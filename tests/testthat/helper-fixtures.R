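# Shared fixture builders (all data generated in code; no files).

toy <- function() {
  fx <- makeImbalancedToyGraph()
  fx$nbhs <- extractNeighborhoods(fx$graph, entities(fx$data), 1)
  fx
}

# small triple table helper
triples_of <- function(s, p, o, o_type = "iri") {
  data.frame(subject = s, subject_type = "iri", predicate = p,
             object = o, object_type = o_type,
             object_lang = NA_character_, object_datatype = NA_character_,
             stringsAsFactors = FALSE)
}

# random triple set over a pool of entity IRIs (duplicate triples excluded
# so the |V| = E + T identity is exercised on distinct triples)
random_triples <- function(seed, n_triples = 20, n_entities = 8,
                           n_preds = 4) {
  set.seed(seed)
  pool <- paste0("e", seq_len(n_entities))
  preds <- paste0("p", seq_len(n_preds))
  df <- unique(data.frame(s = sample(pool, 3 * n_triples, replace = TRUE),
                          p = sample(preds, 3 * n_triples, replace = TRUE),
                          o = sample(pool, 3 * n_triples, replace = TRUE),
                          stringsAsFactors = FALSE))
  df <- head(df, n_triples)
  triples_of(df$s, df$p, df$o)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
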
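test_that("N-Triples files parse in file order, with counts and literals preserved", {
  f <- withr::local_tempfile(fileext = ".nt")
  writeLines(c('<urn:a> <urn:p> <urn:b> .',
               '<urn:a> <urn:q> "v \\"quoted\\"\\n"@en .',
               '_:b1 <urn:p> "0.016"^^<http://www.w3.org/2001/XMLSchema#double> .'),
             f)
  tr <- readTriples(f, "ntriples")
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$subject, c("urn:a", "urn:a", "_:b1"))
  expect_equal(tr$object[2], "v \"quoted\"\n")
  expect_equal(tr$object_lang[2], "en")
  expect_equal(tr$object[3], "0.016")
  expect_equal(tr$object_type, c("iri", "literal", "literal"))

  # empty file
  f2 <- withr::local_tempfile(fileext = ".nt")
  writeLines(character(0), f2)
  expect_equal(nrow(readTriples(f2, "ntriples")), 0L)

  # round trip through the writer
  f3 <- withr::local_tempfile(fileext = ".nt")
  writeNTriples(tr, f3)
  expect_identical(readTriples(f3, "ntriples"), tr)
})

test_that("malformed N-Triples lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".nt")
  writeLines(c('<urn:a> <urn:p> <urn:b> .', '<urn:a> <urn:p> broken'), f)
  expect_error(readTriples(f, "ntriples"), "line 2")
  expect_error(readTriples(f, "unknown-format"), "unknown RDF format")
  expect_error(readTriples(tempfile(), "ntriples"), "not found")
})

test_that("the Turtle subset parses directives, lists and literals", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c('@prefix ex: <http://ex.org/> .',
               '@base <http://base.org/> .',
               'ex:a a ex:T ;',
               '  ex:p ex:b , "lit"@en ;',
               '  ex:q 3.14 , true .',
               '<rel> ex:p _:bn .'), f)
  tr <- readTriples(f, "turtle")
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$predicate[1],
               "http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
  expect_equal(tr$subject[6], "http://base.org/rel")
  expect_equal(tr$object[3:5], c("lit", "3.14", "true"))
  expect_equal(tr$object_type[6], "blank")

  fe <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c('@prefix ex: <http://ex.org/> .', 'ex:a undeclared:p ex:b .'),
             fe)
  expect_error(readTriples(fe, "turtle"), "line 2")
})

test_that("conversion yields |V| = E + T, |E| = 2T and per-occurrence predicate vertices", {
  tr <- triples_of(c("a", "a", "b"), "p", c("b", "c", "d"))
  g <- convertToLabeledGraph(tr)
  expect_equal(numVertices(g), 4L + 3L)
  expect_equal(numEdges(g), 2L * 3L)
  expect_true(isConverted(g))

  # two triples sharing predicate IRI -> two distinct predicate vertices
  tr2 <- triples_of(c("a", "a"), "p", c("b", "c"))
  g2 <- convertToLabeledGraph(tr2)
  labs <- vertexLabels(g2)
  kinds <- igraph::V(asIgraph(g2))$kind
  expect_equal(sum(kinds == "predicate" & labs == "p"), 2L)

  # excluded predicate drops its triple entirely
  tr3 <- triples_of(c("a", "a"), c("p", "leak"), c("b", "c"))
  g3 <- convertToLabeledGraph(tr3, excludePredicates = "leak")
  expect_equal(numVertices(g3), 2L + 1L)
  expect_equal(numEdges(g3), 2L)
})

test_that("shared predicate vertices would forge walks; fresh ones do not", {
  # with (a,p,b) and (x,p,c): a must reach b at depth 2, never c
  tr <- triples_of(c("a", "x"), "p", c("b", "c"))
  g <- convertToLabeledGraph(tr)
  nb <- extractNeighborhood(g, "a", 2)
  expect_true(containsWalk(nb, walk("b", 2)))
  expect_false(containsWalk(nb, walk("c", 2)))
})

test_that("every kept triple is recoverable as a labeled length-2 path", {
  tr <- random_triples(seed = 11, n_triples = 15)
  g <- convertToLabeledGraph(tr)
  for (i in seq_len(nrow(tr))) {
    nb <- extractNeighborhood(g, tr$subject[i], 2)
    expect_true(containsWalk(nb, walk(tr$predicate[i], 1)))
    expect_true(containsWalk(nb, walk(tr$object[i], 2)))
  }
})

test_that("identical literals share a vertex and IRIs never collide with literals", {
  tr <- rbind(triples_of("a", "p", "0.016", o_type = "literal"),
              triples_of("b", "q", "0.016", o_type = "literal"),
              triples_of("c", "r", "0.016", o_type = "iri"))
  g <- convertToLabeledGraph(tr)
  # entities: a, b, c, one shared literal vertex, one IRI vertex "0.016"
  expect_equal(numVertices(g), 5L + 3L)
  nb <- extractNeighborhood(g, "a", 2)
  expect_true(containsWalk(nb, walk("0.016", 2)))
})

test_that("entity label tables resolve, reject unknowns and police duplicates", {
  tr <- triples_of(c("a", "b", "c", "d"), "p", c("b", "c", "d", "a"))
  g <- convertToLabeledGraph(tr)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(entity = c("a", "b", "c", "d"),
                       label = c("x", "y", "x", "y")), f)
  ds <- readEntityLabels(f, g)
  expect_s4_class(ds, "EntityDataset")
  expect_equal(length(ds), 4L)
  expect_equal(classNames(ds), c("x", "y"))

  write_tsv(data.frame(entity = c("a", "missing1"), label = c("x", "y")), f)
  expect_error(readEntityLabels(f, g), "missing1")

  write_tsv(data.frame(entity = c("a", "a"), label = c("x", "y")), f)
  expect_error(readEntityLabels(f, g), "conflicting")

  write_tsv(data.frame(entity = c("a", "a", "b"), label = c("x", "x", "y")),
            f)
  expect_warning(ds2 <- readEntityLabels(f, g), "collapsing")
  expect_equal(length(ds2), 2L)
})

test_that("predicate exclusion lists ignore blanks and comments", {
  f <- withr::local_tempfile()
  writeLines(c("# leaky", "", "urn:leak1", "  urn:leak2  "), f)
  expect_equal(readPredicateExclusions(f), c("urn:leak1", "urn:leak2"))
})
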
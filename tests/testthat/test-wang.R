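chain_dag <- function() {
  ontology_dag(c("A", "B", "C"),
               data.frame(child = c("A", "B"), parent = c("B", "C"),
                          relation = c("is_a", "is_a")),
               namespace = "BP")
}

test_that("S-values follow the max-product recursion", {
  root_only <- ontology_dag("R", data.frame(child = character(0),
                                            parent = character(0),
                                            relation = character(0)),
                            namespace = "BP")
  sv <- wang_svalues(root_only, "R")
  expect_equal(sv$svalues, c(R = 1))
  expect_equal(sv$sv, 1)

  dag <- chain_dag()
  sv <- wang_svalues(dag, "A")
  expect_equal(sv$svalues[["A"]], 1)
  expect_equal(sv$svalues[["B"]], 0.8)
  expect_equal(sv$svalues[["C"]], 0.8 * 0.8)
  expect_equal(sv$sv, 1 + 0.8 + 0.64)

  # diamond: two equal paths, max over paths
  diamond <- ontology_dag(c("A", "B", "C", "D"),
                          data.frame(child = c("A", "A", "B", "C"),
                                     parent = c("B", "C", "D", "D"),
                                     relation = "is_a"),
                          namespace = "BP")
  sv <- wang_svalues(diamond, "A")
  expect_equal(sv$svalues[["D"]], 0.64)
  expect_error(wang_svalues(diamond, "nope"), "unknown term")
})

test_that("term similarity matches hand evaluation and its invariants", {
  pair <- ontology_dag(c("A", "B"),
                       data.frame(child = "A", parent = "B",
                                  relation = "is_a"),
                       namespace = "BP")
  expect_equal(wang_term_similarity(pair, "A", "A"), 1)
  expect_equal(wang_term_similarity(pair, "A", "B"), (0.8 + 1) / (1.8 + 1),
               tolerance = 1e-12)
  dag <- chain_dag()
  expect_equal(wang_term_similarity(dag, "A", "B"),
               wang_term_similarity(dag, "B", "A"))
  # three-term chain, evaluated by hand from the S-value definition
  expect_equal(wang_term_similarity(dag, "A", "B"),
               (0.8 + 1 + 0.64 + 0.8) / (2.44 + 1.8), tolerance = 1e-12)
  disjoint <- ontology_dag(c("A", "B"),
                           data.frame(child = character(0),
                                      parent = character(0),
                                      relation = character(0)),
                           namespace = "BP")
  expect_equal(wang_term_similarity(disjoint, "A", "B"), 0)
})

test_that("part_of edges use their own weight", {
  dag <- ontology_dag(c("A", "B"),
                      data.frame(child = "A", parent = "B",
                                 relation = "part_of"),
                      namespace = "CC")
  sv <- wang_svalues(dag, "A")
  expect_equal(sv$svalues[["B"]], 0.6)
})

test_that("gene similarity is a best-match average over term pairs", {
  dag <- ontology_dag(c("A", "B"),
                      data.frame(child = "A", parent = "B",
                                 relation = "is_a"),
                      namespace = "BP")
  dag <- set_annotations(dag, list(g1 = "A", g2 = "B", g3 = c("A", "B"),
                                   g4 = character(0)))
  expect_equal(gene_semantic_similarity(dag, "g3", "g3"), 1)
  # single-pair best-match average equals the pair similarity itself
  expect_equal(gene_semantic_similarity(dag, "g1", "g2"), 1.8 / 2.8,
               tolerance = 1e-12)
  expect_true(is.na(gene_semantic_similarity(dag, "g1", "g4")))

  # two disjoint roots, both genes annotated to both: BMA of [[1,0],[0,1]] = 1
  two <- ontology_dag(c("X", "Y"),
                      data.frame(child = character(0), parent = character(0),
                                 relation = character(0)),
                      namespace = "BP",
                      annotations = list(ga = c("X", "Y"), gb = c("X", "Y")))
  expect_equal(gene_semantic_similarity(two, "ga", "gb"), 1)
})

test_that("the vectorised gene matrix equals pairwise BMA", {
  dag <- random_dag(15, seed = 42)
  set.seed(43)
  genes <- paste0("g", 1:8)
  ann <- setNames(lapply(genes, function(g) {
    sort(sample(dag$terms, sample(1:3, 1)))
  }), genes)
  dag <- set_annotations(dag, ann)
  m <- go_similarity_matrix(dag, genes = c(genes, "orphan"))
  for (i in 1:8) {
    for (j in 1:8) {
      expect_equal(m[genes[i], genes[j]],
                   gene_semantic_similarity(dag, genes[i], genes[j]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(is.na(m["orphan", ])))
  expect_true(all(diag(m[genes, genes]) == 1))
  expect_true(all(m[genes, genes] >= 0 & m[genes, genes] <= 1))
})

test_that("dynamic-programming S-values equal path enumeration on random DAGs", {
  for (s in 1:20) {
    dag <- random_dag(sample(5:25, 1), seed = s)
    term <- sample(dag$terms, 1)
    got <- wang_svalues(dag, term)
    want <- oracle_wang_svalues(dag, term)
    expect_equal(got$svalues[sort(names(got$svalues))],
                 want$svalues[sort(names(want$svalues))], tolerance = 1e-12)
    expect_equal(got$sv, want$sv, tolerance = 1e-12)
    expect_true(all(got$svalues > 0 & got$svalues <= 1))
  }
})
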
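test_that("worlds are deterministic under the spec seed", {
  sp <- small_spec(seed = 7)
  w1 <- simulate_world(sp)
  w2 <- simulate_world(sp)
  expect_identical(w1$expression$values, w2$expression$values)
  expect_identical(w1$associations, w2$associations)
  expect_identical(w1$graph$edges, w2$graph$edges)
  expect_identical(w1$ontologies$BP$annotations, w2$ontologies$BP$annotations)
})

test_that("positive label count follows the binomial law", {
  sp <- world_spec(n_targets = 100, n_diseases = 50, n_modules = 5,
                   n_tissues = 6, samples_per_tissue = 3,
                   label_rate = 0.3, seed = 11)
  w <- simulate_world(sp)
  n_true <- sum(w$truth$indication)
  expect_equal(n_true, 100 / 5 * 50 / 5 * 5)  # 1000 same-module pairs
  n_pos <- sum(w$associations$known_drug > 0)
  sd3 <- 3 * sqrt(n_true * 0.3 * 0.7)
  expect_gt(n_pos, 300 - sd3)
  expect_lt(n_pos, 300 + sd3)
  # positives only among true pairs, and kd in [0.3, 1]
  kd <- w$associations$known_drug
  truth <- w$truth$indication[cbind(w$associations$target_id,
                                    w$associations$disease_id)]
  expect_true(all(kd[truth == 0] == 0))
  expect_true(all(kd[kd > 0] >= 0.3 & kd[kd > 0] <= 1))
})

test_that("signal_strength 0 gives a null expression world", {
  sp <- small_spec(seed = 5, signal_strength = 0, view_noise = 0)
  w <- simulate_world(sp)
  mod_t <- w$truth$target_module
  tissue_of <- as.integer(sub("TIS", "", w$expression$meta$tissue))
  own <- log(w$expression$values)[cbind(
    seq_along(mod_t),
    vapply(mod_t, function(m) which(tissue_of == m)[1], integer(1))
  )]
  other <- log(w$expression$values)[cbind(
    seq_along(mod_t),
    vapply(mod_t, function(m) which(tissue_of != m)[1], integer(1))
  )]
  expect_lt(abs(mean(own) - mean(other)), 0.15)
})

test_that("infeasible specs are rejected", {
  expect_error(world_spec(n_targets = 10, n_diseases = 10, n_modules = 8,
                          n_tissues = 4), "n_modules")
  expect_error(world_spec(label_rate = 0), "label_rate")
  expect_error(world_spec(samples_per_tissue = 1), "samples per tissue")
})

test_that("world invariants hold: one module each, valid associations", {
  w <- simulate_world(small_spec(seed = 2))
  expect_equal(sort(names(w$truth$target_module)),
               sort(unique(w$associations$target_id)))
  expect_true(all(w$truth$target_module %in% 1:3))
  expect_true(all(w$truth$disease_module %in% 1:3))
  scores <- as.matrix(w$associations[, c("genetic_association",
                                         "somatic_mutation",
                                         "affected_pathway", "rna_expression",
                                         "animal_model", "known_drug")])
  expect_true(all(scores >= 0 & scores <= 1))
  expect_false(any(w$graph$edges$from == w$graph$edges$to))
})

test_that("written world artifacts read back through the io layer", {
  w <- simulate_world(small_spec(seed = 4))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  assoc <- read_associations(file.path(dir, "associations.tsv"))
  expect_equal(nrow(assoc), nrow(w$associations))
  expect_equal(assoc$known_drug, w$associations$known_drug)
  g <- read_string_edges(file.path(dir, "interactions.tsv"),
                         dialect = "thousand")
  expect_equal(nrow(g$edges), nrow(w$graph$edges))
  dag <- read_obo_subset(file.path(dir, "ontology_BP.obo"))
  expect_setequal(dag$terms, w$ontologies$BP$terms)
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "samples.tsv"))
  expect_equal(dim(expr$values), dim(w$expression$values))
  ann <- read_annotations(file.path(dir, "annotations_MF.tsv"))
  expect_equal(ann, w$ontologies$MF$annotations)
})

test_that("planted modules separate within- from between-module similarity", {
  # strong signal, clean views: within-module mean similarity must exceed
  # between-module mean for all three similarity families
  hits <- vapply(1:5, function(s) {
    w <- simulate_world(small_spec(seed = s, signal_strength = 8,
                                   evidence_noise = 0.05, view_noise = 0))
    sims <- suppressWarnings(build_similarities(w, node2vec = quick_n2v(s)))
    mod <- w$truth$target_module
    same <- outer(mod, mod, "==")
    diag(same) <- NA
    all(vapply(sims[c("tissue", "GO_BP", "ppi_embedding")], function(m) {
      m <- unclass(m)
      ids <- rownames(m)  # isolated nodes may be absent from the ppi source
      sm <- same[ids, ids]
      mean(m[sm & !is.na(sm)]) > mean(m[!sm & !is.na(sm)])
    }, logical(1)))
  }, logical(1))
  expect_true(all(hits))
})
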
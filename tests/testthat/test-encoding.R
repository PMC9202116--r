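two_neighbor_setup <- function(mask = character(0)) {
  sim <- matrix(c(1, 0.5, 0.5,
                  0.5, 1, 0,
                  0.5, 0, 1), 3, byrow = TRUE,
                dimnames = list(c("j", "n1", "n2"), c("j", "n1", "n2")))
  assoc <- make_assoc(c("j", "n1", "n2"), "d1", known_drug = c(0, 0.2, 0.6))
  list(sim = sim, kd = known_drug_matrix(assoc, mask = mask))
}

test_that("top-k neighbors sort by similarity with lexicographic ties", {
  sim <- matrix(0.1, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                           c("A", "B", "C", "D")))
  diag(sim) <- 1
  sim["A", c("B", "C", "D")] <- sim[c("B", "C", "D"), "A"] <- c(0.9, 0.9, 0.1)
  ns <- top_k_neighbors(sim, "A", k = 2)
  expect_equal(ns$neighbor_id, c("B", "C"))  # tie broken lexicographically
  all3 <- top_k_neighbors(sim, "A", k = 1000)
  expect_equal(nrow(all3), 3)  # k exceeding n-1 returns all others
  expect_false("A" %in% all3$neighbor_id)  # never its own neighbor
  expect_error(top_k_neighbors(sim, "Z", 1), "unknown target")
})

test_that("the worked encoding example gives 0.4 unmasked and 0.3 masked", {
  su <- two_neighbor_setup()
  ns <- top_k_neighbors(su$sim, "j", k = 2)
  expect_equal(encode_disease_associations(ns, su$kd, "d1"),
               (0.5 * 0.2 + 0.5 * 0.6) / 1.0)
  sm <- two_neighbor_setup(mask = "n1")
  expect_equal(encode_disease_associations(ns, sm$kd, "d1"),
               (0 + 0.5 * 0.6) / 1.0)
  # all-zero known drug scores encode to 0
  z <- known_drug_matrix(make_assoc(c("j", "n1", "n2"), "d1", known_drug = 0))
  expect_equal(encode_disease_associations(ns, z, "d1"), 0)
})

test_that("zero denominator yields 0 and neighbor order does not matter", {
  su <- two_neighbor_setup()
  ns <- top_k_neighbors(su$sim, "j", k = 2)
  flipped <- ns[2:1, ]
  expect_equal(encode_disease_associations(flipped, su$kd, "d1"),
               encode_disease_associations(ns, su$kd, "d1"))
  zero_w <- ns
  zero_w$similarity <- c(0, 0)
  expect_equal(encode_disease_associations(zero_w, su$kd, "d1"), 0)
})

test_that("equal similarities with no mask reduce to the plain mean", {
  set.seed(8)
  ids <- sprintf("T%02d", 1:12)
  sim <- matrix(0.7, 12, 12, dimnames = list(ids, ids))
  diag(sim) <- 1
  assoc <- make_assoc(rep(ids, 2), rep(c("d1", "d2"), each = 12),
                      known_drug = round(runif(24), 3))
  kd <- known_drug_matrix(assoc)
  enc <- encode_feature_matrix(sim, kd, k = 11)
  for (j in ids) {
    expect_equal(enc[j, "d2"], mean(kd[setdiff(ids, j), "d2"]),
                 tolerance = 1e-12)
  }
})

test_that("masking is idempotent with physically zeroed rows", {
  set.seed(21)
  ids <- sprintf("T%02d", 1:15)
  sim <- random_sim(15, seed = 22, ids = ids)
  assoc <- make_assoc(rep(ids, 3), rep(paste0("d", 1:3), each = 15),
                      known_drug = round(runif(45), 3))
  mask <- c("T03", "T07", "T11")
  enc_masked <- encode_feature_matrix(sim, known_drug_matrix(assoc, mask),
                                      k = 6)
  zeroed <- assoc
  zeroed$known_drug[zeroed$target_id %in% mask] <- 0
  class(zeroed) <- c("assoc_table", "data.frame")
  enc_zeroed <- encode_feature_matrix(sim, known_drug_matrix(zeroed), k = 6)
  expect_identical(enc_masked, enc_zeroed)
})

test_that("the fast encoder matches the naive double-loop oracle", {
  for (s in 1:5) {
    ids <- sprintf("T%02d", 1:30)
    sim <- random_sim(30, seed = s, ids = ids)
    set.seed(100 + s)
    assoc <- make_assoc(rep(ids, 4), rep(paste0("d", 1:4), each = 30),
                        known_drug = round(runif(120) * rbinom(120, 1, 0.4), 3))
    mask <- sample(ids, 5)
    kd <- known_drug_matrix(assoc, mask)
    got <- encode_feature_matrix(sim, kd, k = 7)
    want <- oracle_encode(sim, unclass(kd), k = 7, mask = mask)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("feature assembly fills, drops all-zero rows and labels by drug score", {
  assoc <- make_assoc(c("T1", "T1", "T2"), c("d1", "d2", "d1"),
                      known_drug = c(0.05, 0, 0),
                      genetic_association = c(0.4, 0, 0.1))
  enc <- matrix(c(0.3, 0, 0, 0.2), 2, dimnames = list(c("T1", "T2"),
                                                      c("d1", "d2")))
  suppressMessages(
    ft <- assemble_feature_table(assoc, list(tissue = enc))
  )
  # (T2, d2) comes in from the encoding alone: one value, other features 0
  row <- ft[ft$target_id == "T2" & ft$disease_id == "d2", ]
  expect_equal(row$enc_tissue, 0.2)
  expect_equal(sum(as.matrix(row[, attr(ft, "feature_cols")]) != 0), 1)
  # (T1, d2) has all-zero features and is dropped
  expect_equal(nrow(ft[ft$target_id == "T1" & ft$disease_id == "d2", ]), 0)
  # labels: known_drug 0.05 -> 1, 0 -> 0, absent pair -> 0
  expect_equal(ft$label[ft$target_id == "T1" & ft$disease_id == "d1"], 1L)
  expect_equal(ft$label[ft$target_id == "T2" & ft$disease_id == "d1"], 0L)
  expect_equal(ft$label[ft$target_id == "T2" & ft$disease_id == "d2"], 0L)
})
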
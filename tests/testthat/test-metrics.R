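test_that("pr_roc matches hand-evaluated cases", {
  r <- pr_roc(c(0.9, 0.1), c(1, 0))
  expect_equal(r$auroc, 1)
  expect_equal(r$aupr, 1)
  flipped <- pr_roc(c(0.1, 0.9), c(1, 0))
  expect_equal(flipped$auroc, 0)
  expect_equal(flipped$aupr, 0.5)  # AP with the positive ranked last
  expect_error(pr_roc(c(0.2, 0.4), c(1, 1)), "positive and one negative")
})

test_that("pr_roc and threshold curve match brute-force oracles", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- pr_roc(scores, labels)
    expect_equal(r$aupr, oracle_ap(scores, labels), tolerance = 1e-12)
    expect_equal(r$auroc, oracle_auroc(scores, labels), tolerance = 1e-12)
    oc <- oracle_curve(scores, labels)
    expect_equal(r$curve$threshold, oc$threshold)
    expect_equal(r$curve$recall, oc$tp / sum(labels), tolerance = 1e-12)
    expect_equal(r$curve$specificity, oc$tn / sum(labels == 0),
                 tolerance = 1e-12)
  }
})

test_that("best F-beta threshold scans all candidates with smallest-tie rule", {
  got <- best_threshold_fbeta(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0), beta = 1)
  expect_equal(got$threshold, 0.4)
  expect_equal(got$fbeta, 0.8)
  # large beta favours recall: the maximiser sits in the recall-1 region
  # (the scan keeps 0.4 over 0.3 because precision is higher at equal recall)
  rec <- best_threshold_fbeta(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0), beta = 10)
  expect_equal(rec$recall, 1)
  expect_lte(rec$threshold, 0.4)
  expect_equal(rec$threshold,
               oracle_best_fbeta(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0),
                                 10)$threshold)
  perfect <- best_threshold_fbeta(c(0.9, 0.8, 0.2), c(1, 1, 0), beta = 1.5)
  expect_equal(perfect$fbeta, 1)
  expect_error(best_threshold_fbeta(c(0.1, 0.2), c(0, 0), 1), "no positive")
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(5:40, 1)
    scores <- round(runif(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0) next
    beta <- sample(c(0.5, 1, 1.5, 2), 1)
    got <- best_threshold_fbeta(scores, labels, beta)
    want <- oracle_best_fbeta(scores, labels, beta)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$fbeta, want$fbeta, tolerance = 1e-12)
  }
})

test_that("agreement statistics match the confusion-matrix formulas", {
  perfect <- agreement_stats(c(0.9, 0.8, 0.1), c(1, 1, 0), threshold = 0.5)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$mcc, 1)
  # TP=2, TN=1, FP=1, FN=0
  st <- agreement_stats(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0), threshold = 0.5)
  expect_equal(st$counts, c(tp = 2, fp = 1, fn = 0, tn = 1))
  expect_equal(st$mcc, 2 / sqrt(12), tolerance = 1e-12)
  expect_equal(st$sensitivity, 1)
  expect_equal(st$precision, 2 / 3, tolerance = 1e-12)
  # empty-denominator conventions
  none_pred <- agreement_stats(c(0.1, 0.2), c(1, 0), threshold = 0.9)
  expect_equal(none_pred$precision, 0)
  expect_true("precision_undefined" %in% none_pred$flags)
  expect_equal(none_pred$mcc, 0)
})

test_that("random predictions give near-zero kappa", {
  set.seed(99)
  n <- 10000
  labels <- rbinom(n, 1, 0.5)
  scores <- runif(n)
  st <- agreement_stats(scores, labels, threshold = 0.5)
  expect_lt(abs(st$kappa), 0.05)
  expect_lt(abs(st$mcc), 0.05)
})

test_that("group-wise AUPR flags unevaluable groups and keeps all rows", {
  scores <- c(0.9, 0.8, 0.2, 0.6, 0.4, 0.3)
  labels <- c(1, 1, 0, 1, 0, 1)
  groups <- c("sep", "sep", "sep", "allpos", "mixed", "mixed")
  gm <- groupwise_metrics(scores, labels, groups)
  expect_equal(sum(gm$n), length(scores))
  expect_false(gm$evaluable[gm$group == "allpos"])
  expect_true(is.na(gm$aupr[gm$group == "allpos"]))
  expect_equal(gm$pos_fraction[gm$group == "allpos"], 1)
  expect_equal(gm$aupr[gm$group == "sep"], 1)  # separable group
})

test_that("indication ranking sorts, breaks ties by id and reports AUROC", {
  rk <- rank_indications(c(0.9, 0.2, 0.5), diseases = c("d1", "d2", "d3"),
                         labels = c(1, 0, 1))
  expect_equal(rk$disease_id, c("d1", "d3", "d2"))
  expect_equal(rk$rank, 1:3)
  expect_equal(attr(rk, "auroc"), pr_roc(c(0.9, 0.2, 0.5), c(1, 0, 1))$auroc)
  tie <- rank_indications(c(0.5, 0.5), diseases = c("zz", "aa"))
  expect_equal(tie$disease_id, c("aa", "zz"))
  expect_error(rank_indications(numeric(0), diseases = character(0)),
               "no scores")
})

test_that("hypergeometric overlap matches exact summation", {
  expect_equal(hypergeometric_overlap(5, 5, 5, 10)$p_value, 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(1, 2, 2, 4)$p_value, 5 / 6,
               tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(0, 0, 7, 20)$p_value, 1)
  expect_error(hypergeometric_overlap(6, 5, 5, 10), "overlap exceeds")
  expect_error(hypergeometric_overlap(1, 30, 5, 10), "universe")
  for (s in 1:25) {
    set.seed(200 + s)
    universe <- sample(10:60, 1)
    a <- sample(1:universe, 1)
    b <- sample(1:universe, 1)
    ov <- sample(0:min(a, b), 1)
    expect_equal(hypergeometric_overlap(ov, a, b, universe)$p_value,
                 oracle_hyper_tail(ov, a, b, universe), tolerance = 1e-12)
  }
})
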
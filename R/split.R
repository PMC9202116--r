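#' Remove diseases from excluded therapeutic areas
#'
#' Drops every row whose disease carries any of the excluded therapeutic-area
#' tags. The default exclusion list removes non-specific, non-disease
#' categories so the label task focuses on real disorders.
#'
#' @param assoc an [assoc_table()].
#' @param excluded character vector of area tags to exclude.
#' @return the filtered [assoc_table()].
#' @export
filter_therapeutic_areas <- function(assoc,
                                     excluded = c("measurement", "phenotype",
                                                  "biological process",
                                                  "cell proliferation disorder")) {
  if (length(excluded) == 0) return(assoc)
  areas <- strsplit(assoc$therapeutic_areas, ";", fixed = TRUE)
  drop <- vapply(areas, function(a) any(trimws(a) %in% excluded), logical(1))
  out <- assoc[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Split associations into working and prediction datasets
#'
#' Targets with at least one indication in clinical trials (some pair with
#' known-drug score greater than 0) form the working dataset used to train
#' and evaluate models; all remaining targets form the prediction dataset
#' scored for novel indications.
#'
#' @param assoc an [assoc_table()].
#' @return list with `working` and `prediction` association tables.
#' @export
split_working_prediction <- function(assoc) {
  kd <- assoc$known_drug
  kd[is.na(kd)] <- 0
  pos_targets <- unique(assoc$target_id[kd > 0])
  in_working <- assoc$target_id %in% pos_targets
  working <- assoc[in_working, , drop = FALSE]
  prediction <- assoc[!in_working, , drop = FALSE]
  rownames(working) <- rownames(prediction) <- NULL
  class(working) <- class(prediction) <- c("assoc_table", "data.frame")
  list(working = working, prediction = prediction)
}

#' Target-level train/test split
#'
#' Partitions targets (not pairs) uniformly at random into train and test
#' sets, so no target contributes rows to both sides and pair-level leakage
#' is impossible by construction. Train receives `floor(n * train_frac)`
#' targets; the remainder goes to test.
#'
#' @param targets character vector of target ids.
#' @param train_frac fraction of targets assigned to training (default 0.7).
#' @param seed RNG seed.
#' @return list of class `split_plan` with `train_targets`, `test_targets`,
#'   `folds` (`NULL` until [make_folds()]) and `seed`.
#' @export
target_level_split <- function(targets, train_frac = 0.7, seed = 1) {
  targets <- sort(unique(as.character(targets)))
  if (length(targets) < 2) stop("need at least 2 targets to split")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  set.seed(seed)
  n_train <- floor(length(targets) * train_frac)
  if (n_train < 1 || n_train >= length(targets)) {
    stop("train_frac leaves an empty train or test set")
  }
  train <- sort(sample(targets, n_train))
  structure(list(train_targets = train,
                 test_targets = setdiff(targets, train),
                 folds = NULL, seed = seed),
            class = "split_plan")
}

#' Grouped k-fold assignment of training targets
#'
#' Shuffles the training targets and deals them into `k` folds whose sizes
#' differ by at most one target. Folds group by target, so per-fold row
#' counts differ according to how many pairs each target carries, and a
#' target's pairs never straddle a train/validation boundary.
#'
#' @param plan a [target_level_split()] plan.
#' @param k number of folds (default 5).
#' @param seed RNG seed (defaults to the plan's seed).
#' @return the plan with `folds` set: a named list `fold1..foldk` of
#'   validation target sets partitioning `train_targets`.
#' @export
make_folds <- function(plan, k = 5, seed = plan$seed) {
  n <- length(plan$train_targets)
  if (k < 2) stop("need at least 2 folds")
  if (k > n) stop("more folds than training targets")
  set.seed(seed)
  shuffled <- sample(plan$train_targets)
  sizes <- rep(floor(n / k), k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  plan$folds <- setNames(
    lapply(seq_len(k), function(i) sort(shuffled[starts[i]:ends[i]])),
    paste0("fold", seq_len(k))
  )
  plan
}

#' Rows of a feature or association table belonging to a target set
#'
#' @param table data.frame with a `target_id` column.
#' @param targets character vector of target ids.
#' @return the subset, original class preserved.
#' @export
subset_targets <- function(table, targets) {
  out <- table[table$target_id %in% targets, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("feature_cols", "filled")) {
    attr(out, a) <- attr(table, a)
  }
  class(out) <- class(table)
  out
}
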
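#' Build the five target-target similarity matrices
#'
#' Tissue-specificity cosine similarity from the expression matrix, Wang
#' best-match-average similarity for each ontology namespace, and node2vec
#' embedding cosine similarity from the confidence-filtered interaction
#' graph.
#'
#' @param world a [simulate_world()] result, or a list with elements
#'   `expression`, `ontologies` (named BP/MF/CC) and `graph` built from real
#'   files.
#' @param node2vec named list of arguments passed to [node2vec_embed()]
#'   (e.g. `dim`, `walk_length`, `num_walks`, `window`, `seed`).
#' @return named list of five [similarity_matrix()] objects
#'   (`tissue`, `GO_BP`, `GO_MF`, `GO_CC`, `ppi_embedding`).
#' @export
build_similarities <- function(world, node2vec = list()) {
  sims <- list(tissue = tissue_similarity(world$expression))
  for (ns in c("BP", "MF", "CC")) {
    sims[[paste0("GO_", ns)]] <- go_similarity_matrix(world$ontologies[[ns]])
  }
  emb <- do.call(node2vec_embed, c(list(graph = world$graph), node2vec))
  sims$ppi_embedding <- embedding_similarity(emb)
  sims
}

#' Encode all similarity sources and assemble the feature table
#'
#' Builds the known-drug matrix from the association table (with the given
#' target mask applied inside every encoding computation), encodes each
#' similarity source through the collaborative-filtering equation and
#' assembles the 10-feature table. The mask must contain every target whose
#' rows will be used for validation or testing, so held-out drug status can
#' never leak into the encoded features.
#'
#' @param assoc an [assoc_table()].
#' @param sims named list of [similarity_matrix()] objects.
#' @param k neighborhood size (default 1000; worlds smaller than `k` fall
#'   back to all-but-self).
#' @param mask character vector of held-out target ids.
#' @return a `feature_table` (see [assemble_feature_table()]).
#' @export
build_feature_table <- function(assoc, sims, k = 1000, mask = character(0)) {
  kd <- known_drug_matrix(assoc, mask = mask)
  encodings <- lapply(sims, encode_feature_matrix, kd = kd, k = k)
  assemble_feature_table(assoc, encodings)
}

#' Verify that encoded features are leakage-free
#'
#' Recomputes the encoded features from scratch after physically zeroing the
#' masked targets' known-drug rows (with no mask), and checks that every
#' encoded value in the pipeline's training-time feature table is reproduced
#' exactly. A pipeline that failed to mask held-out drug status fails this
#' check whenever a held-out target carries a positive known-drug score.
#'
#' @param features the feature table the pipeline trained on.
#' @param sims the similarity matrices used to encode it.
#' @param assoc the association table used to encode it.
#' @param plan a [target_level_split()] plan; the mask defaults to its test
#'   targets.
#' @param k neighborhood size used at encoding time.
#' @param mask held-out target ids (default `plan$test_targets`; pass the
#'   union with the current validation fold during cross-validation).
#' @return `TRUE` when every encoded feature matches the leak-free
#'   recomputation exactly, `FALSE` otherwise.
#' @export
leak_free_check <- function(features, sims, assoc, plan = NULL, k = 1000,
                            mask = NULL) {
  if (is.null(mask)) {
    if (is.null(plan)) stop("supply a split plan or an explicit mask")
    mask <- plan$test_targets
  }
  zeroed <- assoc
  kd <- zeroed$known_drug
  kd[is.na(kd)] <- 0
  kd[zeroed$target_id %in% mask] <- 0
  zeroed$known_drug <- kd
  class(zeroed) <- c("assoc_table", "data.frame")
  kd0 <- known_drug_matrix(zeroed, mask = character(0))
  for (src in names(sims)) {
    col <- paste0("enc_", src)
    if (!col %in% names(features)) next
    ref <- encode_feature_matrix(sims[[src]], kd0, k = k)
    got <- features[[col]]
    expected <- numeric(nrow(features))
    in_ref <- features$target_id %in% rownames(ref) &
      features$disease_id %in% colnames(ref)
    expected[in_ref] <- ref[cbind(features$target_id[in_ref],
                                  features$disease_id[in_ref])]
    if (!identical(got, expected)) return(FALSE)
  }
  TRUE
}

#' End-to-end synthetic benchmark of the encoding method
#'
#' Runs the complete study on one synthetic world: simulate, build the five
#' similarity matrices, split targets 70/30, encode features with the test
#' targets masked, train XGBoost once on all 10 features and once on the 5
#' evidence features alone, and evaluate both on the held-out test rows.
#' Optionally appends a pure-noise feature and computes permutation
#' importance on the held-out set.
#'
#' @param seed seed for the world, the split and training.
#' @param spec a [world_spec()]; its seed is overridden by `seed`.
#' @param k encoder neighborhood size.
#' @param node2vec arguments for [node2vec_embed()]; the defaults here size
#'   the embedding for worlds of a few hundred targets.
#' @param importance compute permutation importance (with a planted noise
#'   column) on the held-out rows.
#' @param importance_repeats shuffles per feature.
#' @param nrounds XGBoost boosting rounds.
#' @return list with `aupr_full`, `aupr_evidence`, `auroc_full`, `plan`,
#'   `features`, `sims`, and (when requested) `importance`.
#' @export
run_indication_benchmark <- function(seed = 1,
                                     spec = world_spec(seed = seed),
                                     k = 50,
                                     node2vec = list(dim = 64,
                                                     walk_length = 40,
                                                     num_walks = 10,
                                                     window = 5,
                                                     seed = seed),
                                     importance = FALSE,
                                     importance_repeats = 5,
                                     nrounds = 100) {
  spec$seed <- seed
  world <- simulate_world(spec)
  working <- split_working_prediction(world$associations)$working
  plan <- target_level_split(unique(working$target_id), train_frac = 0.7,
                             seed = seed)
  sims <- build_similarities(world, node2vec = node2vec)
  features <- build_feature_table(working, sims, k = k,
                                  mask = plan$test_targets)
  train_rows <- subset_targets(features, plan$train_targets)
  test_rows <- subset_targets(features, plan$test_targets)
  feature_cols <- attr(features, "feature_cols")
  enc_cols <- grep("^enc_", feature_cols, value = TRUE)

  fit_eval <- function(cols) {
    xy_train <- feature_xy(train_rows, cols)
    model <- train(xy_train, model_spec("xgboost",
                                        hyperparameters = list(nrounds = nrounds),
                                        seed = seed))
    scores <- predict(model, feature_xy(test_rows, cols)$x)
    list(model = model, eval = pr_roc(scores, test_rows$label))
  }
  full <- fit_eval(feature_cols)
  evidence <- fit_eval(ot_evidence_cols)

  out <- list(seed = seed,
              aupr_full = full$eval$aupr,
              aupr_evidence = evidence$eval$aupr,
              auroc_full = full$eval$auroc,
              auroc_evidence = evidence$eval$auroc,
              n_train = nrow(train_rows), n_test = nrow(test_rows),
              plan = plan, features = features, sims = sims,
              model = full$model)
  if (importance) {
    set.seed(seed + 10007L)
    noise_col <- "noise"
    train_noise <- cbind(feature_xy(train_rows, feature_cols)$x,
                         noise = runif(nrow(train_rows)))
    test_noise <- cbind(feature_xy(test_rows, feature_cols)$x,
                        noise = runif(nrow(test_rows)))
    model_imp <- train(list(x = train_noise, y = train_rows$label),
                       model_spec("xgboost",
                                  hyperparameters = list(nrounds = nrounds),
                                  seed = seed))
    out$importance <- permutation_importance(model_imp, test_noise,
                                             labels = test_rows$label,
                                             repeats = importance_repeats,
                                             seed = seed)
    out$noise_feature <- noise_col
    out$encoded_features <- enc_cols
  }
  out
}
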
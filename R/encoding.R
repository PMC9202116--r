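#' Known-drug score matrix
#'
#' Builds the target x disease matrix of known-drug association scores from
#' an association table, with an optional mask of target ids whose rows must
#' read as 0 in every encoding computation (held-out targets). Missing scores
#' count as 0 here (no known drug recorded).
#'
#' @param assoc an [assoc_table()].
#' @param mask character vector of masked target ids.
#' @return numeric matrix with a `mask` attribute, class `known_drug_matrix`.
#' @export
known_drug_matrix <- function(assoc, mask = character(0)) {
  targets <- sort(unique(assoc$target_id))
  diseases <- sort(unique(assoc$disease_id))
  m <- matrix(0, length(targets), length(diseases),
              dimnames = list(targets, diseases))
  kd <- assoc$known_drug
  kd[is.na(kd)] <- 0
  m[cbind(assoc$target_id, assoc$disease_id)] <- kd
  structure(m, mask = as.character(mask),
            class = c("known_drug_matrix", class(m)))
}

#' Top-k most similar neighbors of a target
#'
#' Returns the `k` targets with highest similarity to `target` (all others,
#' if fewer than `k` exist), sorted by similarity descending with ties broken
#' lexicographically by neighbor id. The target itself is never a neighbor,
#' so its own known-drug row cannot leak into its encoded feature.
#'
#' @param sim a [similarity_matrix()].
#' @param target target id.
#' @param k neighborhood size (default 1000, the published choice).
#' @return data.frame with columns `neighbor_id`, `similarity` and attribute
#'   `target`, class `neighbor_set`.
#' @export
top_k_neighbors <- function(sim, target, k = 1000) {
  if (!target %in% rownames(sim)) stop("unknown target: ", target)
  if (k < 1) stop("k must be >= 1")
  s <- sim[target, ]
  s <- s[names(s) != target]
  ord <- order(-s, names(s))
  take <- ord[seq_len(min(k, length(ord)))]
  structure(data.frame(neighbor_id = names(s)[take],
                       similarity = unname(s[take])),
            target = target, class = c("neighbor_set", "data.frame"))
}

#' Collaborative-filtering disease-association encoding
#'
#' The encoded score of target `j` for one disease is the similarity-weighted
#' average of its neighbors' known-drug scores:
#' `sum_i sim(j,i) * kd(i, disease) / sum_i |sim(j,i)|`. A masked neighbor
#' contributes `kd = 0` to the numerator but its `|sim|` still counts in the
#' denominator (the mask hides drug status, not similarity). A zero
#' denominator yields 0.
#'
#' @param neighbors a [top_k_neighbors()] set.
#' @param kd a [known_drug_matrix()]; every neighbor must be one of its rows.
#' @param disease disease id (column of `kd`).
#' @return encoded score (signed if similarities can be negative).
#' @export
encode_disease_associations <- function(neighbors, kd, disease) {
  ids <- neighbors$neighbor_id
  missing_n <- setdiff(ids, rownames(kd))
  if (length(missing_n) > 0) {
    stop("neighbor ", missing_n[1], " absent from the known-drug matrix")
  }
  if (!disease %in% colnames(kd)) stop("unknown disease: ", disease)
  w <- neighbors$similarity
  v <- kd[ids, disease]
  v[ids %in% attr(kd, "mask")] <- 0
  den <- sum(abs(w))
  if (den == 0) return(0)
  sum(w * v) / den
}

#' Encode one similarity source into a target x disease feature matrix
#'
#' Applies [encode_disease_associations()] for every target of the known-drug
#' matrix that also appears in the similarity matrix, over all diseases at
#' once. Neighbors are drawn from the targets shared by both matrices.
#'
#' @param sim a [similarity_matrix()]; `NA` entries are treated as similarity
#'   0 (missing source coverage).
#' @param kd a [known_drug_matrix()] (carries the mask).
#' @param k neighborhood size.
#' @return numeric matrix (shared targets x diseases) of encoded scores.
#' @export
encode_feature_matrix <- function(sim, kd, k = 1000) {
  sim <- unclass(sim)
  sim[is.na(sim)] <- 0
  targets <- intersect(rownames(kd), rownames(sim))
  if (length(targets) < 2) stop("need at least 2 targets shared by sim and kd")
  kd0 <- unclass(kd)[targets, , drop = FALSE]
  kd0[rownames(kd0) %in% attr(kd, "mask"), ] <- 0
  out <- matrix(0, length(targets), ncol(kd),
                dimnames = list(targets, colnames(kd)))
  sub <- sim[targets, targets, drop = FALSE]
  for (j in seq_along(targets)) {
    s <- sub[j, -j]
    ord <- order(-s, names(s))
    take <- ord[seq_len(min(k, length(ord)))]
    w <- s[take]
    den <- sum(abs(w))
    if (den == 0) next
    out[j, ] <- as.numeric(w %*% kd0[names(s)[take], , drop = FALSE]) / den
  }
  out
}

#' Assemble the 10-feature table
#'
#' Joins the five evidence scores from the association table with the five
#' encoded scores (one per similarity source) over the outer union of
#' (target, disease) pairs observed in any source. Missing entries are filled
#' with 0; rows whose 10 features are all 0 are dropped (their count is
#' reported in a message). The binary label is 1 when the pair's known-drug
#' score is greater than 0.
#'
#' @param assoc an [assoc_table()] (missing evidence read as 0).
#' @param encodings named list of encoded target x disease matrices; names
#'   must be among `tissue`, `GO_BP`, `GO_MF`, `GO_CC`, `ppi_embedding`.
#' @return data.frame of class `feature_table` with columns `target_id`,
#'   `disease_id`, the 5 evidence features, the encoded features
#'   (`enc_<source>`) and `label`; attribute `feature_cols` lists the feature
#'   column names.
#' @export
assemble_feature_table <- function(assoc, encodings) {
  if (is.null(names(encodings)) ||
      !all(names(encodings) %in% ot_similarity_sources)) {
    stop("encodings must be named by similarity source")
  }
  pair_key <- function(t, d) paste(t, d, sep = "\r")
  keys <- pair_key(assoc$target_id, assoc$disease_id)
  if (anyDuplicated(keys)) stop("duplicate pair in association table")
  enc_pairs <- lapply(encodings, function(m) {
    nz <- which(m != 0, arr.ind = TRUE)
    pair_key(rownames(m)[nz[, 1]], colnames(m)[nz[, 2]])
  })
  all_keys <- sort(unique(c(keys, unlist(enc_pairs, use.names = FALSE))))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(target_id = vapply(parts, `[`, "", 1),
                    disease_id = vapply(parts, `[`, "", 2))
  idx <- match(all_keys, keys)
  for (col in ot_evidence_cols) {
    v <- assoc[[col]][idx]
    v[is.na(v)] <- 0
    out[[col]] <- v
  }
  enc_cols <- character(0)
  for (src in names(encodings)) {
    m <- encodings[[src]]
    col <- paste0("enc_", src)
    enc_cols <- c(enc_cols, col)
    v <- numeric(nrow(out))
    in_m <- out$target_id %in% rownames(m) & out$disease_id %in% colnames(m)
    v[in_m] <- m[cbind(out$target_id[in_m], out$disease_id[in_m])]
    out[[col]] <- v
  }
  feature_cols <- c(ot_evidence_cols, enc_cols)
  kd <- assoc$known_drug[idx]
  kd[is.na(kd)] <- 0
  out$label <- as.integer(kd > 0)
  all_zero <- rowSums(abs(as.matrix(out[, feature_cols])) > 0) == 0
  if (any(all_zero)) {
    message("dropping ", sum(all_zero), " all-zero feature row(s)")
    out <- out[!all_zero, , drop = FALSE]
  }
  out <- out[order(out$target_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, feature_cols = feature_cols,
            class = c("feature_table", "data.frame"))
}

# Numeric feature matrix + label vector from a feature table.
feature_xy <- function(features, feature_cols = attr(features, "feature_cols")) {
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = features$label)
}
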
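#' Construct a target-target similarity matrix
#'
#' A symmetric matrix of target relatedness tagged with the data source it
#' was derived from. Values lie in `[-1,1]` (`[0,1]` for ontology sources);
#' the diagonal is 1 except for targets with degenerate (zero-norm) profiles,
#' which are flagged in the `zero_norm` attribute and carry similarity 0 to
#' everything, including themselves.
#'
#' @param values symmetric numeric matrix with target ids as dimnames.
#' @param source_tag one of `tissue`, `GO_BP`, `GO_MF`, `GO_CC`,
#'   `ppi_embedding`.
#' @param zero_norm character vector of degenerate target ids.
#' @param validate_diag check the diagonal-is-one invariant (skipped when
#'   reconstructing from triplets, where degeneracy flags are not stored).
#' @return the matrix with class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, source_tag, zero_norm = character(0),
                              validate_diag = TRUE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || !identical(rownames(values), colnames(values))) {
    stop("similarity matrix needs matching row/column target ids")
  }
  if (!source_tag %in% ot_similarity_sources) {
    stop("unknown source_tag: ", source_tag)
  }
  if (max(abs(values - t(values))) > 1e-12) {
    stop("similarity matrix is not symmetric")
  }
  if (any(values < -1 - 1e-9 | values > 1 + 1e-9)) {
    stop("similarity values out of [-1,1]")
  }
  if (validate_diag) {
    ok <- rownames(values) %in% zero_norm
    if (any(abs(diag(values)[!ok] - 1) > 1e-9)) {
      stop("diagonal must be 1 for non-degenerate targets")
    }
  }
  structure(values, source_tag = source_tag, zero_norm = zero_norm,
            class = c("similarity_matrix", class(values)))
}

#' Cosine similarity between profile rows
#'
#' Computes `dot(u, v) / (|u| |v|)` for every pair of rows. Rows with zero
#' norm have no direction: they get similarity 0 to all rows and a 0
#' diagonal, and are flagged in the result's `zero_norm` attribute so
#' downstream top-k selection stays total.
#'
#' @param profiles numeric matrix, one profile per row, rownames = target ids.
#' @param source_tag source tag for the resulting [similarity_matrix()].
#' @return a [similarity_matrix()].
#' @export
cosine_similarity <- function(profiles, source_tag = "tissue") {
  stopifnot(is.matrix(profiles), is.numeric(profiles))
  if (!all(is.finite(profiles))) stop("non-finite values in profiles")
  if (ncol(profiles) < 1) stop("profiles need at least one column")
  norms <- sqrt(rowSums(profiles^2))
  zero <- norms == 0
  safe <- ifelse(zero, 1, norms)
  unit <- profiles / safe
  sim <- tcrossprod(unit)
  sim[zero, ] <- 0
  sim[, zero] <- 0
  sim <- pmin(pmax(sim, -1), 1)
  diag(sim)[!zero] <- 1
  sim <- (sim + t(sim)) / 2  # exact symmetry against FP noise
  similarity_matrix(sim, source_tag = source_tag,
                    zero_norm = rownames(profiles)[zero])
}
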
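#' Tissue-specificity statistics from expression profiles
#'
#' For each retained gene and each tissue, fits an ordinary least-squares
#' linear model on `log2(x + 1)`-scaled expression of the samples in that
#' tissue versus the samples of all other tissue *groups* (samples from
#' different tissues in the same group are excluded from the contrast), with
#' age and sex as covariates, and reports the t-statistic of the
#' tissue-membership indicator. Genes failing the expression filter (no
#' tissue with a non-zero count) are dropped; a gene with zero residual
#' variance in some contrast gets statistic 0 with a warning.
#'
#' Samples are put in a canonical order (by sample id) before fitting, so the
#' result is invariant to the input sample order.
#'
#' @param expr an [expression_matrix()].
#' @param min_expressed filter rule; currently `"nonzero_in_one_tissue"`:
#'   keep genes whose summed count is non-zero in at least one tissue.
#' @return genes x tissues numeric matrix of t-statistics, with attribute
#'   `dropped_genes` (ids removed by the expression filter).
#' @export
compute_tissue_specificity <- function(expr,
                                       min_expressed = "nonzero_in_one_tissue") {
  min_expressed <- match.arg(min_expressed)
  ord <- order(expr$meta$sample_id)
  meta <- expr$meta[ord, , drop = FALSE]
  values <- expr$values[, ord, drop = FALSE]

  tissues <- sort(unique(meta$tissue))
  if (length(unique(meta$tissue_group)) < 2) {
    stop("need samples from at least two tissue groups")
  }
  counts <- table(meta$tissue)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    stop("tissue '", small[1], "' has fewer than 2 samples")
  }
  group_of <- vapply(tissues, function(t) {
    g <- unique(meta$tissue_group[meta$tissue == t])
    if (length(g) > 1) stop("tissue '", t, "' maps to multiple tissue groups")
    g
  }, character(1))

  tissue_sums <- t(rowsum(t(values), meta$tissue))
  keep <- rowSums(tissue_sums > 0) >= 1
  dropped <- rownames(values)[!keep]
  values <- values[keep, , drop = FALSE]
  if (nrow(values) == 0) stop("no genes pass the expression filter")

  y_all <- t(log2(values + 1))  # samples x genes
  sex_num <- as.numeric(factor(meta$sex))
  stat <- matrix(NA_real_, nrow(values), length(tissues),
                 dimnames = list(rownames(values), tissues))
  degenerate <- FALSE

  for (ti in seq_along(tissues)) {
    t_name <- tissues[ti]
    in_tissue <- meta$tissue == t_name
    use <- in_tissue | (meta$tissue_group != group_of[ti])
    ind <- as.numeric(in_tissue[use])
    covars <- cbind(age = meta$age[use], sex = sex_num[use])
    covars <- covars[, apply(covars, 2, function(v) length(unique(v)) > 1),
                     drop = FALSE]
    x <- cbind(intercept = 1, tissue = ind, covars)
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(x)
    }
    coef_idx <- match("tissue", colnames(x))
    y <- y_all[use, , drop = FALSE]
    beta <- qr.coef(qx, y)
    res <- y - x %*% beta
    df <- nrow(x) - qx$rank
    if (df <= 0) stop("not enough samples to fit covariate model for tissue ",
                      t_name)
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(qr.R(qx))
    se <- sqrt(sigma2 * xtx_inv[coef_idx, coef_idx])
    tval <- beta[coef_idx, ] / se
    # a response with no variance across the contrast has no information:
    # its near-zero residuals are floating-point noise, not evidence
    centered <- y - matrix(colMeans(y), nrow(y), ncol(y), byrow = TRUE)
    zero_var <- colSums(centered^2) == 0
    bad <- zero_var | !is.finite(tval)
    if (any(bad)) {
      degenerate <- TRUE
      tval[bad] <- 0
    }
    stat[, ti] <- tval
  }
  if (degenerate) {
    warning("zero-variance gene-contrast(s) set to statistic 0")
  }
  attr(stat, "dropped_genes") <- dropped
  stat
}

#' Tissue-specificity similarity matrix
#'
#' Convenience wrapper: [compute_tissue_specificity()] followed by
#' [cosine_similarity()] over the gene rows of the specificity matrix.
#'
#' @param expr an [expression_matrix()].
#' @return a [similarity_matrix()] tagged `tissue`.
#' @export
tissue_similarity <- function(expr) {
  spec <- compute_tissue_specificity(expr)
  cosine_similarity(unclass(spec), source_tag = "tissue")
}
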
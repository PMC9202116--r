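#' Construct an expression matrix with sample metadata
#'
#' @param values numeric genes x samples matrix of non-negative counts or
#'   TPM, with gene ids as rownames and sample ids as colnames.
#' @param meta data.frame with columns `sample_id`, `tissue`, `tissue_group`,
#'   `age` (years), `sex`; one row per sample of `values`.
#' @return list of class `expr_matrix` with elements `values` and `meta`.
#' @export
expression_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id: ", rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample id: ", colnames(values)[duplicated(colnames(values))][1])
  }
  if (any(values < 0)) stop("negative expression values")
  required <- c("sample_id", "tissue", "tissue_group", "age", "sex")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("sample metadata missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  unmatched <- setdiff(colnames(values), meta$sample_id)
  if (length(unmatched) > 0) {
    stop("sample ", unmatched[1], " has no metadata row")
  }
  extra <- setdiff(meta$sample_id, colnames(values))
  if (length(extra) > 0) {
    stop("metadata sample ", extra[1], " absent from the matrix")
  }
  if (any(is.na(meta$tissue) | meta$tissue == "")) {
    stop("every sample needs a tissue")
  }
  if (any(is.na(meta$tissue_group) | meta$tissue_group == "")) {
    stop("every sample needs a tissue_group")
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expr_matrix")
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix TSV has a `gene_id` first column and one column per sample;
#' the metadata TSV is keyed by `sample_id` and carries `tissue`,
#' `tissue_group`, `age` and `sex`. Sample sets must reconcile exactly.
#'
#' @param path_matrix expression TSV.
#' @param path_meta metadata TSV.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path_matrix, path_meta) {
  raw <- read.delim(path_matrix, check.names = FALSE)
  if (names(raw)[1] != "gene_id") stop("first matrix column must be gene_id")
  genes <- as.character(raw$gene_id)
  if (anyDuplicated(genes)) {
    stop("duplicate gene id: ", genes[duplicated(genes)][1])
  }
  values <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  meta <- read.delim(path_meta, colClasses = "character", check.names = FALSE)
  if (!"age" %in% names(meta)) stop("metadata missing age column")
  meta$age <- as.numeric(meta$age)
  expression_matrix(values, meta)
}

#' Write an expression matrix and metadata to TSV
#'
#' @param expr an [expression_matrix()].
#' @param path_matrix output path for the matrix TSV.
#' @param path_meta output path for the metadata TSV.
#' @return `path_matrix`, invisibly.
#' @export
write_expression <- function(expr, path_matrix, path_meta) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path_matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$meta, path_meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path_matrix)
}

#' Write a similarity matrix as an upper-triangle triplet TSV
#'
#' Stores rows `(target_a, target_b, value)` for `a <= b` (the matrix is
#' symmetric); the source tag is kept in a header comment.
#'
#' @param sim a [similarity_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  ids <- rownames(sim)
  ut <- which(upper.tri(sim, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(target_a = ids[ut[, 1]], target_b = ids[ut[, 2]],
                   value = sim[ut])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# source_tag: ", attr(sim, "source_tag")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity triplet TSV
#'
#' @param path file written by [write_similarity()].
#' @return a [similarity_matrix()].
#' @export
read_similarity <- function(path) {
  first <- readLines(path, n = 1)
  tag <- if (startsWith(first, "# source_tag:")) {
    trimws(sub("# source_tag:", "", first))
  } else "tissue"
  df <- read.delim(path, comment.char = "#",
                   colClasses = c("character", "character", "numeric"))
  ids <- sort(unique(c(df$target_a, df$target_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(df$target_a, df$target_b)] <- df$value
  m[cbind(df$target_b, df$target_a)] <- df$value
  similarity_matrix(m, source_tag = tag, validate_diag = FALSE)
}
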
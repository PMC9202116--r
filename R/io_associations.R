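#' Construct an association table
#'
#' An association table holds one row per (target, disease) pair with the
#' five evidence scores, the known-drug score, a direct-association flag and
#' the disease's therapeutic-area tags (semicolon-delimited string). Scores
#' live in `[0,1]`; a missing score (`NA`) is distinguishable from an explicit
#' zero until [fill_missing_scores()] is applied.
#'
#' @param df data.frame with columns `target_id`, `disease_id`, the six score
#'   columns, `is_direct` (logical) and `therapeutic_areas` (character).
#' @return data.frame of class `assoc_table`.
#' @export
assoc_table <- function(df) {
  required <- c("target_id", "disease_id", ot_score_cols, "is_direct",
                "therapeutic_areas")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("association table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$target_id <- as.character(df$target_id)
  df$disease_id <- as.character(df$disease_id)
  df$therapeutic_areas <- as.character(df$therapeutic_areas)
  df$is_direct <- as.logical(df$is_direct)
  for (col in ot_score_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) stop("score column '", col, "' is not numeric")
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0) {
      stop("score '", col, "' out of [0,1] in row ", bad[1])
    }
  }
  key <- paste(df$target_id, df$disease_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (target, disease) pair: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }
  # therapeutic areas are a per-disease attribute; rows of one disease must agree
  areas <- split(df$therapeutic_areas, df$disease_id)
  inconsistent <- names(areas)[vapply(areas, function(a) length(unique(a)) > 1,
                                      logical(1))]
  if (length(inconsistent) > 0) {
    stop("inconsistent therapeutic_areas across rows of disease ",
         inconsistent[1])
  }
  rownames(df) <- NULL
  class(df) <- c("assoc_table", "data.frame")
  df
}

#' Read an Open-Targets-style association table
#'
#' Reads a TSV with header columns `target_id`, `disease_id`, the five
#' evidence scores (`genetic_association`, `somatic_mutation`,
#' `affected_pathway`, `rna_expression`, `animal_model`), `known_drug`,
#' `is_direct` and `therapeutic_areas` (semicolon-delimited). Rows whose
#' `is_direct` flag is false are dropped: indirect associations duplicate
#' information propagated through the disease ontology. An empty cell or the
#' token `NA` in a score column means missing, which is distinct from an
#' explicit 0.
#'
#' @param path TSV file path.
#' @param fill_missing if `TRUE`, missing scores are filled with 0 (missing
#'   evidence is read as "no evidence found") and the filled cells are
#'   recorded in the `filled` attribute.
#' @return An [assoc_table()] of the direct associations.
#' @export
read_associations <- function(path, fill_missing = FALSE) {
  raw <- read.delim(path, colClasses = "character", na.strings = c("NA", ""),
                    check.names = FALSE)
  required <- c("target_id", "disease_id", ot_score_cols, "is_direct",
                "therapeutic_areas")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in ot_score_cols) {
    v <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0) {
      stop("malformed score '", col, "' at line ", bad[1] + 1L,
           " of ", path, ": '", v[bad[1]], "'")
    }
    out_of_range <- which(!is.na(parsed) & (parsed < 0 | parsed > 1))
    if (length(out_of_range) > 0) {
      stop("score '", col, "' out of [0,1] at line ", out_of_range[1] + 1L,
           " of ", path, ": ", v[out_of_range[1]])
    }
    raw[[col]] <- parsed
  }
  raw$is_direct <- toupper(raw$is_direct) %in% c("TRUE", "T", "1")
  raw$therapeutic_areas[is.na(raw$therapeutic_areas)] <- ""
  tab <- assoc_table(raw)
  tab <- tab[tab$is_direct, , drop = FALSE]
  rownames(tab) <- NULL
  if (fill_missing) tab <- fill_missing_scores(tab) else {
    attr(tab, "filled") <- data.frame(target_id = character(0),
                                      disease_id = character(0),
                                      column = character(0))
  }
  class(tab) <- c("assoc_table", "data.frame")
  tab
}

#' Fill missing association scores with zero
#'
#' Missingness in evidence channels is interpreted as "no evidence found",
#' so absent scores become 0. The filled cells are recorded in the `filled`
#' attribute so the fill remains a distinguishable, logged step.
#'
#' @param assoc an [assoc_table()].
#' @return the table with `NA` scores replaced by 0.
#' @export
fill_missing_scores <- function(assoc) {
  filled <- list()
  for (col in ot_score_cols) {
    idx <- which(is.na(assoc[[col]]))
    if (length(idx) > 0) {
      filled[[col]] <- data.frame(target_id = assoc$target_id[idx],
                                  disease_id = assoc$disease_id[idx],
                                  column = col)
      assoc[[col]][idx] <- 0
    }
  }
  filled <- if (length(filled) > 0) do.call(rbind, filled) else
    data.frame(target_id = character(0), disease_id = character(0),
               column = character(0))
  rownames(filled) <- NULL
  attr(assoc, "filled") <- filled
  assoc
}

#' Write an association table to TSV
#'
#' Inverse of [read_associations()]; missing scores are written as empty
#' cells so a read/write round trip preserves missingness.
#'
#' @param assoc an [assoc_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a literature disease-hit list
#'
#' A TSV with a `disease_id` column and optionally a `gene_id` column
#' (gene-disease text-mining hits). Ids are deduplicated; empty ids are an
#' error.
#'
#' @param path TSV file path.
#' @return list with `disease_ids` (character) and `hits` (data.frame or
#'   `NULL`), class `literature_hits`.
#' @export
read_literature_hits <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!"disease_id" %in% names(raw)) stop("hit list needs a disease_id column")
  ids <- raw$disease_id
  if (any(is.na(ids) | ids == "")) stop("empty disease_id in hit list")
  hits <- NULL
  if ("gene_id" %in% names(raw)) {
    if (any(is.na(raw$gene_id) | raw$gene_id == "")) {
      stop("empty gene_id in hit list")
    }
    hits <- unique(raw[, c("gene_id", "disease_id")])
    rownames(hits) <- NULL
  }
  structure(list(disease_ids = sort(unique(ids)), hits = hits),
            class = "literature_hits")
}
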
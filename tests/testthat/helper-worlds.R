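# Small fixtures generated in code.

small_spec <- function(seed = 1, ...) {
  args <- modifyList(list(n_targets = 60, n_diseases = 12, n_modules = 3,
                          n_tissues = 6, samples_per_tissue = 4, seed = seed),
                     list(...))
  do.call(world_spec, args)
}

quick_n2v <- function(seed = 1) {
  list(dim = 16, walk_length = 20, num_walks = 5, window = 4, seed = seed)
}

# Inline association table builder; scores default to 0.
make_assoc <- function(target_id, disease_id, known_drug = 0, is_direct = TRUE,
                       therapeutic_areas = "", ...) {
  df <- data.frame(target_id = target_id, disease_id = disease_id,
                   stringsAsFactors = FALSE)
  scores <- list(...)
  for (col in c("genetic_association", "somatic_mutation", "affected_pathway",
                "rna_expression", "animal_model")) {
    df[[col]] <- if (!is.null(scores[[col]])) scores[[col]] else 0
  }
  df$known_drug <- known_drug
  df$is_direct <- is_direct
  df$therapeutic_areas <- therapeutic_areas
  assoc_table(df)
}

# Random similarity matrix (symmetric, diag 1) over padded target ids.
random_sim <- function(n, seed, ids = sprintf("T%03d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

assoc_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- paste("target_id", "disease_id", "genetic_association",
                  "somatic_mutation", "affected_pathway", "rna_expression",
                  "animal_model", "known_drug", "is_direct",
                  "therapeutic_areas", sep = "\t")
  writeLines(c(header, lines), path)
  path
}

arow <- function(target, disease, scores = rep("0", 6), direct = "TRUE",
                 areas = "") {
  paste(c(target, disease, scores, direct, areas), collapse = "\t")
}
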
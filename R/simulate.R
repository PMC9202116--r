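#' Specification of a synthetic target-disease world
#'
#' The generator plants the statistical structure the encoding method
#' assumes: targets and diseases belong to functional modules, targets of a
#' module are co-expressed in that module's tissue, annotated in the same
#' ontology subtree, densely interconnected in the interaction network, and
#' truly indicated for the diseases of their module. Only a fraction of true
#' indications carry a positive known-drug score, which makes the labels
#' positive-unlabeled.
#'
#' @param n_targets,n_diseases,n_modules counts; modules must not exceed
#'   `min(n_targets, n_diseases, n_tissues)`.
#' @param n_tissues,samples_per_tissue expression design; module `m` is
#'   over-expressed in tissue `m`, tissues are paired into tissue groups.
#' @param signal_strength expression fold-change of module genes in their
#'   tissue is `1 + signal_strength` (0 gives the null world).
#' @param label_rate fraction of true indications receiving a positive
#'   known-drug score.
#' @param evidence_noise standard deviation of the Gaussian noise added to
#'   the evidence scores (truncated to `[0,1]`).
#' @param evidence_scale mean evidence score of a true indication before
#'   noise; keeps the evidence channels weakly informative.
#' @param view_noise fraction of targets whose expression and ontology views
#'   misassign the functional module (independently per view and per
#'   namespace). Real similarity sources are imperfect, partially
#'   complementary views of function — expression specificity is a weak
#'   proxy and annotations are incomplete — while the confidence-filtered
#'   interaction network is the cleanest view, so the network view is left
#'   uncorrupted.
#' @param p_within,p_between planted-partition edge probabilities of the
#'   interaction network.
#' @param seed RNG seed; the whole world is deterministic given the spec.
#' @return list of class `world_spec`.
#' @export
world_spec <- function(n_targets = 300, n_diseases = 60, n_modules = 6,
                       n_tissues = 12, samples_per_tissue = 6,
                       signal_strength = 4, label_rate = 0.3,
                       evidence_noise = 0.25, evidence_scale = 0.1,
                       view_noise = 0.25,
                       p_within = 0.3, p_between = 0.02, seed = 1) {
  counts <- c(n_targets = n_targets, n_diseases = n_diseases,
              n_modules = n_modules, n_tissues = n_tissues,
              samples_per_tissue = samples_per_tissue)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("counts must be positive integers")
  }
  if (n_modules > min(n_targets, n_diseases, n_tissues)) {
    stop("n_modules must not exceed min(n_targets, n_diseases, n_tissues)")
  }
  if (samples_per_tissue < 2) stop("need at least 2 samples per tissue")
  if (label_rate <= 0 || label_rate >= 1) stop("label_rate must be in (0,1)")
  if (signal_strength < 0) stop("signal_strength must be non-negative")
  if (evidence_noise < 0) stop("evidence_noise must be non-negative")
  if (view_noise < 0 || view_noise >= 1) stop("view_noise must be in [0,1)")
  structure(list(n_targets = n_targets, n_diseases = n_diseases,
                 n_modules = n_modules, n_tissues = n_tissues,
                 samples_per_tissue = samples_per_tissue,
                 signal_strength = signal_strength, label_rate = label_rate,
                 evidence_noise = evidence_noise,
                 evidence_scale = evidence_scale, view_noise = view_noise,
                 p_within = p_within, p_between = p_between, seed = seed),
            class = "world_spec")
}

pad_id <- function(prefix, i, n) {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), i)
}

#' Simulate a complete synthetic world
#'
#' Generates, deterministically under the spec's seed: an expression matrix
#' with age/sex covariate effects and module genes over-expressed in their
#' module's tissue; three single-namespace ontologies (BP/MF/CC) with
#' per-module term subtrees and within-subtree gene annotations; a
#' planted-partition interaction graph (within-module confidence
#' `U(0.5, 1)`, between `U(0.2, 0.8)`); an association table over the full
#' target x disease grid where true indications are same-module pairs, a
#' `label_rate` fraction of them carries `known_drug ~ U(0.3, 1)`, and the
#' five evidence scores are a scaled true-indication indicator plus truncated
#' Gaussian noise; and the ground truth (module maps and the binary
#' indication matrix).
#'
#' @param spec a [world_spec()].
#' @return list of class `synthetic_world` with elements `expression`,
#'   `ontologies` (named list BP/MF/CC), `graph`, `associations`, `truth` and
#'   `spec`.
#' @export
simulate_world <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  targets <- pad_id("T", seq_len(spec$n_targets), spec$n_targets)
  diseases <- pad_id("D", seq_len(spec$n_diseases), spec$n_diseases)
  target_module <- setNames(((seq_len(spec$n_targets) - 1L) %% spec$n_modules) + 1L,
                            targets)
  disease_module <- setNames(((seq_len(spec$n_diseases) - 1L) %% spec$n_modules) + 1L,
                             diseases)

  # an imperfect view of the module map: each target's module is misassigned
  # with probability view_noise (independently per view)
  corrupt_view <- function(modules) {
    flip <- runif(length(modules)) < spec$view_noise
    if (spec$n_modules > 1 && any(flip)) {
      modules[flip] <- vapply(modules[flip], function(m) {
        alt <- setdiff(seq_len(spec$n_modules), m)
        alt[sample.int(length(alt), 1)]
      }, integer(1))
    }
    modules
  }

  ## expression -------------------------------------------------------------
  tissues <- pad_id("TIS", seq_len(spec$n_tissues), spec$n_tissues)
  tissue_group <- paste0("G", ceiling(seq_len(spec$n_tissues) / 2))
  n_samples <- spec$n_tissues * spec$samples_per_tissue
  meta <- data.frame(
    sample_id = pad_id("S", seq_len(n_samples), n_samples),
    tissue = rep(tissues, each = spec$samples_per_tissue),
    tissue_group = rep(tissue_group, each = spec$samples_per_tissue),
    age = round(runif(n_samples, 20, 70)),
    sex = sample(c("F", "M"), n_samples, replace = TRUE)
  )
  base <- rlnorm(spec$n_targets, meanlog = 2, sdlog = 0.5)
  age_slope <- rnorm(spec$n_targets, 0, 0.003)
  sex_effect <- rnorm(spec$n_targets, 0, 0.1)
  tissue_idx <- rep(seq_len(spec$n_tissues), each = spec$samples_per_tissue)
  expr_module <- corrupt_view(target_module)
  signal <- outer(expr_module, tissue_idx, "==") * log(1 + spec$signal_strength)
  log_mu <- log(base) + signal +
    outer(age_slope, meta$age - 45) +
    outer(sex_effect, as.numeric(meta$sex == "M"))
  values <- exp(log_mu + matrix(rnorm(spec$n_targets * n_samples, 0, 0.3),
                                spec$n_targets))
  rownames(values) <- targets
  colnames(values) <- meta$sample_id
  expression <- expression_matrix(values, meta)

  ## ontologies -------------------------------------------------------------
  leaves_per_module <- 3L
  ontologies <- lapply(c(BP = "BP", MF = "MF", CC = "CC"), function(ns) {
    root <- paste0(ns, ":ROOT")
    mod_terms <- paste0(ns, ":M", seq_len(spec$n_modules))
    leaf_terms <- unlist(lapply(seq_len(spec$n_modules), function(m) {
      paste0(ns, ":M", m, "L", seq_len(leaves_per_module))
    }))
    edges <- rbind(
      data.frame(child = mod_terms, parent = root, relation = "is_a"),
      do.call(rbind, lapply(seq_len(spec$n_modules), function(m) {
        data.frame(child = paste0(ns, ":M", m, "L", seq_len(leaves_per_module)),
                   parent = paste0(ns, ":M", m),
                   relation = c("is_a", "is_a", "part_of"))
      }))
    )
    ann_module <- corrupt_view(target_module)
    annotations <- lapply(targets, function(tg) {
      m <- ann_module[tg]
      leaves <- paste0(ns, ":M", m, "L", seq_len(leaves_per_module))
      sort(sample(leaves, 2))
    })
    names(annotations) <- targets
    ontology_dag(c(root, mod_terms, leaf_terms), edges, namespace = ns,
                 annotations = annotations)
  })

  ## interaction graph ------------------------------------------------------
  pairs <- which(upper.tri(matrix(0, spec$n_targets, spec$n_targets)),
                 arr.ind = TRUE)
  same <- target_module[pairs[, 1]] == target_module[pairs[, 2]]
  p_edge <- ifelse(same, spec$p_within, spec$p_between)
  has_edge <- runif(nrow(pairs)) < p_edge
  conf <- ifelse(same[has_edge],
                 runif(sum(has_edge), 0.5, 1),
                 runif(sum(has_edge), 0.2, 0.8))
  graph <- weighted_graph(
    data.frame(from = targets[pairs[has_edge, 1]],
               to = targets[pairs[has_edge, 2]],
               confidence = conf),
    nodes = targets
  )

  ## associations -----------------------------------------------------------
  grid_t <- rep(targets, times = spec$n_diseases)
  grid_d <- rep(diseases, each = spec$n_targets)
  true_ind <- target_module[grid_t] == disease_module[grid_d]
  labeled <- true_ind & (runif(length(true_ind)) < spec$label_rate)
  known_drug <- numeric(length(true_ind))
  known_drug[labeled] <- runif(sum(labeled), 0.3, 1)
  assoc <- data.frame(target_id = grid_t, disease_id = grid_d)
  for (col in ot_evidence_cols) {
    raw <- spec$evidence_scale * true_ind +
      rnorm(length(true_ind), 0, spec$evidence_noise)
    assoc[[col]] <- pmin(pmax(raw, 0), 1)  # truncated, preserving mass at 0
  }
  assoc$known_drug <- known_drug
  assoc$is_direct <- TRUE
  assoc$therapeutic_areas <- paste0("area_", disease_module[grid_d])
  associations <- assoc_table(assoc)

  truth <- list(
    target_module = target_module,
    disease_module = disease_module,
    indication = matrix(as.integer(true_ind), spec$n_targets,
                        dimnames = list(targets, diseases))
  )
  structure(list(expression = expression, ontologies = ontologies,
                 graph = graph, associations = associations, truth = truth,
                 spec = spec),
            class = "synthetic_world")
}

#' Write all world artifacts to a directory
#'
#' Emits the expression matrix and metadata, the three OBO ontologies with
#' their annotation TSVs, the STRING-style edge list, the association table
#' and `ground_truth.tsv` in the package's file schemas.
#'
#' @param world a [simulate_world()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_world <- function(world, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  write_expression(world$expression, p("expression.tsv"), p("samples.tsv"))
  for (ns in names(world$ontologies)) {
    dag <- world$ontologies[[ns]]
    write_obo_subset(dag, p(paste0("ontology_", ns, ".obo")))
    write_annotations(dag$annotations, p(paste0("annotations_", ns, ".tsv")))
  }
  write_string_edges(world$graph, p("interactions.tsv"))
  write_associations(world$associations, p("associations.tsv"))
  gt <- data.frame(target_id = names(world$truth$target_module),
                   module = as.integer(world$truth$target_module))
  gd <- data.frame(disease_id = names(world$truth$disease_module),
                   module = as.integer(world$truth$disease_module))
  write.table(gt, p("ground_truth_targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gd, p("ground_truth_diseases.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(outdir)
}
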
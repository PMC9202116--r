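#' Wang S-values of a term's ancestor sub-DAG
#'
#' The semantic contribution of each ancestor `t` of an anchor term `A` is
#' the maximal product of edge weights along any path from `A` up to `t`:
#' `S_A(A) = 1` and `S_A(t) = max over children c of t (within A's ancestor
#' sub-DAG) of w(c -> t) * S_A(c)`, with `w` determined by the edge relation.
#' The semantic value `SV(A)` is the sum of S-values over the sub-DAG.
#'
#' @param dag an [ontology_dag()].
#' @param term anchor term id.
#' @param weights named numeric: contribution factor per edge relation
#'   (defaults `is_a = 0.8`, `part_of = 0.6`).
#' @return list with `term`, `svalues` (named numeric over the sub-DAG) and
#'   `sv` (their sum), class `svalue_map`.
#' @export
wang_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  edges <- dag$edges
  # ancestor sub-DAG: anchor plus everything reachable upward
  sub <- term
  frontier <- term
  while (length(frontier) > 0) {
    up <- unique(edges$parent[edges$child %in% frontier])
    frontier <- setdiff(up, sub)
    sub <- c(sub, frontier)
  }
  e <- edges[edges$child %in% sub & edges$parent %in% sub, , drop = FALSE]
  w <- unname(weights[e$relation])
  s <- setNames(rep(-Inf, length(sub)), sub)
  s[term] <- 1
  # Kahn topological order over child -> parent edges within the sub-DAG
  indeg <- setNames(integer(length(sub)), sub)
  tab <- table(e$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0]
  order_out <- character(0)
  indeg_work <- indeg
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, v)
    out <- which(e$child == v)
    for (i in out) {
      p <- e$parent[i]
      indeg_work[p] <- indeg_work[p] - 1L
      if (indeg_work[p] == 0L) queue <- c(queue, p)
    }
  }
  for (v in order_out) {
    out <- which(e$child == v)
    if (s[v] == -Inf) next  # not reachable from the anchor going up
    for (i in out) {
      p <- e$parent[i]
      cand <- w[i] * s[v]
      if (cand > s[p]) s[p] <- cand
    }
  }
  s <- s[is.finite(s)]
  structure(list(term = term, svalues = s, sv = sum(s)), class = "svalue_map")
}

#' Wang semantic similarity between two ontology terms
#'
#' `sim(A, B) = sum over shared ancestors t of (S_A(t) + S_B(t)) /
#' (SV(A) + SV(B))`. Symmetric, `sim(A, A) = 1`, and 0 when the terms share
#' no ancestor.
#'
#' @inheritParams wang_svalues
#' @param term_a,term_b term ids.
#' @return similarity in `[0, 1]`.
#' @export
wang_term_similarity <- function(dag, term_a, term_b,
                                 weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- wang_svalues(dag, term_a, weights)
  sb <- wang_svalues(dag, term_b, weights)
  common <- intersect(names(sa$svalues), names(sb$svalues))
  if (length(common) == 0) return(0)
  sum(sa$svalues[common] + sb$svalues[common]) / (sa$sv + sb$sv)
}

# Pairwise Wang similarity over a set of terms, with S-values computed once.
term_similarity_matrix <- function(dag, terms,
                                   weights = c(is_a = 0.8, part_of = 0.6)) {
  svs <- lapply(terms, wang_svalues, dag = dag, weights = weights)
  names(svs) <- terms
  n <- length(terms)
  m <- diag(1, n)
  dimnames(m) <- list(terms, terms)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      si <- svs[[i]]
      for (j in seq((i + 1), n)) {
        sj <- svs[[j]]
        common <- intersect(names(si$svalues), names(sj$svalues))
        val <- if (length(common) == 0) 0 else {
          sum(si$svalues[common] + sj$svalues[common]) / (si$sv + sj$sv)
        }
        m[i, j] <- m[j, i] <- val
      }
    }
  }
  m
}

#' Gene-level semantic similarity (best-match average)
#'
#' Aggregates the term-term Wang similarity matrix between the two genes'
#' annotation sets by the best-match average: the mean of all per-row maxima
#' and per-column maxima. Returns `NA` when either gene carries no
#' annotation in this namespace (callers later fill missing with 0).
#'
#' @inheritParams wang_svalues
#' @param gene_a,gene_b gene ids, looked up in `dag$annotations`.
#' @param combine aggregation rule; only `"BMA"` is implemented.
#' @return similarity in `[0, 1]`, or `NA` for an unannotated gene.
#' @export
gene_semantic_similarity <- function(dag, gene_a, gene_b, combine = "BMA",
                                     weights = c(is_a = 0.8, part_of = 0.6)) {
  combine <- match.arg(combine)
  ta <- dag$annotations[[gene_a]]
  tb <- dag$annotations[[gene_b]]
  if (is.null(ta) || is.null(tb) || length(ta) == 0 || length(tb) == 0) {
    return(NA_real_)
  }
  m <- term_similarity_matrix(dag, unique(c(ta, tb)), weights)[ta, tb,
                                                               drop = FALSE]
  mean(c(apply(m, 1, max), apply(m, 2, max)))
}

#' Semantic similarity matrix over a gene universe
#'
#' Computes the best-match-average Wang similarity for every gene pair in one
#' ontology namespace. The computation is vectorised through the identity
#' `BMA(g1, g2) = (sum over t in g1 of B[t, g2] + sum over t in g2 of
#' B[t, g1]) / (|g1| + |g2|)` where `B[t, g]` is the best term-term
#' similarity between `t` and any annotation of `g`. Unannotated genes get
#' `NA` rows/columns (missing, to be filled 0 by the caller).
#'
#' @inheritParams wang_svalues
#' @param genes gene universe (character); defaults to all annotated genes.
#' @return a [similarity_matrix()] tagged `GO_<namespace>`.
#' @export
go_similarity_matrix <- function(dag, genes = NULL,
                                 weights = c(is_a = 0.8, part_of = 0.6)) {
  ann <- dag$annotations
  if (is.null(genes)) genes <- sort(names(ann))
  ann <- ann[intersect(genes, names(ann))]
  ann <- ann[lengths(ann) > 0]
  annotated <- names(ann)
  if (length(annotated) == 0) stop("no annotated genes in this namespace")
  terms <- sort(unique(unlist(ann, use.names = FALSE)))
  m <- term_similarity_matrix(dag, terms, weights)
  # indicator terms x genes and per-term best match against each gene's set
  a_ind <- matrix(0, length(terms), length(annotated),
                  dimnames = list(terms, annotated))
  b_best <- matrix(0, length(terms), length(annotated),
                   dimnames = list(terms, annotated))
  for (g in seq_along(annotated)) {
    tg <- ann[[g]]
    a_ind[tg, g] <- 1
    b_best[, g] <- do.call(pmax, as.data.frame(m[, tg, drop = FALSE]))
  }
  cross <- crossprod(a_ind, b_best)  # cross[g1, g2] = sum_{t in g1} B[t, g2]
  sizes <- lengths(ann)
  sim <- (cross + t(cross)) / outer(sizes, sizes, "+")
  diag(sim) <- 1
  sim <- (sim + t(sim)) / 2
  out <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
  out[annotated, annotated] <- sim
  tag <- paste0("GO_", dag$namespace)
  structure(out, source_tag = tag,
            zero_norm = setdiff(genes, annotated),
            class = c("similarity_matrix", class(out)))
}
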
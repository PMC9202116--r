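# Independent brute-force oracles. These deliberately re-derive each quantity
# from its definition (path enumeration, exhaustive threshold scans, pairwise
# counts, naive per-cell sums) and share no code with the implementation.

oracle_wang_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  best <- new.env(parent = emptyenv())
  assign(term, 1, envir = best)
  recurse <- function(node, prod) {
    e <- dag$edges[dag$edges$child == node, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      p <- e$parent[i]
      val <- prod * weights[[e$relation[i]]]
      cur <- if (exists(p, envir = best)) get(p, envir = best) else -Inf
      if (val > cur) assign(p, val, envir = best)
      recurse(p, val)  # enumerate every upward path
    }
  }
  recurse(term, 1)
  s <- unlist(as.list(best))
  list(svalues = s, sv = sum(s))
}

# Random DAG: term i >= 2 attaches to 1-2 earlier terms with random relations.
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- sprintf("t%02d", seq_len(n_terms))
  child <- parent <- relation <- character(0)
  for (i in seq(2, n_terms)) {
    n_par <- sample(1:2, 1)
    pars <- sample(seq_len(i - 1), min(n_par, i - 1))
    child <- c(child, rep(terms[i], length(pars)))
    parent <- c(parent, terms[pars])
    relation <- c(relation, sample(c("is_a", "part_of"), length(pars),
                                   replace = TRUE))
  }
  ontology_dag(terms, data.frame(child = child, parent = parent,
                                 relation = relation), namespace = "BP")
}

# Naive double-loop transcription of the encoding equation.
oracle_encode <- function(sim, kd, k, mask = character(0)) {
  targets <- rownames(kd)
  diseases <- colnames(kd)
  kd_eff <- kd
  kd_eff[rownames(kd_eff) %in% mask, ] <- 0
  out <- matrix(0, length(targets), length(diseases),
                dimnames = list(targets, diseases))
  for (j in targets) {
    s <- sim[j, setdiff(targets, j)]
    ord <- order(-s, names(s))
    ids <- names(s)[ord][seq_len(min(k, length(s)))]
    w <- unname(s[ids])
    den <- sum(abs(w))
    if (den == 0) next
    for (d in diseases) {
      out[j, d] <- sum(w * kd_eff[ids, d]) / den
    }
  }
  out
}

# Exhaustive threshold scan: confusion counts recomputed per threshold by
# direct comparison.
oracle_curve <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(thresholds, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
               fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0))
  }))
}

oracle_ap <- function(scores, labels) {
  cc <- oracle_curve(scores, labels)
  precision <- cc$tp / (cc$tp + cc$fp)
  recall <- cc$tp / sum(labels == 1)
  sum(diff(c(0, recall)) * precision)
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

oracle_best_fbeta <- function(scores, labels, beta) {
  cc <- oracle_curve(scores, labels)
  best <- list(threshold = NA, fbeta = -1)
  b2 <- beta^2
  for (i in seq_len(nrow(cc))) {
    precision <- if (cc$tp[i] + cc$fp[i] == 0) 0 else cc$tp[i] / (cc$tp[i] + cc$fp[i])
    recall <- cc$tp[i] / sum(labels == 1)
    fb <- if (b2 * precision + recall == 0) 0 else
      (1 + b2) * precision * recall / (b2 * precision + recall)
    if (fb > best$fbeta ||
        (fb == best$fbeta && cc$threshold[i] < best$threshold)) {
      best <- list(threshold = cc$threshold[i], precision = precision,
                   recall = recall, fbeta = fb)
    }
  }
  best
}

oracle_hyper_tail <- function(overlap, size_a, size_b, universe) {
  i <- seq(overlap, min(size_a, size_b))
  sum(choose(size_b, i) * choose(universe - size_b, size_a - i)) /
    choose(universe, size_a)
}
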
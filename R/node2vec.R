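#' Second-order biased random walks (node2vec)
#'
#' Simulates node2vec walks over a weighted, undirected graph. The first step
#' from a start node follows edge confidences; each later step from node `v`
#' with predecessor `t` picks neighbor `x` with probability proportional to
#' `confidence(v, x) * alpha`, where `alpha = 1/p` if `x == t` (return),
#' `1` if `x` is adjacent to `t`, and `1/q` otherwise (in-out). With
#' `p = q = 1` this reduces to a first-order weighted random walk.
#'
#' @param graph a [weighted_graph()] (already confidence-filtered).
#' @param p return parameter.
#' @param q in-out parameter.
#' @param walk_length number of nodes per walk.
#' @param num_walks walks started from every node.
#' @param seed RNG seed (set internally when not `NULL`).
#' @return list with `walks` (list of integer vectors indexing `nodes`) and
#'   `nodes` (character ids).
#' @export
node2vec_walks <- function(graph, p = 1, q = 1, walk_length = 80,
                           num_walks = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0 || nrow(graph$edges) == 0) stop("empty graph")
  fi <- match(graph$edges$from, nodes)
  ti <- match(graph$edges$to, nodes)
  w <- graph$edges$confidence
  ends <- c(fi, ti)
  nbr <- split(c(ti, fi), ends)
  wts <- split(c(w, w), ends)
  nbrs <- vector("list", n)
  wl <- vector("list", n)
  idx <- as.integer(names(nbr))
  nbrs[idx] <- nbr
  wl[idx] <- wts
  walks <- vector("list", n * num_walks)
  k <- 0L
  for (iter in seq_len(num_walks)) {
    starts <- sample.int(n)  # node2vec shuffles start order each pass
    for (s in starts) {
      walk <- integer(walk_length)
      walk[1] <- s
      cand <- nbrs[[s]]
      if (is.null(cand)) {
        k <- k + 1L
        walks[[k]] <- walk[1]
        next
      }
      cw <- wl[[s]]
      walk[2] <- if (length(cand) == 1) cand else
        cand[sample.int(length(cand), 1, prob = cw)]
      step <- 2L
      while (step < walk_length) {
        prev <- walk[step - 1L]
        cur <- walk[step]
        cand <- nbrs[[cur]]
        if (is.null(cand)) break
        bias <- rep.int(1 / q, length(cand))
        bias[cand %in% nbrs[[prev]]] <- 1
        bias[cand == prev] <- 1 / p
        pr <- wl[[cur]] * bias
        step <- step + 1L
        walk[step] <- if (length(cand) == 1) cand else
          cand[sample.int(length(cand), 1, prob = pr)]
      }
      k <- k + 1L
      walks[[k]] <- walk[seq_len(step)]
    }
  }
  list(walks = walks[seq_len(k)], nodes = nodes)
}

#' node2vec node embeddings
#'
#' Filters the interaction graph to high-confidence edges (confidence
#' strictly greater than `min_confidence`), simulates second-order biased
#' walks and trains a skip-gram model with negative sampling on the walk
#' corpus (single-threaded, deterministic under `seed`).
#'
#' @inheritParams node2vec_walks
#' @param dim embedding dimension.
#' @param window maximum skip-gram window (sampled dynamically per position,
#'   as in word2vec).
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the walk corpus.
#' @param alpha initial learning rate (decays linearly).
#' @param min_confidence confidence cutoff applied before walking; set to
#'   `NULL` if the graph is already filtered.
#' @param seed RNG seed for walks, initialisation and negative sampling.
#' @return numeric nodes x dim matrix with node ids as rownames.
#' @export
node2vec_embed <- function(graph, p = 1, q = 1, walk_length = 80,
                           num_walks = 10, dim = 128, window = 10,
                           negatives = 5, epochs = 1, alpha = 0.025,
                           min_confidence = 0.5, seed = 1) {
  if (!is.null(min_confidence)) graph <- filter_graph(graph, min_confidence)
  if (length(graph$nodes) == 0 || nrow(graph$edges) == 0) {
    stop("graph is empty after confidence filtering")
  }
  wk <- node2vec_walks(graph, p = p, q = q, walk_length = walk_length,
                       num_walks = num_walks, seed = seed)
  emb <- sgns_train(wk$walks, length(wk$nodes), as.integer(dim),
                    as.integer(window), as.integer(negatives),
                    as.integer(epochs), alpha, as.integer(seed))
  rownames(emb) <- wk$nodes
  emb
}

#' Cosine similarity between node embeddings
#'
#' @param emb embedding matrix from [node2vec_embed()].
#' @return a [similarity_matrix()] tagged `ppi_embedding`.
#' @export
embedding_similarity <- function(emb) {
  if (nrow(emb) == 0) stop("empty embedding")
  cosine_similarity(emb, source_tag = "ppi_embedding")
}
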
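#' Construct a weighted interaction graph
#'
#' Undirected protein-protein interaction graph with per-edge confidence in
#' `[0,1]`. Self-loops are not allowed; duplicate undirected edges must have
#' been collapsed by the reader.
#'
#' @param edges data.frame with columns `from`, `to`, `confidence`.
#' @param nodes optional character vector of node ids (defaults to the nodes
#'   appearing in `edges`).
#' @return list of class `weighted_graph` with elements `nodes` and `edges`.
#' @export
weighted_graph <- function(edges, nodes = NULL) {
  stopifnot(all(c("from", "to", "confidence") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) stop("self-loop in edge list")
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidence out of [0,1]")
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "weighted_graph")
}

#' Read a STRING-style weighted edge list
#'
#' Whitespace- or tab-delimited lines of `node node score`, with an optional
#' header. Released STRING files carry integer combined scores on a 0-1000
#' scale (`dialect = "thousand"`); scores already in `[0,1]` use
#' `dialect = "unit"`. Duplicate undirected edges are collapsed keeping the
#' maximum confidence; self-loops are dropped with a message.
#'
#' @param path edge-list file.
#' @param dialect `"thousand"` (divide scores by 1000) or `"unit"`.
#' @return a [weighted_graph()].
#' @export
read_string_edges <- function(path, dialect = c("thousand", "unit")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty edge list: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) != 3)) {
    stop("malformed edge line ", which(lengths(fields) != 3)[1], " in ", path)
  }
  first_score <- suppressWarnings(as.numeric(fields[[1]][3]))
  if (is.na(first_score)) fields <- fields[-1]  # header line
  m <- do.call(rbind, fields)
  score <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(score)) stop("non-numeric score at edge line ", which(is.na(score))[1])
  if (any(score < 0)) stop("negative score at edge line ", which(score < 0)[1])
  if (dialect == "thousand") score <- score / 1000
  if (any(score > 1)) {
    stop("score above the dialect maximum at edge line ", which(score > 1)[1])
  }
  from <- m[, 1]; to <- m[, 2]
  loops <- from == to
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    from <- from[!loops]; to <- to[!loops]; score <- score[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  keep <- tapply(score, key, max)
  parts <- strsplit(names(keep), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      confidence = as.numeric(keep))
  edges <- edges[order(edges$from, edges$to), ]
  weighted_graph(edges)
}

#' Write a weighted graph as a STRING-style edge list
#'
#' @param graph a [weighted_graph()].
#' @param path output file path.
#' @param dialect score scale, as in [read_string_edges()].
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(graph, path, dialect = c("thousand", "unit")) {
  dialect <- match.arg(dialect)
  out <- graph$edges
  if (dialect == "thousand") out$confidence <- out$confidence * 1000
  names(out) <- c("protein1", "protein2", "combined_score")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a graph by edge confidence
#'
#' Keeps only interactions with confidence strictly greater than the cutoff
#' (high-trust network); nodes left without any edge are dropped with a
#' warning.
#'
#' @param graph a [weighted_graph()].
#' @param min_confidence edges with confidence `<= min_confidence` are removed
#'   (default 0.5).
#' @return the filtered [weighted_graph()].
#' @export
filter_graph <- function(graph, min_confidence = 0.5) {
  edges <- graph$edges[graph$edges$confidence > min_confidence, , drop = FALSE]
  kept <- sort(unique(c(edges$from, edges$to)))
  dropped <- setdiff(graph$nodes, kept)
  if (length(dropped) > 0) {
    warning(length(dropped), " node(s) isolated after confidence filter")
  }
  weighted_graph(edges, nodes = kept)
}

#' Construct an ontology DAG
#'
#' A single-namespace ontology with typed `is_a` / `part_of` edges from child
#' to parent, plus optional gene annotations. The edge graph must be acyclic.
#'
#' @param terms character vector of term ids.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (each relation one of `is_a`, `part_of`).
#' @param namespace one of `"BP"`, `"MF"`, `"CC"`.
#' @param annotations named list mapping gene id to a character vector of
#'   annotated terms (all terms must exist in the DAG).
#' @return list of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, edges, namespace = c("BP", "MF", "CC"),
                         annotations = list()) {
  namespace <- match.arg(namespace)
  terms <- as.character(terms)
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  if (!all(edges$relation %in% c("is_a", "part_of"))) {
    stop("edge relation must be is_a or part_of")
  }
  unknown <- setdiff(c(edges$child, edges$parent), terms)
  if (length(unknown) > 0) stop("edge references unknown term ", unknown[1])
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = terms)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1)]
      stop("ontology contains a cycle involving term ", cyc[1])
    }
  }
  bad_ann <- setdiff(unlist(annotations, use.names = FALSE), terms)
  if (length(bad_ann) > 0) {
    stop("annotation references unknown term ", bad_ann[1])
  }
  rownames(edges) <- NULL
  structure(list(terms = terms, edges = edges, namespace = namespace,
                 annotations = annotations),
            class = "ontology_dag")
}

#' Read an OBO-subset ontology file
#'
#' Parses `[Term]` stanzas with `id`, `namespace`, `is_a` and
#' `relationship: part_of` fields. Namespaces `biological_process`,
#' `molecular_function` and `cellular_component` map to BP/MF/CC; the file
#' must contain a single namespace. Cycles are rejected.
#'
#' @param path OBO file path.
#' @return an [ontology_dag()] (without annotations).
#' @export
read_obo_subset <- function(path) {
  lines <- readLines(path)
  terms <- character(0)
  ns <- character(0)
  child <- parent <- relation <- character(0)
  cur <- NULL
  flush_ws <- function(x) sub("\\s*!.*$", "", trimws(x))
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") { cur <- NULL; next }
    if (startsWith(line, "id:")) {
      cur <- flush_ws(sub("^id:", "", line))
      terms <- c(terms, cur)
    } else if (startsWith(line, "namespace:") && !is.null(cur)) {
      ns <- c(ns, flush_ws(sub("^namespace:", "", line)))
    } else if (startsWith(line, "is_a:") && !is.null(cur)) {
      child <- c(child, cur)
      parent <- c(parent, flush_ws(sub("^is_a:", "", line)))
      relation <- c(relation, "is_a")
    } else if (startsWith(line, "relationship:") && !is.null(cur)) {
      rest <- flush_ws(sub("^relationship:", "", line))
      parts <- strsplit(rest, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        child <- c(child, cur)
        parent <- c(parent, parts[2])
        relation <- c(relation, "part_of")
      }
    }
  }
  if (length(terms) == 0) stop("no terms found in ", path)
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC")
  ns <- unique(ns_map[ns])
  ns <- ns[!is.na(ns)]
  if (length(ns) > 1) stop("mixed namespaces in ", path)
  if (length(ns) == 0) ns <- "BP"
  ontology_dag(terms,
               data.frame(child = child, parent = parent, relation = relation),
               namespace = ns)
}

#' Write an ontology DAG as an OBO subset
#'
#' @param dag an [ontology_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo_subset <- function(dag, path) {
  ns_long <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")[dag$namespace]
  out <- c("format-version: 1.2", "")
  for (term in dag$terms) {
    out <- c(out, "[Term]", paste0("id: ", term),
             paste0("namespace: ", ns_long))
    e <- dag$edges[dag$edges$child == term, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[i] == "is_a") {
        paste0("is_a: ", e$parent[i])
      } else {
        paste0("relationship: part_of ", e$parent[i])
      })
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene-to-term annotations
#'
#' GAF-like two-column TSV (`gene_id`, `term_id`), one annotation per line.
#'
#' @param path TSV file path.
#' @return named list mapping gene id to character vector of terms.
#' @export
read_annotations <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(raw))) {
    stop("annotation file needs gene_id and term_id columns")
  }
  lapply(split(raw$term_id, raw$gene_id), function(x) sort(unique(x)))
}

#' Write gene-to-term annotations
#'
#' @param annotations named list of term vectors per gene.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    gene_id = rep(names(annotations), lengths(annotations)),
    term_id = unlist(annotations, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach annotations to an ontology DAG
#'
#' @param dag an [ontology_dag()].
#' @param annotations named list mapping gene id to terms of this namespace.
#' @return the DAG with annotations set.
#' @export
set_annotations <- function(dag, annotations) {
  ontology_dag(dag$terms, dag$edges, dag$namespace, annotations)
}
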
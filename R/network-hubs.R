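# PPI networks: STRING-style edge lists, pivoting Bron-Kerbosch maximal
# clique enumeration, Maximal Clique Centrality (MCC) hub scoring.
#
# MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!.
# An isolated node owns the singleton maximal clique {v} and scores
# (1 - 1)! = 1.

#' Construct a PPI graph
#'
#' Normalizes to a simple undirected graph: self-loops dropped (with a
#' warning), duplicate and reversed-duplicate edges collapsed (keeping
#' the maximum score), edges stored with node1 < node2.
#'
#' @param nodes Character vector of node ids (closed over edges; nodes
#'   mentioned only in `edges` are added).
#' @param edges data.frame with `node1`, `node2` and optional `score`.
#' @return List of class `ppi_graph` with sorted `nodes` and canonical
#'   `edges`.
#' @export
ppi_graph <- function(nodes = character(0),
                      edges = data.frame(node1 = character(0),
                                         node2 = character(0))) {
  stopifnot(all(c("node1", "node2") %in% colnames(edges)))
  if (!"score" %in% colnames(edges)) edges$score <- rep(1, nrow(edges))
  loops <- edges$node1 == edges$node2
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    score <- tapply(edges$score, key, max)
    uk <- names(score)
    parts <- strsplit(uk, "\r", fixed = TRUE)
    edges <- data.frame(node1 = vapply(parts, `[`, "", 1),
                        node2 = vapply(parts, `[`, "", 2),
                        score = as.numeric(score),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(node1 = a, node2 = b, score = edges$score,
                        stringsAsFactors = FALSE)
  }
  o <- order(edges$node1, edges$node2)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(nodes, edges$node1, edges$node2)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_graph")
}

#' Read a STRING-style edge list
#'
#' Two or three tab-separated columns: node1, node2, optional
#' combined score. Edges scoring below `min_score` are dropped;
#' duplicates, reversed duplicates and self-loops are normalized away.
#'
#' @param path Path to the TSV (a header line starting with "node1" is
#'   tolerated and skipped).
#' @param min_score Minimum edge score retained (default 0).
#' @return A [ppi_graph()].
#' @export
read_edge_list <- function(path, min_score = 0.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && grepl("^node1\t", lines[1]))
    lines <- lines[-1]
  n1 <- character(length(lines)); n2 <- n1
  sc <- rep(1, length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% c(2, 3))
      stop("malformed edge-list line ", i, ": expected 2 or 3 fields")
    if (length(f) == 3) {
      s <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s)) stop("malformed edge-list line ", i,
                         ": unparseable score '", f[3], "'")
      sc[i] <- s
    }
    n1[i] <- f[1]; n2[i] <- f[2]
  }
  keep <- sc >= min_score
  ppi_graph(edges = data.frame(node1 = n1[keep], node2 = n2[keep],
                               score = sc[keep], stringsAsFactors = FALSE))
}

#' Write a PPI graph as an edge-list TSV
#' @param g A `ppi_graph`.
#' @param path Output path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "ppi_graph"))
  write_tsv(g$edges, path)
  invisible(path)
}

#' Induced subgraph on a node subset
#' @param g A `ppi_graph`.
#' @param keep Character vector of node ids to retain.
#' @return A `ppi_graph` on `intersect(g$nodes, keep)`.
#' @export
subgraph_on <- function(g, keep) {
  stopifnot(inherits(g, "ppi_graph"))
  nodes <- intersect(g$nodes, keep)
  e <- g$edges[g$edges$node1 %in% nodes & g$edges$node2 %in% nodes, ,
               drop = FALSE]
  ppi_graph(nodes, e)
}

adjacency_list <- function(g) {
  n <- length(g$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  i1 <- match(g$edges$node1, g$nodes)
  i2 <- match(g$edges$node2, g$nodes)
  for (k in seq_along(i1)) {
    adj[[i1[k]]] <- c(adj[[i1[k]]], i2[k])
    adj[[i2[k]]] <- c(adj[[i2[k]]], i1[k])
  }
  lapply(adj, sort)
}

#' Enumerate all maximal cliques
#'
#' Pivoting Bron-Kerbosch enumeration. Output is canonical: each clique's
#' members sorted, cliques in lexicographic order. An isolated node yields
#' the singleton clique {v}; the empty graph yields an empty list.
#'
#' @param g A `ppi_graph`.
#' @return List of character vectors (the maximal cliques).
#' @export
enumerate_maximal_cliques <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  n <- length(g$nodes)
  if (n == 0) return(list())
  adj <- adjacency_list(g)
  out <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    cand <- c(P, X)
    nn <- vapply(cand, function(u) length(intersect(P, adj[[u]])),
                 integer(1))
    u <- cand[which.max(nn)]
    for (v in setdiff(P, adj[[u]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible()
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques <- lapply(out, function(idx) g$nodes[sort(idx)])
  keys <- vapply(cliques, paste, "", collapse = "\r")
  cliques[order(keys)]
}

#' Maximal Clique Centrality hub table
#'
#' MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!.
#' Rows sorted by MCC descending, then degree descending, then node id
#' ascending; `rank` is 1..n in that order.
#'
#' @param g A `ppi_graph`.
#' @return data.frame `node`, `mcc`, `degree`, `rank`.
#' @export
mcc_scores <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  cliques <- enumerate_maximal_cliques(g)
  mcc <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  for (cl in cliques) mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  deg <- stats::setNames(integer(length(g$nodes)), g$nodes)
  dt <- table(c(g$edges$node1, g$edges$node2))
  deg[names(dt)] <- as.integer(dt)
  out <- data.frame(node = g$nodes, mcc = unname(mcc),
                    degree = unname(deg), stringsAsFactors = FALSE)
  out <- out[order(-out$mcc, -out$degree, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top-k hub nodes
#'
#' @param t A [mcc_scores()] table.
#' @param k Number of hubs (default 10); if `k` exceeds the node count,
#'   all nodes are returned with a warning.
#' @return Character vector of node ids in hub order.
#' @export
top_hubs <- function(t, k = 10) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(t)) {
    warning("k = ", k, " exceeds node count ", nrow(t),
            "; returning all nodes")
    k <- nrow(t)
  }
  t$node[seq_len(k)]
}
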
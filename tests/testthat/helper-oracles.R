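# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# Exhaustive maximal-clique oracle: tests all 2^n node subsets using
# bitmask arithmetic (n <= 20). A subset is a clique iff every member's
# non-neighbours are absent; maximal iff no outside vertex is adjacent to
# all members.
oracle_max_cliques <- function(g) {
  nodes <- g$nodes
  n <- length(nodes)
  stopifnot(n <= 20)
  if (n == 0) return(list())
  bit <- bitwShiftL(1L, 0:(n - 1))
  adjm <- integer(n)
  i1 <- match(g$edges$node1, nodes)
  i2 <- match(g$edges$node2, nodes)
  for (k in seq_along(i1)) {
    adjm[i1[k]] <- bitwOr(adjm[i1[k]], bit[i2[k]])
    adjm[i2[k]] <- bitwOr(adjm[i2[k]], bit[i1[k]])
  }
  allmask <- bitwShiftL(1L, n) - 1L
  S <- 0:allmask
  isclq <- rep(TRUE, length(S))
  for (v in seq_len(n)) {
    comp <- bitwAnd(allmask, bitwNot(bitwOr(adjm[v], bit[v])))
    inS <- bitwAnd(S, bit[v]) > 0L
    isclq <- isclq & (!inS | bitwAnd(S, comp) == 0L)
  }
  isclq[1] <- FALSE  # empty set
  extendable <- rep(FALSE, length(S))
  for (w in seq_len(n)) {
    notin <- bitwAnd(S, bit[w]) == 0L
    covered <- bitwAnd(S, bitwNot(adjm[w])) == 0L
    extendable <- extendable | (notin & covered)
  }
  masks <- S[isclq & !extendable]
  cliques <- lapply(masks, function(mm) nodes[bitwAnd(mm, bit) > 0L])
  keys <- vapply(cliques, paste, "", collapse = "\r")
  cliques[order(keys)]
}

oracle_mcc <- function(g) {
  cliques <- oracle_max_cliques(g)
  mcc <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  for (cl in cliques) mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  mcc
}

# Exhaustive hypergeometric upper tail: enumerate every size-n study draw
# from a population with K annotated members and count draws with >= k
# annotated.
oracle_hyper_upper <- function(N, K, n, k) {
  pop <- seq_len(N)
  annotated <- seq_len(K)
  draws <- utils::combn(pop, n)
  hits <- colSums(matrix(draws %in% annotated, nrow = n))
  mean(hits >= k)
}

# Literal Benjamini-Hochberg step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[o][i:m] * m / (i:m)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

random_test_graph <- function(n, p = 0.3, prefix = "n") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  if (n < 2)
    return(ppi_graph(nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  ppi_graph(nodes, data.frame(node1 = pairs[1, keep],
                              node2 = pairs[2, keep],
                              stringsAsFactors = FALSE))
}

graph_from_mask <- function(n, mask_bits) {
  # build a graph on n labelled nodes from a vector of 0/1 edge indicators
  nodes <- sprintf("v%d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- mask_bits == 1L
  ppi_graph(nodes, data.frame(node1 = pairs[1, keep],
                              node2 = pairs[2, keep],
                              stringsAsFactors = FALSE))
}
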
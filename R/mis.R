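#' Standalone conflict graph
#'
#' Lightweight constructor used to run the independent-set machinery on an
#' arbitrary vertex-weighted graph (tests, oracles, reductions) without
#' going through candidate-pair construction.
#'
#' @param n vertex count; vertices are 1..n.
#' @param edges two-column matrix of 1-based vertex pairs (may be `NULL`).
#' @param scores numeric vertex weights (default 0).
#' @return an object usable by [enumerate_top_k()].
#' @export
conflict_graph <- function(n, edges = NULL, scores = rep(0, n)) {
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1 | edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed")
  }
  structure(list(n = as.integer(n), edges = edges, scores = scores),
            class = "conflict_graph")
}

graph_parts <- function(X) {
  if (inherits(X, "aux_graph"))
    list(n = nrow(X$pairs), edges = X$edges, scores = X$pairs$score)
  else if (inherits(X, "conflict_graph"))
    list(n = X$n, edges = X$edges, scores = X$scores)
  else stop("expected an aux_graph or conflict_graph")
}

ranked_set <- function(members, scores) {
  members <- sort(as.integer(members))
  list(members = members, cardinality = length(members),
       total_score = if (length(members)) sum(scores[members]) else 0)
}

# total order: cardinality desc, total score desc, lexicographic members asc
rank_order <- function(sets) {
  if (length(sets) == 0) return(integer(0))
  card <- vapply(sets, `[[`, integer(1), "cardinality")
  sc <- vapply(sets, `[[`, numeric(1), "total_score")
  key <- vapply(sets, function(s)
    paste(sprintf("%06d", s$members), collapse = ","), character(1))
  order(-card, -sc, key)
}

#' Enumerate the top-K maximal independent sets
#'
#' Branch-and-bound enumeration of maximal independent sets of a conflict
#' graph, returned in decreasing (cardinality, total score) order with a
#' deterministic lexicographic tie-break; the first element is always a
#' maximum independent set. "Top-K" is read over *maximal* sets, so K > 1
#' surfaces near-optimal alternative alignments even when the maximum is
#' unique.
#'
#' The search is a pivoted branch-and-bound over (chosen, candidate,
#' excluded) vertex sets in the complement (compatibility) relation, with
#' a cardinality upper bound `|chosen| + |candidates|` pruning branches
#' that cannot reach the current K-th best cardinality.
#'
#' @param X an [build_auxiliary_graph()] result or a [conflict_graph()].
#' @param K maximum number of sets to return (>= 1).
#' @return list of ranked sets, each a list with `members` (sorted 1-based
#'   vertex ids), `cardinality` and `total_score`. The empty graph yields
#'   one empty set.
#' @export
enumerate_top_k <- function(X, K = 1000) {
  stopifnot(K >= 1)
  gp <- graph_parts(X)
  n <- gp$n
  if (n == 0) return(list(ranked_set(integer(0), numeric(0))))
  comp <- matrix(TRUE, n, n)                # compatibility = non-adjacency
  diag(comp) <- FALSE
  if (nrow(gp$edges) > 0) {
    comp[gp$edges] <- FALSE
    comp[gp$edges[, 2:1, drop = FALSE]] <- FALSE
  }
  st <- new.env(parent = emptyenv())
  st$sets <- vector("list", 256)
  st$count <- 0L
  st$bound <- -1L                           # K-th best cardinality so far
  scores <- gp$scores

  compress <- function() {
    sets <- st$sets[seq_len(st$count)]
    o <- rank_order(sets)
    keep <- o[seq_len(min(K, length(o)))]
    st$sets <- sets[keep]
    length(st$sets) <- max(256, 2L * K)
    st$count <- length(keep)
    if (st$count >= K) st$bound <- st$sets[[st$count]]$cardinality
  }
  record <- function(R) {
    st$count <- st$count + 1L
    if (st$count > length(st$sets)) length(st$sets) <- 2L * length(st$sets)
    st$sets[[st$count]] <- ranked_set(R, scores)
    if (st$count >= 2L * K + 64L) compress()
    else if (st$count == K && st$bound < 0L) compress()
  }
  bk <- function(R, P, X_) {
    if (st$bound >= 0L && length(R) + length(P) < st$bound) return()
    if (length(P) == 0L) {
      if (length(X_) == 0L) record(R)
      return()
    }
    cand <- c(P, X_)
    deg <- vapply(cand, function(u) sum(comp[u, P]), integer(1))
    u <- cand[which.max(deg)]
    ext <- P[!comp[u, P]]
    for (v in ext) {
      bk(c(R, v), P[comp[v, P]], X_[comp[v, X_]])
      P <- P[P != v]
      X_ <- c(X_, v)
      if (st$bound >= 0L && length(R) + length(P) < st$bound) return()
    }
  }
  bk(integer(0), 1:n, integer(0))
  compress()
  st$sets[seq_len(st$count)]
}

#' Exhaustive top-K maximal independent sets (oracle)
#'
#' Subset-scan reference implementation: every vertex subset is tested for
#' independence and maximality via bitmask arithmetic, then the same
#' (cardinality, score, lexicographic) order as [enumerate_top_k()] is
#' applied. Guarded to at most 20 vertices.
#'
#' @inheritParams enumerate_top_k
#' @return list of ranked sets.
#' @export
brute_force_top_k <- function(X, K = 1000) {
  gp <- graph_parts(X)
  n <- gp$n
  if (n > 20) stop("brute_force_top_k is guarded to n <= 20 vertices")
  if (n == 0) return(list(ranked_set(integer(0), numeric(0))))
  adj_mask <- integer(n)
  if (nrow(gp$edges) > 0) {
    for (e in seq_len(nrow(gp$edges))) {
      a <- gp$edges[e, 1]; b <- gp$edges[e, 2]
      adj_mask[a] <- bitwOr(adj_mask[a], bitwShiftL(1L, b - 1L))
      adj_mask[b] <- bitwOr(adj_mask[b], bitwShiftL(1L, a - 1L))
    }
  }
  subs <- 0:(2^n - 1)
  indep <- rep(TRUE, length(subs))
  maximal <- rep(TRUE, length(subs))
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    in_v <- bitwAnd(subs, bit) != 0L
    hit <- bitwAnd(subs, adj_mask[v]) != 0L
    indep <- indep & !(in_v & hit)
    maximal <- maximal & (in_v | hit)
  }
  ok <- which(indep & maximal)
  sets <- lapply(subs[ok], function(s)
    ranked_set(which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L),
               gp$scores))
  o <- rank_order(sets)
  sets[o[seq_len(min(K, length(o)))]]
}

#' Maximum independent set of a conflict graph
#'
#' @inheritParams enumerate_top_k
#' @return one ranked set: the first element of `enumerate_top_k(X, 1)`.
#' @export
maximum_independent_set <- function(X) enumerate_top_k(X, 1)[[1]]
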
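#' Build the auxiliary conflict graph
#'
#' Every candidate pair g_i -> h_j becomes a vertex x_ij. Two vertices
#' x_ij and x_kl conflict (get an edge) when the two mappings cannot
#' coexist in one valid alignment:
#' \enumerate{
#'   \item they share an endpoint: i = k or j = l;
#'   \item (sequential mode only) they cross: i < k and j > l, or i > k
#'     and j < l;
#'   \item the query SSEs are in contact while the host SSEs are not:
#'     \{g_i, g_k\} in E(G) but \{h_j, h_l\} not in E(H).
#' }
#' Independent sets of the result are exactly the valid partial
#' alignments; dropping condition 2 (`sequential = FALSE`) permits
#' non-sequential SSE correspondences.
#'
#' Duplicate (g_index, h_index) pairs in the input are deduplicated,
#' keeping the maximum score.
#'
#' @param pairs data.frame of candidate pairs (`g_index`, `h_index`,
#'   `score`), e.g. from [top_r_candidates()].
#' @param G,H the query and host `mixed_graph`s.
#' @param sequential apply the order-crossing condition?
#' @return an object of class `aux_graph`: list with `pairs` (the vertex
#'   table), `edges` (two-column matrix of 1-based vertex row indices) and
#'   `sequential`.
#' @export
build_auxiliary_graph <- function(pairs, G, H, sequential = TRUE) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0) {
    if (any(pairs$g_index < 0 | pairs$g_index >= n_sse(G)) ||
        any(pairs$h_index < 0 | pairs$h_index >= n_sse(H)))
      stop("candidate pair references an SSE index out of range")
    o <- order(pairs$g_index, pairs$h_index, -pairs$score)
    pairs <- pairs[o, , drop = FALSE]
    pairs <- pairs[!duplicated(pairs[, c("g_index", "h_index")]), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
  }
  n <- nrow(pairs)
  edges <- NULL
  if (n > 1) {
    eg <- edge_flag_matrix(G)
    eh <- edge_flag_matrix(H)
    idx <- utils::combn(n, 2)
    i <- pairs$g_index[idx[1, ]]; j <- pairs$h_index[idx[1, ]]
    k <- pairs$g_index[idx[2, ]]; l <- pairs$h_index[idx[2, ]]
    c1 <- (i == k) | (j == l)
    c2 <- if (sequential) (i < k & j > l) | (i > k & j < l) else FALSE
    c3 <- eg[cbind(i + 1L, k + 1L)] & !eh[cbind(j + 1L, l + 1L)]
    conflict <- c1 | c2 | c3
    if (any(conflict))
      edges <- cbind(idx[1, conflict], idx[2, conflict])
  }
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  structure(list(pairs = pairs, edges = edges, sequential = sequential),
            class = "aux_graph")
}

# symmetric logical contact matrix with FALSE diagonal
edge_flag_matrix <- function(g) {
  n <- max(n_sse(g), 1L)
  m <- matrix(FALSE, n, n)
  if (nrow(g$edges) > 0) {
    m[g$edges + 1L] <- TRUE
    m[g$edges[, 2:1, drop = FALSE] + 1L] <- TRUE
  }
  m
}

#' @export
print.aux_graph <- function(x, ...) {
  cat(sprintf("Auxiliary conflict graph: %d candidate-pair vertices, %d edges (%s mode)\n",
              nrow(x$pairs), nrow(x$edges),
              if (x$sequential) "sequential" else "non-sequential"))
  invisible(x)
}

#' Verify a set of candidate pairs as a valid partial alignment
#'
#' Direct restatement of the embedding conditions, computed from G and H
#' without the auxiliary graph: the pair set must be injective in both
#' coordinates, order-preserving when `sequential`, and every contact
#' between matched query SSEs must map onto a host contact.
#'
#' @param pairs_subset data.frame with `g_index`, `h_index`.
#' @param G,H the query and host `mixed_graph`s.
#' @param sequential require order preservation?
#' @return logical.
#' @export
verify_alignment <- function(pairs_subset, G, H, sequential = TRUE) {
  p <- as.data.frame(pairs_subset)
  m <- nrow(p)
  if (m == 0) return(TRUE)
  if (anyDuplicated(p$g_index) || anyDuplicated(p$h_index)) return(FALSE)
  if (m > 1) {
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      if (sequential &&
          sign(p$g_index[a] - p$g_index[b]) !=
          sign(p$h_index[a] - p$h_index[b])) return(FALSE)
      if (has_edge(G, p$g_index[a], p$g_index[b]) &&
          !has_edge(H, p$h_index[a], p$h_index[b])) return(FALSE)
    }
  }
  TRUE
}

#' Trim low-scoring vertices from an auxiliary graph
#'
#' Optional size reduction before enumeration. Either an absolute score
#' floor (`min_score`) or a per-query-SSE keep fraction (`keep_frac`,
#' retaining the top fraction of candidates of each g_index) may be
#' given; the default is no trimming. The induced subgraph is returned.
#'
#' @param X an `aux_graph`.
#' @param min_score drop vertices with score strictly below this value.
#' @param keep_frac fraction in (0, 1]: per g_index, keep the
#'   `ceiling(keep_frac * count)` best-scoring vertices.
#' @return trimmed `aux_graph`.
#' @export
trim_auxiliary_graph <- function(X, min_score = NULL, keep_frac = NULL) {
  n <- nrow(X$pairs)
  keep <- rep(TRUE, n)
  if (!is.null(min_score)) keep <- keep & (X$pairs$score >= min_score)
  if (!is.null(keep_frac)) {
    stopifnot(keep_frac > 0, keep_frac <= 1)
    for (g in unique(X$pairs$g_index)) {
      ix <- which(X$pairs$g_index == g)
      kn <- ceiling(keep_frac * length(ix))
      drop <- ix[order(-X$pairs$score[ix], X$pairs$h_index[ix])][-seq_len(kn)]
      keep[drop] <- FALSE
    }
  }
  if (all(keep)) return(X)
  message("trimming auxiliary graph: ", sum(!keep), " of ", n,
          " vertices removed")
  new_id <- cumsum(keep)
  edges <- X$edges
  if (nrow(edges) > 0) {
    ok <- keep[edges[, 1]] & keep[edges[, 2]]
    edges <- cbind(new_id[edges[ok, 1]], new_id[edges[ok, 2]])
  }
  pairs <- X$pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, edges = edges, sequential = X$sequential),
            class = "aux_graph")
}

#' Write an auxiliary graph as an edge list
#'
#' One `vertex <id> <g_index> <h_index> <score>` line per vertex followed
#' by one `<id1> <id2>` line per conflict edge.
#'
#' @param X an `aux_graph`.
#' @param path output path; if `NULL` the text is returned invisibly.
#' @return the text, invisibly.
#' @export
write_aux_graph <- function(X, path = NULL) {
  lines <- c(
    sprintf("vertex %d %d %d %.6g", seq_len(nrow(X$pairs)),
            X$pairs$g_index, X$pairs$h_index, X$pairs$score),
    if (nrow(X$edges) > 0) sprintf("%d %d", X$edges[, 1], X$edges[, 2])
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}
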
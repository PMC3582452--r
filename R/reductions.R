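#' CLIQUE-to-embedding instance generator
#'
#' Ground-truthed hard instances: given an undirected graph G' on n
#' vertices, build the width-1 embedding instance whose maximum partial
#' embedding size equals the maximum clique size of G'. Both G and H are
#' copies of the vertex set joined by the sequence path; every G vertex
#' may map only to its own copy (L(v_i) = {u_i}); G's contacts form the
#' complete graph and H's contacts are exactly the edges of G'.
#'
#' @param n vertex count of G'.
#' @param edges two-column matrix of 1-based vertex pairs of G'.
#' @param k clique size sought (carried along for convenience).
#' @return list with `inst` (an `embedding_instance`) and `k`.
#' @export
clique_to_embedding <- function(n, edges, k = NULL) {
  dummy_sses <- function() data.frame(
    index = seq_len(n) - 1L, kind = rep("helix", n),
    start_res = 6L * (seq_len(n) - 1L) + 1L,
    end_res = 6L * (seq_len(n) - 1L) + 5L)
  all_pairs <- if (n > 1) t(utils::combn(n, 2)) - 1L else NULL
  G <- mixed_graph(dummy_sses(), all_pairs, length = 6L * n,
                   protein_id = "clique_G")
  h_edges <- if (!is.null(edges) && nrow(matrix(edges, ncol = 2)) > 0)
    matrix(as.integer(edges), ncol = 2) - 1L else NULL
  H <- mixed_graph(dummy_sses(), h_edges, length = 6L * n,
                   protein_id = "clique_H")
  lists <- lapply(seq_len(n) - 1L, function(i) i)
  list(inst = embedding_instance(G, H, lists), k = k)
}

#' Maximum partial embedding by exhaustive search
#'
#' Scans every subset of G's vertices and every choice from the candidate
#' lists, checking the partial-embedding conditions directly: list
#' membership, injectivity, order preservation (unless
#' `sequential = FALSE`) and contact preservation. Exponential; hard
#' guard at 12 G vertices.
#'
#' @param inst an `embedding_instance`.
#' @param sequential require order preservation?
#' @return list with `size` (largest embeddable subset) and `witness`
#'   (data.frame `g_index`, `h_index`, 0-based; empty at size 0).
#' @export
max_embedding_bruteforce <- function(inst, sequential = TRUE) {
  n <- n_sse(inst$G)
  if (n > 12) stop("max_embedding_bruteforce is guarded to |V(G)| <= 12")
  eg <- edge_flag_matrix(inst$G); eh <- edge_flag_matrix(inst$H)
  best_size <- 0L
  best <- data.frame(g_index = integer(0), h_index = integer(0))
  if (n == 0) return(list(size = best_size, witness = best))
  for (s in 0:(2^n - 1)) {
    S <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(S) <= best_size) next
    if (any(vapply(inst$lists[S], length, integer(1)) == 0)) next
    combos <- do.call(expand.grid, inst$lists[S])
    for (ci in seq_len(nrow(combos))) {
      f <- as.integer(unlist(combos[ci, ], use.names = FALSE))
      if (anyDuplicated(f)) next
      ok <- TRUE
      if (length(S) > 1) {
        for (a in 1:(length(S) - 1)) {
          for (b in (a + 1):length(S)) {     # S ascending: a precedes b
            if (sequential && f[a] >= f[b]) { ok <- FALSE; break }
            if (!sequential && f[a] == f[b]) { ok <- FALSE; break }
            if (eg[S[a], S[b]] && !eh[f[a] + 1L, f[b] + 1L]) {
              ok <- FALSE; break
            }
          }
          if (!ok) break
        }
      }
      if (ok) {
        best_size <- length(S)
        best <- data.frame(g_index = S - 1L, h_index = f)
        break
      }
    }
  }
  list(size = best_size, witness = best)
}

#' Maximum clique by exhaustive search
#'
#' Subset-scan oracle for small graphs; hard guard at 16 vertices.
#'
#' @param n vertex count.
#' @param edges two-column matrix of 1-based vertex pairs.
#' @return largest clique size (0 for the empty graph).
#' @export
max_clique_bruteforce <- function(n, edges) {
  if (n > 16) stop("max_clique_bruteforce is guarded to n <= 16")
  if (n == 0) return(0L)
  adj <- matrix(FALSE, n, n)
  if (!is.null(edges) && nrow(matrix(edges, ncol = 2)) > 0) {
    edges <- matrix(as.integer(edges), ncol = 2)
    adj[edges] <- TRUE; adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  best <- 0L
  for (s in 0:(2^n - 1)) {
    S <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(S) <= best) next
    ok <- TRUE
    if (length(S) > 1) {
      for (a in 1:(length(S) - 1)) {
        if (!all(adj[S[a], S[(a + 1):length(S)]])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(S)
  }
  best
}

#' Maximum partial embedding through the independent-set route
#'
#' Converts the candidate lists into pair vertices, builds the auxiliary
#' conflict graph and takes its maximum independent set: the system-level
#' route the comparison pipeline uses, applicable at any map width.
#'
#' @param inst an `embedding_instance`.
#' @param sequential require order preservation?
#' @return list with `size` and `witness` (data.frame `g_index`,
#'   `h_index`).
#' @export
max_embedding_mis <- function(inst, sequential = TRUE) {
  n <- length(inst$lists)
  pairs <- do.call(rbind, lapply(seq_len(n), function(v) {
    if (length(inst$lists[[v]]) == 0) return(NULL)
    data.frame(g_index = v - 1L, h_index = inst$lists[[v]], score = 0)
  }))
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(size = 0L,
                witness = data.frame(g_index = integer(0),
                                     h_index = integer(0))))
  aux <- build_auxiliary_graph(pairs, inst$G, inst$H,
                               sequential = sequential)
  top <- maximum_independent_set(aux)
  w <- aux$pairs[top$members, c("g_index", "h_index"), drop = FALSE]
  w <- w[order(w$g_index), , drop = FALSE]
  rownames(w) <- NULL
  list(size = top$cardinality, witness = w)
}
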
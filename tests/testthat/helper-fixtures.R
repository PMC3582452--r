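# shared fixture builders and independent mini-oracles

# random vertex-weighted conflict graph for MIS tests
random_conflict_graph <- function(n, edge_prob, seed) {
  set.seed(seed)
  edges <- NULL
  if (n > 1) {
    ap <- t(combn(n, 2))
    pick <- runif(nrow(ap)) < edge_prob
    if (any(pick)) edges <- ap[pick, , drop = FALSE]
  }
  conflict_graph(n, edges, scores = round(runif(n), 3))
}

# random candidate-pair instance over two random mixed graphs
random_pair_instance <- function(seed, nG = NULL, nH = NULL, n_pairs = NULL) {
  set.seed(seed)
  nG <- nG %||% sample(3:6, 1)
  nH <- nH %||% sample(nG:(nG + 3), 1)
  G <- random_mixed_graph(nG, edge_prob = 0.4, seed = seed * 2 + 1)
  H <- random_mixed_graph(nH, edge_prob = 0.4, seed = seed * 2 + 2)
  all_pairs <- expand.grid(g_index = 0:(nG - 1), h_index = 0:(nH - 1))
  n_pairs <- n_pairs %||% sample(4:min(10, nrow(all_pairs)), 1)
  sel <- sample(nrow(all_pairs), n_pairs)
  pairs <- all_pairs[sel, ]
  pairs$score <- round(runif(n_pairs), 3)
  rownames(pairs) <- NULL
  list(G = G, H = H, pairs = pairs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# membership test used against the aux-graph edge set
is_independent_in <- function(X, members) {
  if (nrow(X$edges) == 0 || length(members) < 2) return(TRUE)
  !any(X$edges[, 1] %in% members & X$edges[, 2] %in% members)
}

clause_satisfied <- function(cl, a) {
  any(vapply(cl, function(l) if (l > 0) a[l] else !a[-l], logical(1)))
}

# truth-table 2-CNF oracle (exhaustive over assignments)
twosat_truth_table <- function(f) {
  n <- f$n_vars
  if (n == 0) return(TRUE)
  stopifnot(n <= 16)
  for (s in 0:(2^n - 1)) {
    a <- bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L
    if (all(vapply(f$clauses, clause_satisfied, logical(1), a = a)))
      return(TRUE)
  }
  FALSE
}

# brute-force decision for whole-graph embedding: try every list choice
embed_bruteforce_decision <- function(inst) {
  n <- length(inst$lists)
  if (n == 0) return(TRUE)
  if (any(vapply(inst$lists, length, integer(1)) == 0)) return(FALSE)
  combos <- do.call(expand.grid, inst$lists)
  for (ci in seq_len(nrow(combos))) {
    f <- as.integer(unlist(combos[ci, ], use.names = FALSE))
    if (verify_embedding(inst$G, inst$H, f, lists = inst$lists)) return(TRUE)
  }
  FALSE
}

# random width-<=2 embedding instance
random_width2_instance <- function(seed, nG_max = 6) {
  set.seed(seed)
  nG <- sample(2:nG_max, 1)
  nH <- sample(nG:(nG + 3), 1)
  G <- random_mixed_graph(nG, edge_prob = 0.5, seed = seed * 3 + 1)
  H <- random_mixed_graph(nH, edge_prob = 0.5, seed = seed * 3 + 2)
  lists <- lapply(seq_len(nG), function(v)
    sort(sample(0:(nH - 1), sample(1:2, 1))))
  embedding_instance(G, H, lists)
}

# deterministic bank of varied toy proteins (jittered => individual geometry)
toy_bank <- function(n = 20, base_seed = 100) {
  lapply(seq_len(n), function(i) {
    seed <- base_seed + i
    spec <- random_toy_spec(3 + (i %% 4), seed = seed)
    toy_graph(toy_protein(spec, seed = seed, jitter = 0.3,
                          protein_id = sprintf("toy%02d", i)))
  })
}

# straight-chain residue table (rise A per residue along z)
line_residues <- function(n, rise) {
  data.frame(seq_index = 1:n, x = 0, y = 0, z = rise * (0:(n - 1)))
}

sets_identical <- function(a, b) {
  length(a) == length(b) &&
    all(vapply(seq_along(a), function(i)
      identical(a[[i]]$members, b[[i]]$members), logical(1)))
}
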
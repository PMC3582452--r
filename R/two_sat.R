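#' Graph-embedding instance
#'
#' Bundles a query graph G, a host graph H and the per-vertex candidate
#' lists L(v): the v-th element of `lists` holds the 0-based H-SSE indices
#' the v-th G vertex (in path order) may map to. The *map width* is the
#' largest list size; width-2 instances are solvable exactly in polynomial
#' time via 2-CNF satisfiability, wider ones go through the
#' independent-set route.
#'
#' @param G,H `mixed_graph`s.
#' @param lists list of integer vectors, one per G vertex, each a set of
#'   0-based H vertex indices.
#' @return an object of class `embedding_instance`.
#' @export
embedding_instance <- function(G, H, lists) {
  stopifnot(inherits(G, "mixed_graph"), inherits(H, "mixed_graph"),
            length(lists) == n_sse(G))
  for (lv in lists) {
    if (any(lv < 0 | lv >= n_sse(H)))
      stop("candidate list references an H vertex out of range")
  }
  structure(list(G = G, H = H, lists = lapply(lists, as.integer)),
            class = "embedding_instance")
}

#' Map width of an instance
#' @param inst an `embedding_instance`.
#' @return the largest candidate-list size (0 for an empty G).
#' @export
map_width <- function(inst) {
  if (length(inst$lists) == 0) 0L
  else max(vapply(inst$lists, length, integer(1)))
}

#' Reduce a width-2 embedding instance to 2-CNF satisfiability
#'
#' One Boolean variable x(v, v') per allowed image; three clause families:
#' \enumerate{
#'   \item well-definedness: each G vertex takes exactly one image —
#'     `{x(v,a)}` for a singleton list, `{x(v,a), x(v,b)}` and
#'     `{!x(v,a), !x(v,b)}` for a two-element list;
#'   \item injectivity and order: for every v before u on G's path and
#'     images v', u' with u' not strictly after v' on H's path,
#'     `{!x(v,v'), !x(u,u')}`;
#'   \item edge respect: for every contact vu in G and images v', u' not
#'     in contact in H, `{!x(v,v'), !x(u,u')}`.
#' }
#' The instance embeds iff the formula is satisfiable. Any vertex with an
#' empty list makes the instance trivially infeasible and is rejected.
#'
#' @param inst an `embedding_instance` of map width at most 2.
#' @return an object of class `two_cnf`: `n_vars`, `clauses` (list of
#'   signed-variable integer vectors of length 1 or 2) and `vars`
#'   (data.frame mapping variable id to `g` position, 1-based, and `h`
#'   index, 0-based), or `NULL` when some list is empty (instance
#'   rejected).
#' @export
build_formula <- function(inst) {
  w <- map_width(inst)
  if (w > 2) stop("map width exceeds 2; use the independent-set route")
  sizes <- vapply(inst$lists, length, integer(1))
  if (any(sizes == 0)) return(NULL)
  n <- length(inst$lists)
  vars <- do.call(rbind, lapply(seq_len(n), function(v)
    data.frame(g = v, h = inst$lists[[v]])))
  vars <- cbind(id = seq_len(nrow(vars)), vars)
  vid <- function(v, h) vars$id[vars$g == v & vars$h == h]
  clauses <- list()
  add <- function(cl) clauses[[length(clauses) + 1L]] <<- as.integer(cl)
  for (v in seq_len(n)) {
    lv <- inst$lists[[v]]
    if (length(lv) == 1) add(vid(v, lv[1]))
    else {
      a <- vid(v, lv[1]); b <- vid(v, lv[2])
      add(c(a, b)); add(c(-a, -b))
    }
  }
  eh <- edge_flag_matrix(inst$H)
  if (n > 1) {
    for (v in 1:(n - 1)) for (u in (v + 1):n) {
      g_contact <- has_edge(inst$G, v - 1L, u - 1L)
      for (vp in inst$lists[[v]]) for (up in inst$lists[[u]]) {
        if (up <= vp)                       # injectivity + order
          add(c(-vid(v, vp), -vid(u, up)))
        if (g_contact && !eh[vp + 1L, up + 1L])
          add(c(-vid(v, vp), -vid(u, up)))  # edge respect
      }
    }
  }
  structure(list(n_vars = nrow(vars), clauses = clauses, vars = vars),
            class = "two_cnf")
}

#' Solve a 2-CNF formula
#'
#' Classic implication-graph algorithm: each clause (a | b) contributes
#' implications !a -> b and !b -> a; the formula is satisfiable iff no
#' variable shares a strongly connected component with its negation. The
#' returned assignment sets a variable true iff its component comes after
#' its negation's in a topological order of the condensation, which is
#' deterministic.
#'
#' @param f a `two_cnf` (clauses of length 1 or 2 over variables
#'   1..n_vars, negative integers for negated literals).
#' @return logical vector of length `n_vars`, or `NULL` when
#'   unsatisfiable.
#' @export
solve_2sat <- function(f) {
  n <- f$n_vars
  if (n == 0) return(logical(0))
  node <- function(lit) if (lit > 0) lit else n - lit   # !v at n + v
  el <- matrix(integer(0), ncol = 2)
  for (cl in f$clauses) {
    if (length(cl) < 1 || length(cl) > 2) stop("clause must have 1 or 2 literals")
    a <- cl[1]; b <- if (length(cl) == 2) cl[2] else cl[1]
    el <- rbind(el, c(node(-a), node(b)), c(node(-b), node(a)))
  }
  g <- igraph::make_empty_graph(n = 2L * n, directed = TRUE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g, mode = "strong")$membership
  if (any(comp[1:n] == comp[(n + 1):(2 * n)])) return(NULL)
  cond <- igraph::contract(g, comp)
  cond <- igraph::simplify(cond)
  topo <- as.integer(igraph::topo_sort(cond, mode = "out"))
  rank <- integer(length(topo)); rank[topo] <- seq_along(topo)
  rank[comp[1:n]] > rank[comp[(n + 1):(2 * n)]]
}

#' Exact embedding for map width at most 2
#'
#' Builds the 2-CNF formula of [build_formula()], solves it, and decodes
#' the satisfying assignment into a vertex map.
#'
#' @param inst an `embedding_instance` with map width <= 2.
#' @return integer vector f of length |V(G)|: `f[v]` is the 0-based H
#'   index assigned to the v-th G vertex; `NULL` when no valid embedding
#'   exists.
#' @export
embed_width2 <- function(inst) {
  f <- build_formula(inst)
  if (is.null(f)) return(NULL)             # empty list: reject
  if (length(inst$lists) == 0) return(integer(0))
  a <- solve_2sat(f)
  if (is.null(a)) return(NULL)
  sel <- f$vars[a, , drop = FALSE]
  sel <- sel[order(sel$g), , drop = FALSE]
  stopifnot(identical(sel$g, seq_along(inst$lists)))
  as.integer(sel$h)
}

#' Verify a total vertex map as a whole-graph embedding
#'
#' Checks the embedding conditions directly: list membership, injectivity,
#' order preservation along the spanning paths, and contact preservation
#' (every G contact must map to an H contact). Because the arcs of both
#' graphs form spanning paths, the directed-path condition reduces to
#' index-order comparison. `mode = "iff"` (whole-graph embedding) requires
#' the order biconditional; `mode = "forward"` (the partial-embedding
#' variant) only the forward implication — for injective total maps on
#' spanning paths the two coincide.
#'
#' @param G,H `mixed_graph`s.
#' @param f integer vector: `f[v]` = 0-based H index of the v-th G vertex.
#' @param lists optional candidate lists to check membership against.
#' @param mode "iff" or "forward".
#' @return logical.
#' @export
verify_embedding <- function(G, H, f, lists = NULL, mode = c("iff", "forward")) {
  mode <- match.arg(mode)
  n <- n_sse(G)
  if (length(f) != n || anyNA(f)) return(FALSE)
  if (any(f < 0 | f >= n_sse(H))) return(FALSE)
  if (anyDuplicated(f)) return(FALSE)
  if (!is.null(lists)) {
    for (v in seq_len(n)) if (!(f[v] %in% lists[[v]])) return(FALSE)
  }
  if (n > 1) {
    for (v in 1:(n - 1)) for (u in (v + 1):n) {
      # v precedes u on G's path, so the forward condition demands
      # f[v] < f[u]; the reverse implication of "iff" mode then holds
      # automatically for an injective map between two total orders
      if (!(f[v] < f[u])) return(FALSE)
      if (has_edge(G, v - 1L, u - 1L) && !has_edge(H, f[v], f[u]))
        return(FALSE)
    }
  }
  TRUE
}

#' Write a 2-CNF formula in DIMACS CNF format
#'
#' @param f a `two_cnf`.
#' @param path output path; if `NULL` the text is returned invisibly.
#' @return the text, invisibly.
#' @export
write_dimacs <- function(f, path = NULL) {
  lines <- c(sprintf("p cnf %d %d", f$n_vars, length(f$clauses)),
             vapply(f$clauses, function(cl)
               paste(c(cl, 0L), collapse = " "), character(1)))
  if (!is.null(path)) writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}
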
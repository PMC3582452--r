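#' C-alpha distance between two residues
#'
#' @param residues residue data.frame (see [parse_pdb_chain()]).
#' @param p,q 1-based residue numbers (`seq_index` values).
#' @return Euclidean distance in Angstrom.
#' @export
ca_distance <- function(residues, p, q) {
  ip <- match(p, residues$seq_index)
  iq <- match(q, residues$seq_index)
  if (is.na(ip) || is.na(iq))
    stop("residue index out of chain: ", if (is.na(ip)) p else q)
  sqrt((residues$x[ip] - residues$x[iq])^2 +
       (residues$y[ip] - residues$y[iq])^2 +
       (residues$z[ip] - residues$z[iq])^2)
}

#' Distance-pair similarity D
#'
#' `D(d1, d2) = 0.1 - |d1 - d2| / (d1 + d2)`: 0.1 when the two distances
#' are equal, decreasing towards -0.9 as they diverge. The degenerate case
#' d1 = d2 = 0 (two identical zero-length segments) is defined as 0.1.
#'
#' @param d1,d2 non-negative distances (Angstrom).
#' @return similarity in (-0.9, 0.1].
#' @export
d_similarity <- function(d1, d2) {
  if (any(d1 < 0) || any(d2 < 0)) stop("distances must be non-negative")
  s <- d1 + d2
  ifelse(s == 0, 0.1, 0.1 - abs(d1 - d2) / s)
}

# coordinate matrix indexed directly by residue number (NA where absent)
coord_lookup <- function(residues) {
  m <- matrix(NA_real_, nrow = max(residues$seq_index), ncol = 3)
  m[residues$seq_index, ] <- as.matrix(residues[, c("x", "y", "z")])
  m
}

dist_lk <- function(cm, p, q) {
  if (p < 1 || q < 1 || p > nrow(cm) || q > nrow(cm)) return(NA_real_)
  a <- cm[p, ]; b <- cm[q, ]
  if (anyNA(a) || anyNA(b)) return(NA_real_)
  sqrt(sum((a - b)^2))
}

l_ij_lk <- function(cmA, cmB, i, j) {
  # the three local-window distance comparisons; a term counts only when
  # all four of its residues exist in their chains
  terms <- c(
    d_sim_or_na(dist_lk(cmA, i - 2, i + 2), dist_lk(cmB, j - 2, j + 2)),
    d_sim_or_na(dist_lk(cmA, i - 2, i + 1), dist_lk(cmB, j - 2, j + 1)),
    d_sim_or_na(dist_lk(cmA, i - 1, i + 2), dist_lk(cmB, j - 1, j + 2))
  )
  terms <- terms[!is.na(terms)]
  if (length(terms) == 0) 0 else min(terms)
}

d_sim_or_na <- function(d1, d2) {
  if (is.na(d1) || is.na(d2)) NA_real_ else d_similarity(d1, d2)
}

#' Residue-segment similarity L_ij
#'
#' Compares the local backbone geometry around residue `i` of protein A
#' with that around residue `j` of protein B: the minimum of
#' `D` applied to the three distance pairs (i-2,i+2)/(j-2,j+2),
#' (i-2,i+1)/(j-2,j+1) and (i-1,i+2)/(j-1,j+2). Near chain ends the
#' minimum runs over the in-range terms only; a residue pair with no
#' in-range term contributes 0.
#'
#' @param resA,resB residue data.frames of the two chains.
#' @param i,j 1-based residue numbers in A and B.
#' @return similarity value, at most 0.1.
#' @export
l_ij <- function(resA, resB, i, j) {
  l_ij_lk(coord_lookup(resA), coord_lookup(resB), i, j)
}

#' Score one SSE pair
#'
#' The score of an SSE pair is the sum of the residue similarities L_ij
#' over aligned residues. The shorter element (m residues) is slid
#' ungapped along the longer one and the best offset is kept.
#'
#' @param A_sse,B_sse one-row data.frames (or lists) with `kind`,
#'   `start_res`, `end_res`.
#' @param resA,resB residue data.frames of the two chains.
#' @return maximal ungapped sum of L_ij values.
#' @export
sse_pair_score <- function(A_sse, B_sse, resA, resB) {
  if (A_sse$kind != B_sse$kind)
    stop("SSE kind mismatch: ", A_sse$kind, " vs ", B_sse$kind)
  sse_pair_score_lk(A_sse, B_sse, coord_lookup(resA), coord_lookup(resB))
}

sse_pair_score_lk <- function(A_sse, B_sse, cmA, cmB) {
  pa <- A_sse$start_res:A_sse$end_res
  pb <- B_sse$start_res:B_sse$end_res
  swap <- length(pb) < length(pa)
  if (swap) { tmp <- pa; pa <- pb; pb <- tmp }
  m <- length(pa); M <- length(pb)
  best <- -Inf
  for (off in 0:(M - m)) {
    s <- 0
    for (t in seq_len(m)) {
      i <- pa[t]; j <- pb[t + off]
      s <- s + if (swap) l_ij_lk(cmA, cmB, j, i) else l_ij_lk(cmA, cmB, i, j)
    }
    if (s > best) best <- s
  }
  best
}

#' Full SSE-pair score matrix
#'
#' @param G,H `mixed_graph`s with residues attached.
#' @return numeric matrix (rows = G SSEs, cols = H SSEs, both in 0-based
#'   order); `NA` for kind-incompatible pairs.
#' @export
sse_score_matrix <- function(G, H) {
  cmG <- coord_lookup(G$residues); cmH <- coord_lookup(H$residues)
  nG <- n_sse(G); nH <- n_sse(H)
  M <- matrix(NA_real_, nG, nH)
  for (a in seq_len(nG)) for (b in seq_len(nH)) {
    if (G$sses$kind[a] == H$sses$kind[b])
      M[a, b] <- sse_pair_score_lk(G$sses[a, ], H$sses[b, ], cmG, cmH)
  }
  dimnames(M) <- list(G$sses$index, H$sses$index)
  M
}

#' Top-r candidate SSE pairs
#'
#' For every SSE g of the query graph G, the r same-kind SSEs of the host
#' graph H with the highest pair scores (fewer when H has fewer same-kind
#' SSEs; ties broken towards the lower host index). G should be the graph
#' with fewer SSEs.
#'
#' @param G,H `mixed_graph`s with residues.
#' @param r maximum candidates per query SSE (>= 1).
#' @param score_matrix optional precomputed [sse_score_matrix()] output.
#' @return data.frame of candidate pairs: `g_index`, `h_index` (0-based),
#'   `score`, ordered by `g_index` then rank.
#' @export
top_r_candidates <- function(G, H, r = 5, score_matrix = NULL) {
  stopifnot(r >= 1)
  M <- score_matrix %||% sse_score_matrix(G, H)
  out <- vector("list", n_sse(G))
  for (a in seq_len(n_sse(G))) {
    sc <- M[a, ]
    ok <- which(!is.na(sc))
    if (length(ok) == 0) {
      message("SSE ", a - 1L, " of ", G$protein_id,
              " has no same-kind partner in ", H$protein_id)
      next
    }
    o <- ok[order(-sc[ok], ok)]           # score desc, lower h_index wins
    o <- o[seq_len(min(r, length(o)))]
    out[[a]] <- data.frame(g_index = a - 1L, h_index = o - 1L,
                           score = sc[o])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(g_index = integer(0), h_index = integer(0),
                      score = numeric(0))
  rownames(res) <- NULL
  res
}

#' Write an SSE-pair score matrix as TSV
#' @param M matrix from [sse_score_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(M, path) {
  idx <- which(!is.na(M), arr.ind = TRUE)
  df <- data.frame(g_index = as.integer(rownames(M)[idx[, 1]]),
                   h_index = as.integer(colnames(M)[idx[, 2]]),
                   score = M[idx])
  df <- df[order(df$g_index, df$h_index), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
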
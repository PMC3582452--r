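#' Raw alignment score S
#'
#' The sum of SSE-pair scores over the matched pairs of an alignment.
#'
#' @param pairs data.frame with `g_index`, `h_index` (0-based).
#' @param score_matrix matrix from [sse_score_matrix()] (rows = G SSEs,
#'   columns = H SSEs).
#' @return numeric S.
#' @export
alignment_score <- function(pairs, score_matrix) {
  if (nrow(pairs) == 0) return(0)
  v <- score_matrix[cbind(pairs$g_index + 1L, pairs$h_index + 1L)]
  if (anyNA(v)) stop("matched pair missing from the score matrix")
  sum(v)
}

#' Length-normalized score Sn
#'
#' `Sn = S / (lA * lB)` where lA and lB are the residue counts of the two
#' chains; used for cross-protein ranking in database search.
#'
#' @param S raw score.
#' @param lA,lB chain lengths in residues (>= 1).
#' @return numeric Sn.
#' @export
normalized_score <- function(S, lA, lB) {
  if (lA < 1 || lB < 1) stop("chain lengths must be >= 1")
  S / (lA * lB)
}

#' Core coverage of an alignment
#'
#' Matched SSE count divided by the SSE count of the smaller structure;
#' 1.0 means every core of the smaller protein is aligned.
#'
#' @param n_matched number of matched SSE pairs.
#' @param Ac,Bc SSE counts of the two structures.
#' @return fraction in \[0, 1\].
#' @export
core_coverage <- function(n_matched, Ac, Bc) {
  denom <- min(Ac, Bc)
  if (n_matched > denom)
    stop("matched count exceeds the smaller structure's SSE count")
  if (denom == 0) return(0)
  n_matched / denom
}

#' Select the best alignment from enumerated independent sets
#'
#' Every subset of an independent set is itself a valid alignment, so each
#' enumerated set is first reduced to its best-scoring sub-alignment by
#' dropping members with negative pair scores (geometrically dissimilar
#' matches that could only lower S); the reduced sets are then ranked by S,
#' with ties going to the larger set, then to the lexicographically first
#' pair list. S decides here because length normalisation is irrelevant
#' within a single protein pair; Sn is filled in for use in cross-protein
#' ranking. This subset reduction also makes the best S monotone in both
#' K and r.
#'
#' @param topk list from [enumerate_top_k()].
#' @param score_matrix matrix from [sse_score_matrix()].
#' @param aux the `aux_graph` the sets index into.
#' @param G,H the query and host `mixed_graph`s.
#' @return an object of class `epc_alignment`: `matched_pairs`
#'   (data.frame `g_index`, `h_index`, `score`, ordered by `g_index`),
#'   `S`, `Sn`, `core_cov`, `sequential`, plus the two protein ids.
#' @export
best_alignment <- function(topk, score_matrix, aux, G, H) {
  stopifnot(length(topk) > 0)
  reduced <- lapply(topk, function(s)
    s$members[aux$pairs$score[s$members] >= 0])
  S_all <- vapply(reduced, function(m) {
    if (length(m) == 0) 0
    else alignment_score(aux$pairs[m, , drop = FALSE], score_matrix)
  }, numeric(1))
  card <- lengths(reduced)
  key <- vapply(reduced, function(m)
    paste(sprintf("%06d", m), collapse = ","), character(1))
  best <- order(-S_all, -card, key)[1]
  pairs <- aux$pairs[reduced[[best]], , drop = FALSE]
  pairs <- pairs[order(pairs$g_index), , drop = FALSE]
  rownames(pairs) <- NULL
  S <- S_all[best]
  structure(list(
    matched_pairs = pairs,
    S = S,
    Sn = normalized_score(S, G$length, H$length),
    core_cov = core_coverage(nrow(pairs), n_sse(G), n_sse(H)),
    sequential = aux$sequential,
    g_protein = G$protein_id, h_protein = H$protein_id
  ), class = "epc_alignment")
}

#' @export
print.epc_alignment <- function(x, ...) {
  cat(sprintf("SSE alignment %s (G) vs %s (H), %s mode\n",
              x$g_protein, x$h_protein,
              if (x$sequential) "sequential" else "non-sequential"))
  cat(sprintf("  matched SSE pairs: %d   S = %.4g   Sn = %.4g   CORE-COV = %.0f%%\n",
              nrow(x$matched_pairs), x$S, x$Sn, 100 * x$core_cov))
  if (nrow(x$matched_pairs) > 0)
    cat("  pairs:", paste(sprintf("(%d,%d)", x$matched_pairs$g_index,
                                  x$matched_pairs$h_index), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.epc_alignment <- function(object, ...) {
  print(object)
  if (nrow(object$matched_pairs) > 0) {
    cat("  per-pair scores:\n")
    print(object$matched_pairs, row.names = FALSE)
  }
  invisible(object)
}

#' Compare two protein structures
#'
#' Full comparison pipeline: candidate SSE pairs are ranked per query SSE
#' (top `r` by segment score), assembled into an auxiliary conflict graph,
#' its top-`K` maximal independent sets are enumerated, and the set with
#' the best raw score S is returned as the alignment. The structure with
#' fewer SSEs always plays the query role G; reported `g_index`/`h_index`
#' refer to G and H respectively (check `g_protein` for which input that
#' is).
#'
#' @param A,B `mixed_graph`s with residues (see [read_protein()],
#'   [toy_protein()]).
#' @param r candidates per query SSE (default 5).
#' @param K number of enumerated independent sets (default 1000).
#' @param sequential require chain-order preservation (default TRUE);
#'   FALSE permits non-sequential SSE correspondences.
#' @param trim_min_score,trim_keep_frac optional auxiliary-graph trimming
#'   (see [trim_auxiliary_graph()]); off by default.
#' @return an `epc_alignment`.
#' @export
epc_compare <- function(A, B, r = 5, K = 1000, sequential = TRUE,
                        trim_min_score = NULL, trim_keep_frac = NULL) {
  stopifnot(inherits(A, "mixed_graph"), inherits(B, "mixed_graph"))
  if (n_sse(B) < n_sse(A)) { G <- B; H <- A } else { G <- A; H <- B }
  M <- sse_score_matrix(G, H)
  pairs <- top_r_candidates(G, H, r = r, score_matrix = M)
  aux <- build_auxiliary_graph(pairs, G, H, sequential = sequential)
  if (!is.null(trim_min_score) || !is.null(trim_keep_frac))
    aux <- trim_auxiliary_graph(aux, min_score = trim_min_score,
                                keep_frac = trim_keep_frac)
  topk <- enumerate_top_k(aux, K = K)
  best_alignment(topk, M, aux, G, H)
}

#' Rank a database of structures against a query
#'
#' Runs [epc_compare()] of the query against every database entry and
#' ranks by normalized score Sn (ties: core coverage, then id). A failure
#' on one target is logged and the target skipped, never aborting the
#' scan.
#'
#' @param query a `mixed_graph` with residues.
#' @param db list of `mixed_graph`s with residues.
#' @param ... passed to [epc_compare()].
#' @return data.frame `protein_id`, `Sn`, `core_cov`, `S`, `n_matched`,
#'   in rank order.
#' @export
rank_database <- function(query, db, ...) {
  stopifnot(length(db) > 0)
  rows <- lapply(db, function(target) {
    res <- tryCatch(epc_compare(query, target, ...), error = function(e) {
      message("skipping target ", target$protein_id, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) return(NULL)
    data.frame(protein_id = target$protein_id, Sn = res$Sn,
               core_cov = res$core_cov, S = res$S,
               n_matched = nrow(res$matched_pairs))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("every database comparison failed")
  out <- out[order(-out$Sn, -out$core_cov, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an alignment as TSV or JSON
#'
#' TSV: one row per matched SSE pair with both spans and the pair score.
#' JSON: the full alignment record.
#'
#' @param aln an `epc_alignment`.
#' @param path output file.
#' @param G,H the compared `mixed_graph`s (query-role first), used for
#'   span columns in TSV output.
#' @param format "tsv" or "json".
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, G = NULL, H = NULL,
                            format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- unclass(aln)
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    p <- aln$matched_pairs
    df <- data.frame(g_index = p$g_index, h_index = p$h_index,
                     score = p$score)
    if (!is.null(G) && !is.null(H)) {
      gi <- match(p$g_index, G$sses$index)
      hi <- match(p$h_index, H$sses$index)
      df$g_span <- sprintf("%d-%d", G$sses$start_res[gi], G$sses$end_res[gi])
      df$h_span <- sprintf("%d-%d", H$sses$start_res[hi], H$sses$end_res[hi])
      df$kind <- G$sses$kind[gi]
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
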
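test_that("S, Sn and CORE-COV follow their definitions", {
  M <- matrix(c(8.3, 1.0, 2.5, 4.0), 2, 2)
  none <- data.frame(g_index = integer(0), h_index = integer(0))
  expect_equal(alignment_score(none, M), 0)
  one <- data.frame(g_index = 0L, h_index = 0L)
  expect_equal(alignment_score(one, M), 8.3)
  three <- data.frame(g_index = c(0L, 0L, 1L), h_index = c(0L, 1L, 1L))
  expect_equal(alignment_score(three, M), 8.3 + 2.5 + 4.0)
  Mna <- M; Mna[1, 1] <- NA
  expect_error(alignment_score(one, Mna), "missing")

  expect_equal(normalized_score(0, 10, 10), 0)
  expect_equal(normalized_score(10, 10, 10), 0.1)
  expect_equal(normalized_score(3 * 10, 10, 10), 3 * normalized_score(10, 10, 10))
  expect_error(normalized_score(1, 0, 10), ">= 1")

  # a 7-SSE query fully matched inside a 40-SSE target covers 100%
  expect_equal(core_coverage(7, 7, 40), 1.0)
  # the smaller partner can be the host: 4 of min(7, 4) is still 100%
  expect_equal(core_coverage(4, 7, 4), 1.0)
  expect_equal(core_coverage(0, 7, 4), 0)
  expect_error(core_coverage(5, 7, 4), "exceeds")
})

test_that("best_alignment maximizes raw score S, not cardinality", {
  G <- random_mixed_graph(5, 0, seed = 1)
  H <- random_mixed_graph(5, 0, seed = 2)
  # aux graph over 5 diagonal pairs; scores make a 4-set beat the 5-set
  pairs <- data.frame(g_index = 0:4, h_index = 0:4,
                      score = c(1, 1, 1, 0.5, -1.5))
  X <- build_auxiliary_graph(pairs, G, H, TRUE)
  M <- matrix(NA_real_, 5, 5); diag(M) <- pairs$score
  # hand-built candidate sets: full identity (S = 2.0) vs first four (S = 3.5)
  topk <- list(list(members = 1:5, cardinality = 5L, total_score = 2.0),
               list(members = 1:4, cardinality = 4L, total_score = 3.5))
  aln <- best_alignment(topk, M, X, G, H)
  expect_equal(nrow(aln$matched_pairs), 4L)
  expect_equal(aln$S, 3.5)
  expect_equal(aln$core_cov, 4 / 5)
  expect_equal(aln$Sn, 3.5 / (30 * 30))
})

test_that("best alignment equals an exhaustive scan over all maximal sets", {
  for (seed in 60:71) {
    inst <- random_pair_instance(seed, n_pairs = 8)
    X <- build_auxiliary_graph(inst$pairs, inst$G, inst$H, TRUE)
    M <- matrix(NA_real_, n_sse(inst$G), n_sse(inst$H))
    M[cbind(X$pairs$g_index + 1, X$pairs$h_index + 1)] <- X$pairs$score
    all_sets <- brute_force_top_k(X, 10000)     # every maximal set
    got <- best_alignment(enumerate_top_k(X, 10000), M, X, inst$G, inst$H)
    # the best valid alignment supported by a maximal set keeps only its
    # non-negative members (subsets of independent sets are independent)
    best_S <- max(vapply(all_sets, function(s)
      sum(pmax(X$pairs$score[s$members], 0)), numeric(1)))
    expect_equal(got$S, best_S)
  }
})

test_that("self-comparison recovers the identity mapping with full coverage", {
  bank <- toy_bank(6, base_seed = 300)
  for (g in bank) {
    aln <- epc_compare(g, g, r = 3, K = 200)
    expect_equal(aln$core_cov, 1.0)
    expect_equal(aln$matched_pairs$g_index, aln$matched_pairs$h_index)
    expect_equal(nrow(aln$matched_pairs), n_sse(g))
  }
})

test_that("a planted query is found verbatim inside a larger target", {
  for (seed in 1:5) {
    pl <- plant_common_structure(random_toy_spec(3 + seed %% 3, seed = seed),
                                 target_padding = 3, seed = seed)
    gq <- toy_graph(pl$query); gt <- toy_graph(pl$target)
    aln <- epc_compare(gq, gt, r = 5, K = 500)
    expect_equal(aln$core_cov, 1.0)
    expect_equal(aln$matched_pairs$g_index, pl$ground_truth$g_index)
    expect_equal(aln$matched_pairs$h_index, pl$ground_truth$h_index)
  }
})

test_that("non-sequential mode recovers an order-scrambled match", {
  # two strands + helix; the 'permuted' protein has the same three elements
  # in a different chain order but identical spatial layout
  mk <- function(order_ix, id) {
    specs <- list(
      list(kind = "strand", length = 5, origin = c(0, 0, 0), axis = c(0, 0, 1)),
      list(kind = "helix", length = 8, origin = c(5, 0, 0), axis = c(0, 0, 1)),
      list(kind = "strand", length = 6, origin = c(10, 0, 0), axis = c(0, 0, 1)))
    toy_graph(toy_protein(specs[order_ix], protein_id = id))
  }
  A <- mk(1:3, "orig")
  B <- mk(c(3, 2, 1), "scrambled")
  seq_aln <- epc_compare(A, B, r = 3, K = 100, sequential = TRUE)
  non_aln <- epc_compare(A, B, r = 3, K = 100, sequential = FALSE)
  expect_gte(non_aln$S, seq_aln$S)
  # the crossed strand correspondence is reachable only without condition 2
  key <- sprintf("%d:%d", non_aln$matched_pairs$g_index,
                 non_aln$matched_pairs$h_index)
  expect_true(all(c("0:2", "2:0") %in% key))
  if (nrow(seq_aln$matched_pairs) > 1)
    expect_true(all(diff(seq_aln$matched_pairs$h_index) > 0))
})

test_that("database ranking is deterministic and puts the query first", {
  db <- toy_bank(8, base_seed = 500)
  rk <- rank_database(db[[3]], db, r = 3, K = 200)
  expect_equal(rk$protein_id[1], db[[3]]$protein_id)
  expect_equal(rk$core_cov[1], 1.0)
  rk2 <- rank_database(db[[3]], db, r = 3, K = 200)
  expect_identical(rk, rk2)
})

test_that("alignment output formats round-trip the matched pairs", {
  g <- toy_bank(1, base_seed = 700)[[1]]
  aln <- epc_compare(g, g, r = 2, K = 50)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_alignment(aln, tsv, G = g, H = g, format = "tsv")
  back <- read.delim(tsv)
  expect_equal(back$g_index, aln$matched_pairs$g_index)
  expect_equal(back$h_index, aln$matched_pairs$h_index)
  write_alignment(aln, js, format = "json")
  jb <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(jb$S, aln$S)
  expect_equal(jb$core_cov, aln$core_cov)
})
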
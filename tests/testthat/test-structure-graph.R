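pdb_line <- function(serial, resno, x, y, z, chain = "A", elety = " CA ") {
  sprintf("ATOM  %5d %s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, elety, chain, resno, x, y, z)
}

test_that("parse_pdb_chain extracts CA residues in order and applies the skip rules", {
  txt <- c(pdb_line(1, 1, 0, 0, 0), pdb_line(2, 2, 0, 0, 1.5),
           pdb_line(3, 3, 0, 0, 3.0), "END")
  res <- parse_pdb_chain(txt, "A")
  expect_equal(res$seq_index, 1:3)
  expect_equal(res$z, c(0, 1.5, 3.0))

  # residue 2 has only a non-CA atom -> skipped with a warning
  txt2 <- c(pdb_line(1, 1, 0, 0, 0), pdb_line(2, 2, 1, 1, 1, elety = " CB "),
            pdb_line(3, 3, 0, 0, 3.0), "END")
  expect_warning(res2 <- parse_pdb_chain(txt2, "A"), "without a CA")
  expect_equal(res2$seq_index, c(1L, 3L))

  expect_error(parse_pdb_chain(txt, "B"), "chain 'B' not found")
})

test_that("parse_dssp reads classic layout, aligns by residue number, skips breaks", {
  dssp_data <- function(codes, resno = seq_along(codes), chain = "A")
    sprintf("%5d%5d %s A  %s", seq_along(codes), resno, chain, codes)
  hdr <- c("==== Secondary Structure Definition ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  codes <- strsplit("HHHHHHHHHH", "")[[1]]
  out <- parse_dssp(c(hdr, dssp_data(codes)), "A")
  expect_equal(unname(out), codes)
  expect_equal(names(out), as.character(1:10))

  # a '!' chain-break line is excluded
  brk <- "   6    6 A !  "
  lines <- c(hdr, dssp_data(codes[1:5]), brk,
             sprintf("%5d%5d A A  %s", 7:11, 6:10, codes[6:10]))
  out2 <- parse_dssp(lines, "A")
  expect_length(out2, 10)

  # blank and E codes round-trip per residue
  mix <- strsplit("  EEE  HHHH", "")[[1]]
  out3 <- parse_dssp(c(hdr, dssp_data(mix)), "A")
  expect_equal(unname(out3), mix)

  expect_error(parse_dssp(c("no header here", "1 2 3"), "A"), "malformed")
})

test_that("segment_sses applies run minima and 0-based indexing", {
  one <- segment_sses("HHHHH")
  expect_equal(nrow(one), 1L)
  expect_equal(one$kind, "helix")
  expect_equal(one$end_res - one$start_res + 1L, 5L)

  expect_equal(nrow(segment_sses("HHH")), 0L)   # below helix minimum
  expect_equal(nrow(segment_sses("EE")), 0L)    # below strand minimum
  expect_equal(nrow(segment_sses("GGGGIIII")), 0L)  # G/I are loop

  got <- segment_sses("EEEELLHHHHHEEE")
  expect_equal(got$index, 0:2)
  expect_equal(got$kind, c("strand", "helix", "strand"))
  expect_equal(got$start_res, c(1L, 7L, 12L))
  expect_equal(got$end_res, c(4L, 11L, 14L))
})

test_that("segment_sses output matches a regex oracle on random code strings", {
  set.seed(42)
  for (rep in 1:25) {
    codes <- paste(sample(c("H", "E", " ", "T", "G", "B"), 40, TRUE,
                          prob = c(.3, .25, .2, .1, .1, .05)), collapse = "")
    got <- segment_sses(codes)
    # oracle: regex over the code string
    oracle <- function(pattern, kind) {
      m <- gregexpr(pattern, codes)[[1]]
      if (m[1] == -1) return(NULL)
      data.frame(kind = kind, start_res = as.integer(m),
                 end_res = as.integer(m) + attr(m, "match.length") - 1L)
    }
    exp <- rbind(oracle("H{4,}", "helix"), oracle("E{3,}", "strand"))
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      exp <- exp[order(exp$start_res), ]
      expect_equal(got$kind, exp$kind)
      expect_equal(got$start_res, exp$start_res)
      expect_equal(got$end_res, exp$end_res)
      # disjoint sorted spans
      if (nrow(got) > 1)
        expect_true(all(got$start_res[-1] > got$end_res[-nrow(got)]))
    }
  }
})

test_that("contact edges follow the minimum inter-CA distance rule", {
  two_strands <- function(gap) {
    res <- rbind(line_residues(5, 3.5),
                 within(line_residues(5, 3.5), x <- gap))
    res$seq_index <- 1:10
    res
  }
  sses <- data.frame(index = 0:1, kind = "strand",
                     start_res = c(1L, 6L), end_res = c(5L, 10L))
  near <- build_structure_graph(two_strands(4.8), sses)
  expect_equal(nrow(near$edges), 1L)
  far <- build_structure_graph(two_strands(30), sses)
  expect_equal(nrow(far$edges), 0L)

  # three collinear strands at 5 A spacing: {0,1},{1,2} but not {0,2}
  res3 <- rbind(line_residues(4, 3.5),
                within(line_residues(4, 3.5), x <- 5),
                within(line_residues(4, 3.5), x <- 10))
  res3$seq_index <- 1:12
  sses3 <- data.frame(index = 0:2, kind = "strand",
                      start_res = c(1L, 5L, 9L), end_res = c(4L, 8L, 12L))
  g3 <- build_structure_graph(res3, sses3)
  expect_equal(unname(g3$edges), cbind(c(0L, 1L), c(1L, 2L)))
  # brute-force distance audit of the {0,2} gap
  d02 <- min(as.matrix(dist(res3[, c("x", "y", "z")]))[1:4, 9:12])
  expect_gt(d02, 8)
})

test_that("contact graph is invariant under rigid-body motion", {
  tp <- toy_protein(random_toy_spec(4, seed = 5), seed = 5, jitter = 0.2)
  g0 <- build_structure_graph(tp$residues, tp$sses)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- tp$residues
  xyz <- as.matrix(rot[, c("x", "y", "z")]) %*% R
  rot$x <- xyz[, 1] + 11; rot$y <- xyz[, 2] - 3; rot$z <- xyz[, 3] + 40
  g1 <- build_structure_graph(rot, tp$sses)
  expect_equal(g0$edges, g1$edges)
})

test_that("graph exchange format round-trips and rejects bad input", {
  g <- random_mixed_graph(6, edge_prob = 0.5, seed = 9)
  txt <- write_graph_file(g)
  g2 <- read_graph_file(txt)
  expect_equal(g2$sses, g$sses)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$length, g$length)
  expect_equal(g2$protein_id, g$protein_id)

  bad_edge <- c("graph x 18", "sse 0 helix 1 5", "sse 1 helix 7 11",
                "sse 2 strand 13 16", "edge 0 99")
  expect_error(read_graph_file(bad_edge), "out of range")
  dup <- c("graph x 18", "sse 0 helix 1 5", "sse 0 helix 7 11")
  expect_error(read_graph_file(dup), "duplicate")
})

test_that("read_protein runs the full input pipeline on generated text", {
  tp <- toy_protein(list(
    list(kind = "helix", length = 10, origin = c(0, 0, 0), axis = c(0, 0, 1)),
    list(kind = "strand", length = 5, origin = c(6, 0, 0), axis = c(0, 0, 1))))
  g <- read_protein(tp$pdb, tp$dssp)
  expect_equal(n_sse(g), 2L)
  expect_equal(g$sses$kind, c("helix", "strand"))
  expect_equal(g$length, 10 + 3 + 5)
  expect_equal(nrow(g$edges), 1L)   # 6 A apart -> contact
})
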
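# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

unit <- function(v) v / sqrt(sum(v^2))

# orthonormal pair perpendicular to axis a
perp_basis <- function(a) {
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(pracma_cross(a, ref))
  e2 <- pracma_cross(a, e1)
  list(e1 = e1, e2 = e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ideal C-alpha trace of one element: helix = spiral with 1.5 A rise,
# 2.3 A radius, 100 degrees per residue; strand = straight 3.5 A steps
element_trace <- function(kind, length, origin, axis) {
  a <- unit(axis)
  i <- seq_len(length) - 1
  if (kind == "helix") {
    b <- perp_basis(a)
    th <- i * 100 * pi / 180
    t(vapply(seq_along(i), function(k)
      origin + 1.5 * i[k] * a + 2.3 * (cos(th[k]) * b$e1 + sin(th[k]) * b$e2),
      numeric(3)))
  } else {
    t(vapply(seq_along(i), function(k) origin + 3.5 * i[k] * a, numeric(3)))
  }
}

# assemble a chain from per-element coordinate blocks: 3-residue linear
# loops between consecutive elements, 1-based numbering, PDB + DSSP text
assemble_toy <- function(kinds, blocks, protein_id, chain_id = "A") {
  stopifnot(length(kinds) == length(blocks))
  ne <- length(blocks)
  for (a in seq_len(max(ne - 1, 0))) for (b in (a + 1):ne) {
    if (min_pair_dist(blocks[[a]], blocks[[b]]) < 1.5)
      stop("overlapping elements in toy-protein layout")
  }
  coords <- NULL; codes <- character(0)
  starts <- integer(ne); ends <- integer(ne)
  for (e in seq_len(ne)) {
    if (e > 1) {                           # 3-residue connecting loop
      p0 <- blocks[[e - 1]][nrow(blocks[[e - 1]]), ]
      p1 <- blocks[[e]][1, ]
      loop <- t(vapply(1:3, function(t_) p0 + (t_ / 4) * (p1 - p0),
                       numeric(3)))
      coords <- rbind(coords, loop)
      codes <- c(codes, rep(" ", 3))
    }
    starts[e] <- nrow(coords %||% matrix(0, 0, 3)) + 1L
    coords <- rbind(coords, blocks[[e]])
    ends[e] <- nrow(coords)
    codes <- c(codes, rep(if (kinds[e] == "helix") "H" else "E",
                          nrow(blocks[[e]])))
  }
  n <- nrow(coords)
  residues <- data.frame(seq_index = seq_len(n),
                         x = coords[, 1], y = coords[, 2], z = coords[, 3])
  sses <- data.frame(index = seq_len(ne) - 1L, kind = kinds,
                     start_res = starts, end_res = ends)
  pdb <- c(sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), chain_id, seq_len(n), coords[, 1], coords[, 2], coords[, 3]),
    "END")
  dssp <- c(
    "==== Secondary Structure Definition, synthetic idealized trace ====",
    sprintf("HEADER synthetic toy protein %s", protein_id),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    sprintf("%5d%5d %s A  %s", seq_len(n), seq_len(n), chain_id, codes))
  structure(list(pdb = paste(pdb, collapse = "\n"),
                 dssp = paste(dssp, collapse = "\n"),
                 ss = paste(codes, collapse = ""),
                 residues = residues, sses = sses,
                 protein_id = protein_id, chain_id = chain_id),
            class = "toy_protein")
}

#' Generate an idealized toy protein
#'
#' Builds a synthetic chain from a layout of helix/strand elements:
#' helices are ideal C-alpha spirals (1.5 A rise and 100 degrees of turn
#' per residue, 2.3 A radius), strands straight 3.5 A-per-residue traces,
#' with 3-residue linear loops between consecutive elements. Emits
#' matching PDB-format and DSSP-format text, so the whole input pipeline
#' is exercisable without downloads. Optional Gaussian coordinate jitter
#' gives each generated protein an individual geometry, emulating the
#' structural variation real chains have on top of ideal secondary
#' structure; outputs are deterministic per seed.
#'
#' @param spec list of elements, each a list with `kind` ("helix" or
#'   "strand"), `length` (residues, at least the segmentation minimum),
#'   `origin` (3-vector, Angstrom) and `axis` (3-vector direction).
#' @param seed RNG seed (only used when `jitter > 0`).
#' @param jitter standard deviation (Angstrom) of i.i.d. Gaussian noise
#'   added to every coordinate; 0 keeps the ideal trace.
#' @param protein_id,chain_id identifiers used in the emitted records.
#' @return object of class `toy_protein`: `pdb` and `dssp` texts, `ss`
#'   code string, `residues`, `sses`, ids.
#' @export
toy_protein <- function(spec, seed = 1, jitter = 0, protein_id = "toy",
                        chain_id = "A") {
  kinds <- vapply(spec, `[[`, character(1), "kind")
  lens <- vapply(spec, function(e) as.integer(e$length), integer(1))
  if (any(kinds == "helix" & lens < 4) || any(kinds == "strand" & lens < 3))
    stop("element shorter than the segmentation minimum")
  blocks <- lapply(spec, function(e)
    element_trace(e$kind, e$length, e$origin, e$axis))
  if (jitter > 0) {
    blocks <- with_seed(seed, lapply(blocks, function(b)
      b + matrix(stats::rnorm(base::length(b), sd = jitter), nrow(b), 3)))
  }
  assemble_toy(kinds, blocks, protein_id, chain_id)
}

#' Build the mixed graph of a toy protein
#'
#' Runs the generated PDB/DSSP text through the standard input pipeline.
#'
#' @param tp a `toy_protein`.
#' @param contact_threshold contact cutoff in Angstrom.
#' @return a `mixed_graph` with residues.
#' @export
toy_graph <- function(tp, contact_threshold = 8) {
  read_protein(tp$pdb, tp$dssp, chain_id = tp$chain_id,
               contact_threshold = contact_threshold,
               protein_id = tp$protein_id)
}

#' Random element layout for a toy protein
#'
#' Draws a plausible chain layout: random helix/strand kinds, helix
#' lengths 6-14 and strand lengths 4-8 residues, elements running in
#' parallel and spaced 4-12 Angstrom apart laterally so that some pairs
#' fall under the 8 A contact cutoff and others do not, yielding varied
#' contact graphs.
#'
#' @param n_sse number of elements.
#' @param seed RNG seed.
#' @return a layout list usable as the `spec` of [toy_protein()].
#' @export
random_toy_spec <- function(n_sse, seed = 1) {
  with_seed(seed, {
    x <- 0
    prev_kind <- "strand"
    lapply(seq_len(n_sse), function(e) {
      kind <- sample(c("helix", "strand"), 1)
      len <- if (kind == "helix") sample(6:14, 1) else sample(4:8, 1)
      # axis-to-axis gap, widened by the 2.3 A helix radius of each
      # neighbour so element traces never collide
      gap <- stats::runif(1, 4, 12) + 2.3 * (kind == "helix") +
        2.3 * (prev_kind == "helix")
      prev_kind <<- kind
      x <<- x + gap
      list(kind = kind, length = len,
           origin = c(x, stats::runif(1, -2, 2), 0), axis = c(0, 0, 1))
    })
  })
}

#' Random mixed graph (no coordinates)
#'
#' n SSE vertices with Bernoulli kinds, the implicit sequence path, and
#' independent Bernoulli(edge_prob) contacts; synthetic residue spans.
#' Deterministic per seed.
#'
#' @param n vertex count.
#' @param edge_prob contact probability per vertex pair.
#' @param kind_prob probability an element is a helix.
#' @param seed RNG seed.
#' @return a `mixed_graph` without residues.
#' @export
random_mixed_graph <- function(n, edge_prob = 0.3, kind_prob = 0.5,
                               seed = 1) {
  with_seed(seed, {
    sses <- data.frame(
      index = seq_len(n) - 1L,
      kind = ifelse(stats::runif(n) < kind_prob, "helix", "strand"),
      start_res = 6L * (seq_len(n) - 1L) + 1L,
      end_res = 6L * (seq_len(n) - 1L) + 5L)
    edges <- NULL
    if (n > 1) {
      all_p <- t(utils::combn(n, 2)) - 1L
      pick <- stats::runif(nrow(all_p)) < edge_prob
      if (any(pick)) edges <- all_p[pick, , drop = FALSE]
    }
    mixed_graph(sses[seq_len(n), , drop = FALSE], edges, length = 6L * n,
                protein_id = sprintf("rnd%d_%d", n, seed))
  })
}

#' Plant a query structure inside a larger synthetic target
#'
#' The target contains the query's elements verbatim (identical
#' coordinates, hence identical local geometry) with extra padding
#' elements inserted before and after along the chain. Padding elements
#' are placed far from the core (and from each other) so they create no
#' spurious contacts. The ground-truth SSE correspondence is recorded.
#'
#' @param query_spec element layout of the query (see [toy_protein()]).
#' @param target_padding total number of padding elements (split between
#'   the N- and C-terminal sides).
#' @param seed RNG seed (jitter draws and padding layout).
#' @param jitter coordinate jitter (Angstrom) applied to the query trace;
#'   the planted copy keeps the jittered coordinates.
#' @return list with `query` and `target` (`toy_protein`s) and
#'   `ground_truth` (data.frame `g_index` in the query, `h_index` in the
#'   target).
#' @export
plant_common_structure <- function(query_spec, target_padding = 3,
                                   seed = 1, jitter = 0.3) {
  query <- toy_protein(query_spec, seed = seed, jitter = jitter,
                       protein_id = "query")
  nq <- length(query_spec)
  core_blocks <- lapply(seq_len(nq), function(e) {
    sel <- query$residues$seq_index >= query$sses$start_res[e] &
           query$residues$seq_index <= query$sses$end_res[e]
    as.matrix(query$residues[sel, c("x", "y", "z")])
  })
  n_before <- ceiling(target_padding / 2)
  n_after <- target_padding - n_before
  ymax <- max(vapply(core_blocks, function(b) max(b[, 2]), numeric(1)))
  pads <- with_seed(seed + 1L, lapply(seq_len(target_padding), function(p) {
    kind <- sample(c("helix", "strand"), 1)
    len <- if (kind == "helix") sample(6:12, 1) else sample(4:7, 1)
    # remote placement: >= 40 A above the core, 25 A apart pairwise
    origin <- c(25 * p, ymax + 40 + 25 * p, 0)
    list(kind = kind,
         block = element_trace(kind, len, origin, c(0, 0, 1)))
  }))
  kinds <- c(vapply(pads[seq_len(n_before)], `[[`, character(1), "kind"),
             query$sses$kind,
             if (n_after > 0)
               vapply(pads[n_before + seq_len(n_after)], `[[`,
                      character(1), "kind"))
  blocks <- c(lapply(pads[seq_len(n_before)], `[[`, "block"),
              core_blocks,
              if (n_after > 0)
                lapply(pads[n_before + seq_len(n_after)], `[[`, "block"))
  if (target_padding == 0) { kinds <- query$sses$kind; blocks <- core_blocks }
  target <- assemble_toy(kinds, blocks, protein_id = "target")
  list(query = query, target = target,
       ground_truth = data.frame(g_index = seq_len(nq) - 1L,
                                 h_index = n_before + seq_len(nq) - 1L))
}
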
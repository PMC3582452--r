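#' Extract C-alpha residues of one chain from PDB text
#'
#' Reads ATOM records through \pkg{bio3d} and keeps one C-alpha per residue
#' of the requested chain, in file order. Alternate locations resolve to the
#' first occurrence. Residues lacking a CA atom are skipped with a warning.
#'
#' @param pdb_text PDB-format text (single string or character vector of
#'   lines); ignored when `path` is given.
#' @param chain_id one-letter chain identifier.
#' @param path optional path to a PDB file.
#' @return data.frame with columns `seq_index` (the PDB residue number,
#'   1-based within the chain) and `x`, `y`, `z` (Angstrom).
#' @export
parse_pdb_chain <- function(pdb_text = NULL, chain_id = "A", path = NULL) {
  if (is.null(path)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(pdb_text, path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0)
    stop("chain '", chain_id, "' not found in PDB input")
  resnos <- unique(at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]  # altloc: first wins
  missing <- setdiff(resnos, ca$resno)
  if (length(missing) > 0)
    warning(length(missing), " residue(s) without a CA atom skipped (chain ",
            chain_id, "): ", paste(utils::head(missing, 5), collapse = ", "))
  data.frame(seq_index = as.integer(ca$resno),
             x = ca$x, y = ca$y, z = ca$z)
}

#' Parse per-residue secondary structure codes from classic DSSP output
#'
#' Expects the classic fixed-column DSSP layout: data lines follow the
#' header line beginning with `"  #  RESIDUE"`; residue number occupies
#' columns 6-10, chain column 12, and the one-letter structure code
#' column 17 (blank = loop). Chain-break lines (`!` in the amino-acid
#' column) are skipped.
#'
#' @param dssp_text DSSP-format text (string or lines); ignored when
#'   `path` is given.
#' @param chain_id chain to extract.
#' @param path optional path to a DSSP file.
#' @return named character vector: one code per residue, names are residue
#'   numbers. Codes are the DSSP dialect H,G,I,E,B,T,S and " ".
#' @export
parse_dssp <- function(dssp_text = NULL, chain_id = "A", path = NULL) {
  if (!is.null(path)) dssp_text <- readLines(path)
  if (length(dssp_text) == 1 && grepl("\n", dssp_text, fixed = TRUE))
    dssp_text <- strsplit(dssp_text, "\n", fixed = TRUE)[[1]]
  hdr <- grep("^  #  RESIDUE", dssp_text)
  if (length(hdr) == 0)
    stop("malformed DSSP input: '  #  RESIDUE' header line not found")
  lines <- dssp_text[seq(hdr[1] + 1L, length.out = length(dssp_text) - hdr[1])]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(character(0), character(0)))
  aa <- substr(lines, 14, 14)
  keep <- aa != "!"                      # chain breaks carry no residue
  lines <- lines[keep]
  ch <- substr(lines, 12, 12)
  lines <- lines[ch == chain_id]
  if (length(lines) == 0)
    stop("chain '", chain_id, "' not found in DSSP input")
  resno <- as.integer(substr(lines, 6, 10))
  code <- substr(lines, 17, 17)
  stats::setNames(code, resno)
}

#' Segment secondary-structure codes into SSE spans
#'
#' Maximal runs of `H` of length >= 4 become helices and maximal runs of
#' `E` of length >= 3 become strands; every other code (including the
#' 3-10/pi helix codes G and I and the isolated bridge code B) is loop.
#' Runs are broken at gaps in the residue numbering.
#'
#' @param ss_codes character vector of one-letter codes (or one string),
#'   as returned by [parse_dssp()]. Names, when present, are residue
#'   numbers; otherwise residues are numbered 1..length.
#' @param min_helix,min_strand minimum run lengths.
#' @return data.frame with columns `index` (0-based), `kind`, `start_res`,
#'   `end_res`; zero rows when nothing qualifies.
#' @export
segment_sses <- function(ss_codes, min_helix = 4L, min_strand = 3L) {
  if (length(ss_codes) == 1 && is.null(names(ss_codes)) &&
      nchar(ss_codes) > 1)
    ss_codes <- strsplit(ss_codes, "")[[1]]
  resno <- if (!is.null(names(ss_codes))) as.integer(names(ss_codes))
           else seq_along(ss_codes)
  empty <- data.frame(index = integer(0), kind = character(0),
                      start_res = integer(0), end_res = integer(0))
  if (length(ss_codes) == 0) return(empty)
  # split runs on code change or numbering gap
  brk <- cumsum(c(1L, (ss_codes[-1] != ss_codes[-length(ss_codes)]) |
                       (diff(resno) != 1L)))
  runs <- lapply(split(seq_along(ss_codes), brk), function(ix) {
    list(code = ss_codes[ix[1]], start = resno[ix[1]],
         end = resno[ix[length(ix)]], len = length(ix))
  })
  keep <- vapply(runs, function(r) {
    (r$code == "H" && r$len >= min_helix) ||
    (r$code == "E" && r$len >= min_strand)
  }, logical(1))
  runs <- runs[keep]
  if (length(runs) == 0) return(empty)
  data.frame(
    index = seq_along(runs) - 1L,
    kind = vapply(runs, function(r) if (r$code == "H") "helix" else "strand",
                  character(1)),
    start_res = vapply(runs, function(r) as.integer(r$start), integer(1)),
    end_res = vapply(runs, function(r) as.integer(r$end), integer(1))
  )
}

#' Build the mixed structure graph of a chain
#'
#' Places an undirected contact edge between two SSEs when the minimum
#' distance between any of their C-alpha atoms is at most
#' `contact_threshold` (8 Angstrom by default, a standard CA-contact
#' convention).
#'
#' @param residues data.frame from [parse_pdb_chain()].
#' @param sses data.frame from [segment_sses()].
#' @param contact_threshold contact cutoff in Angstrom.
#' @param protein_id identifier for the resulting graph.
#' @return a `mixed_graph` carrying the residues.
#' @export
build_structure_graph <- function(residues, sses, contact_threshold = 8,
                                  protein_id = "protein") {
  n <- nrow(sses)
  coords <- lapply(seq_len(n), function(k) {
    sel <- residues$seq_index >= sses$start_res[k] &
           residues$seq_index <= sses$end_res[k]
    as.matrix(residues[sel, c("x", "y", "z"), drop = FALSE])
  })
  if (any(vapply(coords, nrow, integer(1)) == 0))
    stop("an SSE span references no residue present in the chain")
  edges <- NULL
  if (n > 1) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (min_pair_dist(coords[[a]], coords[[b]]) <= contact_threshold)
        edges <- rbind(edges, c(a - 1L, b - 1L))
    }
  }
  mixed_graph(sses, edges, length = nrow(residues),
              protein_id = protein_id, residues = residues)
}

# minimum Euclidean distance between two point sets (rows)
min_pair_dist <- function(a, b) {
  cross <- a %*% t(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * cross
  sqrt(max(0, min(d2)))
}

#' Load a protein ready for comparison
#'
#' Convenience wrapper running the preprocessing chain: PDB parse, DSSP
#' parse, SSE segmentation and contact-graph construction.
#'
#' @param pdb,dssp texts or (with `pdb_path`/`dssp_path`) file paths.
#' @param chain_id chain to extract from both inputs.
#' @param contact_threshold contact cutoff in Angstrom.
#' @param protein_id identifier; defaults to the chain id.
#' @param pdb_path,dssp_path optional file paths.
#' @return a `mixed_graph` with residues attached.
#' @export
read_protein <- function(pdb = NULL, dssp = NULL, chain_id = "A",
                         contact_threshold = 8, protein_id = NULL,
                         pdb_path = NULL, dssp_path = NULL) {
  residues <- parse_pdb_chain(pdb, chain_id, path = pdb_path)
  codes <- parse_dssp(dssp, chain_id, path = dssp_path)
  codes <- codes[names(codes) %in% as.character(residues$seq_index)]
  sses <- segment_sses(codes)
  build_structure_graph(residues, sses, contact_threshold,
                        protein_id = protein_id %||% chain_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
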
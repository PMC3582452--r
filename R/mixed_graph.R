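#' Mixed structure graph of a protein
#'
#' A protein chain is represented as a triple (V, A, E): the vertices V are
#' its secondary structure elements (SSEs, helices and strands) in N-to-C
#' order, the arcs A form the directed path 0 -> 1 -> ... -> n-1 implied by
#' that order (so they are stored implicitly), and the undirected edges E
#' record spatial contacts between SSEs.
#'
#' @param sses data.frame with columns `index` (0-based, consecutive),
#'   `kind` ("helix" or "strand"), `start_res`, `end_res` (1-based,
#'   inclusive residue span).
#' @param edges integer matrix with two columns of 0-based SSE indices, one
#'   undirected contact per row. May have zero rows.
#' @param length total residue count of the chain (used by score
#'   normalisation).
#' @param protein_id identifier string.
#' @param residues optional data.frame of C-alpha coordinates with columns
#'   `seq_index`, `x`, `y`, `z`; required for residue-level scoring.
#' @return an object of class `mixed_graph`.
#' @export
mixed_graph <- function(sses, edges, length, protein_id = "protein",
                        residues = NULL) {
  sses <- as.data.frame(sses)
  stopifnot(all(c("index", "kind", "start_res", "end_res") %in% names(sses)))
  n <- nrow(sses)
  if (n > 0) {
    if (!identical(as.integer(sses$index), 0:(n - 1L)))
      stop("SSE indices must be 0..n-1 in order")
    if (!all(sses$kind %in% c("helix", "strand")))
      stop("SSE kind must be 'helix' or 'strand'")
    if (any(sses$start_res > sses$end_res))
      stop("SSE span has start_res > end_res")
    if (n > 1 && any(diff(sses$start_res) <= 0))
      stop("SSE spans must be sorted by start_res")
    if (n > 1 && any(sses$start_res[-1] <= sses$end_res[-n]))
      stop("SSE spans must be pairwise disjoint")
  }
  edges <- normalize_edges(edges, n)
  structure(
    list(protein_id = as.character(protein_id), sses = sses, edges = edges,
         length = as.integer(length), residues = residues),
    class = "mixed_graph"
  )
}

# canonical form: two-column integer matrix, i < j, unique rows, sorted
normalize_edges <- function(edges, n) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      (!is.matrix(edges) && length(edges) == 0)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (any(edges < 0) || any(edges >= n))
    stop("edge endpoint out of range 0..n-1")
  if (any(edges[, 1] == edges[, 2])) stop("self-loop edge not allowed")
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges
}

#' Number of SSE vertices of a mixed graph
#' @param g a `mixed_graph`.
#' @return integer vertex count.
#' @export
n_sse <- function(g) nrow(g$sses)

#' Test whether two SSEs are in contact
#' @param g a `mixed_graph`.
#' @param i,j 0-based SSE indices.
#' @return logical.
#' @export
has_edge <- function(g, i, j) {
  if (i == j) return(FALSE)
  a <- min(i, j); b <- max(i, j)
  any(g$edges[, 1] == a & g$edges[, 2] == b)
}

#' @export
print.mixed_graph <- function(x, ...) {
  cat(sprintf("Mixed structure graph '%s': %d SSEs (%d helix, %d strand), %d contacts, %d residues\n",
              x$protein_id, n_sse(x), sum(x$sses$kind == "helix"),
              sum(x$sses$kind == "strand"), nrow(x$edges), x$length))
  if (n_sse(x) > 0) {
    lab <- sprintf("%d:%s[%d-%d]", x$sses$index,
                   ifelse(x$sses$kind == "helix", "H", "E"),
                   x$sses$start_res, x$sses$end_res)
    cat(" ", paste(lab, collapse = " -> "), "\n")
  }
  if (nrow(x$edges) > 0)
    cat("  contacts:", paste(sprintf("{%d,%d}", x$edges[, 1], x$edges[, 2]),
                             collapse = " "), "\n")
  invisible(x)
}

#' Write a mixed graph in the plain-text exchange format
#'
#' Line-based format: a `graph <id> <length>` header, one
#' `sse <index> <kind> <start> <end>` line per vertex, then one
#' `edge <i> <j>` line per undirected contact. Blank lines and lines
#' starting with `#` are ignored on read. Coordinates are not carried.
#'
#' @param g a `mixed_graph`.
#' @param path file path; if `NULL` the text is returned invisibly.
#' @return the text, invisibly.
#' @export
write_graph_file <- function(g, path = NULL) {
  lines <- c(
    sprintf("graph %s %d", g$protein_id, g$length),
    sprintf("sse %d %s %d %d", g$sses$index, g$sses$kind,
            g$sses$start_res, g$sses$end_res),
    if (nrow(g$edges) > 0) sprintf("edge %d %d", g$edges[, 1], g$edges[, 2])
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}

#' Read a mixed graph from the plain-text exchange format
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines; ignored when `path` is given.
#' @param path optional file path to read instead of `text`.
#' @return a `mixed_graph` (without residue coordinates).
#' @seealso [write_graph_file()]
#' @export
read_graph_file <- function(text = NULL, path = NULL) {
  if (!is.null(path)) text <- readLines(path)
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- trimws(text)
  text <- text[nzchar(text) & !startsWith(text, "#")]
  if (length(text) == 0 || !startsWith(text[1], "graph "))
    stop("exchange format: missing 'graph <id> <length>' header line")
  hdr <- strsplit(text[1], "\\s+")[[1]]
  if (length(hdr) != 3) stop("exchange format: malformed header")
  id <- hdr[2]; len <- as.integer(hdr[3])
  sse_lines <- text[startsWith(text, "sse ")]
  edge_lines <- text[startsWith(text, "edge ")]
  other <- setdiff(text[-1], c(sse_lines, edge_lines))
  if (length(other) > 0)
    stop("exchange format: unrecognized line: ", other[1])
  sses <- if (length(sse_lines) > 0) {
    f <- do.call(rbind, strsplit(sse_lines, "\\s+"))
    if (ncol(f) != 5) stop("exchange format: malformed sse line")
    idx <- as.integer(f[, 2])
    if (anyDuplicated(idx)) stop("exchange format: duplicate SSE index")
    o <- order(idx)
    data.frame(index = idx[o], kind = f[o, 3],
               start_res = as.integer(f[o, 4]),
               end_res = as.integer(f[o, 5]))
  } else {
    data.frame(index = integer(0), kind = character(0),
               start_res = integer(0), end_res = integer(0))
  }
  edges <- if (length(edge_lines) > 0) {
    f <- do.call(rbind, strsplit(edge_lines, "\\s+"))
    if (ncol(f) != 3) stop("exchange format: malformed edge line")
    cbind(as.integer(f[, 2]), as.integer(f[, 3]))
  } else NULL
  mixed_graph(sses, edges, len, protein_id = id)
}

#' Serialize a mixed graph as JSON
#' @param g a `mixed_graph`.
#' @param path optional output file.
#' @return JSON string, invisibly.
#' @export
graph_to_json <- function(g, path = NULL) {
  obj <- list(protein_id = g$protein_id, length = g$length,
              sses = g$sses,
              edges = if (nrow(g$edges)) unname(as.data.frame(g$edges)) else list())
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}
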
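#' Build a de Bruijn graph from reads
#'
#' Constructs the k-th order de Bruijn graph of a read set: vertices are the
#' k-mers observed in the reads and edges are the observed (k+1)-mers.  Reads
#' are split at ambiguous bases (anything outside A/C/G/T), so no k-mer spans
#' an N.  By default the read set is augmented with the reverse complement of
#' every read before k-mer extraction; the graph remains a plain directed
#' graph (no canonical-k-mer collapsing), which keeps the path-length dynamic
#' program unchanged.
#'
#' @param reads Character vector of DNA sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @param k Integer k-mer size, between 2 and 31 (a (k+1)-mer must fit in a
#'   64-bit word).
#' @param min_abundance Minimum number of observations for a k-mer or
#'   (k+1)-mer to enter the graph.  Use 2 (or more) to suppress singleton
#'   k-mers from sequencing errors; use 1 for error-free data.
#' @param rc_augment Augment the reads with their reverse complements before
#'   extraction (default `TRUE`; turn off only for controlled experiments).
#' @return An object of class `kmer_graph` backed by a compiled hash-table
#'   representation.
#' @examples
#' g <- kmer_graph("ACGTA", k = 3, rc_augment = FALSE)
#' graph_vertices(g)
#' graph_edges(g)
#' @export
kmer_graph <- function(reads, k, min_abundance = 1L, rc_augment = TRUE) {
  reads <- as.character(reads)
  ptr <- .dbg_build(reads, as.integer(k), as.integer(min_abundance),
                    isTRUE(rc_augment))
  structure(
    list(ptr = ptr, k = as.integer(k),
         min_abundance = as.integer(min_abundance),
         rc_augment = isTRUE(rc_augment)),
    class = "kmer_graph"
  )
}

#' @method print kmer_graph
#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf(
    "de Bruijn graph (k = %d): %s k-mer vertices, %s edges%s\n",
    x$k, format(.dbg_vcount(x$ptr), big.mark = ","),
    format(.dbg_ecount(x$ptr), big.mark = ","),
    if (x$rc_augment) " (reverse-complement augmented)" else ""))
  invisible(x)
}

#' Graph accessors
#'
#' `graph_vertices()` returns all k-mer vertices (lexicographically sorted),
#' `graph_edges()` the edge list as a two-column data frame, and
#' `graph_abundance()` the observation counts of given k-mers (0 if absent
#' from the graph, `NA` for malformed k-mers).  Listing vertices or edges
#' materializes the whole graph as strings and is intended for small graphs.
#'
#' @param graph A `kmer_graph`.
#' @param kmers Character vector of k-mers to look up.
#' @return Character vector, data frame, or integer vector respectively.
#' @export
graph_vertices <- function(graph) {
  stopifnot(inherits(graph, "kmer_graph"))
  .dbg_vertices(graph$ptr)
}

#' @rdname graph_vertices
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "kmer_graph"))
  .dbg_edges(graph$ptr)
}

#' @rdname graph_vertices
#' @export
graph_abundance <- function(graph, kmers) {
  stopifnot(inherits(graph, "kmer_graph"))
  .dbg_abundance(graph$ptr, as.character(kmers))
}

#' @rdname graph_vertices
#' @export
graph_has_vertex <- function(graph, kmers) {
  stopifnot(inherits(graph, "kmer_graph"))
  .dbg_has_vertex(graph$ptr, as.character(kmers))
}

#' Number of vertices / edges of a `kmer_graph`
#' @param graph A `kmer_graph`.
#' @return A numeric count.
#' @export
graph_vcount <- function(graph) .dbg_vcount(graph$ptr)

#' @rdname graph_vcount
#' @export
graph_ecount <- function(graph) .dbg_ecount(graph$ptr)

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
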
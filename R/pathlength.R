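#' Count walks of every exact cost (path-length dynamic program)
#'
#' Fills the table `M[v][i]` = number of walks from `s` to vertex `v` of cost
#' exactly `i`, for `i` in `0..cost_hi`, with unit edge costs.  This is the
#' counting dynamic program behind gap filling: a breadth-first sweep over
#' cost layers where `M[v][i]` accumulates `M[w][i - 1]` over all predecessors
#' `w` of `v`.  Counts are walks (vertices may repeat) and saturate at
#' `2^31 - 1`; traceback only requires positivity.
#'
#' This reference implementation operates on an explicit edge list and is
#' meant for inspection and small graphs; [fill_gap()] uses a compiled
#' equivalent specialized to k-mer graphs.
#'
#' @param x A `kmer_graph`, or a data frame with character columns `from` and
#'   `to` giving directed edges.
#' @param s,t Source and target vertex labels; both must be vertices of the
#'   graph.
#' @param cost_hi Largest cost layer to compute (`d` of the accepted interval).
#' @return An object of class `path_count_table`: list with `counts` (a
#'   `|V| x (cost_hi+1)` numeric matrix, columns = costs `0..cost_hi`),
#'   `vertices`, `edges`, `s`, `t`, `cost_hi`.
#' @examples
#' edges <- data.frame(from = c("ACG", "CGT", "GTA"),
#'                     to   = c("CGT", "GTA", "TAC"))
#' tab <- count_paths(edges, "ACG", "TAC", cost_hi = 3)
#' tab$counts["TAC", ]
#' @export
count_paths <- function(x, s, t, cost_hi) {
  edges <- as_edgelist(x)
  cost_hi <- as.integer(cost_hi)
  stopifnot(cost_hi >= 0)
  verts <- sort(unique(c(edges$from, edges$to, s, t)))
  if (!s %in% verts || !t %in% verts)
    stop("s and t must be vertices of the graph")
  nv <- length(verts)
  from_i <- match(edges$from, verts)
  to_i <- match(edges$to, verts)

  M <- matrix(0, nrow = nv, ncol = cost_hi + 1L,
              dimnames = list(verts, 0:cost_hi))
  M[match(s, verts), 1L] <- 1
  if (cost_hi >= 1L && nrow(edges) > 0L) {
    for (i in seq_len(cost_hi)) {
      contrib <- M[from_i, i]
      if (!any(contrib > 0)) break
      agg <- rowsum(contrib, group = to_i)
      M[as.integer(rownames(agg)), i + 1L] <- pmin(agg[, 1L], 2^31 - 1)
    }
  }
  structure(list(counts = M, vertices = verts, edges = edges,
                 s = s, t = t, cost_hi = cost_hi),
            class = "path_count_table")
}

as_edgelist <- function(x) {
  if (inherits(x, "kmer_graph")) return(graph_edges(x))
  if (is.data.frame(x) && all(c("from", "to") %in% names(x)))
    return(data.frame(from = as.character(x$from), to = as.character(x$to),
                      stringsAsFactors = FALSE))
  stop("x must be a kmer_graph or a data frame with columns 'from' and 'to'")
}

#' Trace back a witness path from the count table
#'
#' Returns any path `s .. t` whose cost lies in `[cost_lo..cost_hi]` given a
#' computed [count_paths()] table, or `NULL` when no such path exists
#' (failure is a normal return, not an error).  Determinism: among valid
#' costs the one closest to the interval midpoint is taken (ties broken
#' toward the smaller cost), and at each backward step the lexicographically
#' smallest predecessor label with a positive count is chosen.
#'
#' @param table A `path_count_table` from [count_paths()].
#' @param cost_lo,cost_hi Accepted cost interval; `cost_hi` defaults to the
#'   table's last layer and must not exceed it.
#' @return Character vector of vertex labels, or `NULL` on failure.
#' @export
traceback_path <- function(table, cost_lo, cost_hi = table$cost_hi) {
  stopifnot(inherits(table, "path_count_table"))
  cost_lo <- max(0L, as.integer(cost_lo))
  cost_hi <- as.integer(cost_hi)
  if (cost_hi > table$cost_hi)
    stop("cost_hi exceeds the computed table")
  if (cost_lo > cost_hi) return(NULL)
  M <- table$counts
  trow <- M[table$t, , drop = TRUE]
  cand <- which(trow[(cost_lo:cost_hi) + 1L] > 0) + cost_lo - 1L
  if (length(cand) == 0L) return(NULL)
  mid <- (cost_lo + cost_hi) / 2
  cost <- cand[order(abs(cand - mid), cand)][1L]

  edges <- table$edges
  path <- character(cost + 1L)
  path[cost + 1L] <- table$t
  cur <- table$t
  if (cost >= 1L) {
    for (i in cost:1) {
      preds <- unique(edges$from[edges$to == cur])
      preds <- preds[M[preds, i] > 0]
      if (length(preds) == 0L)
        stop("internal error: traceback lost the path")
      cur <- sort(preds)[1L]
      path[i] <- cur
    }
  }
  path
}

#' Spell the sequence of a k-mer path
#'
#' Concatenates the labels of a path of k-mers overlapping by `k - 1`: the
#' result has length `k + (n - 1)` for an n-vertex path and starts with the
#' first vertex.
#'
#' @param path Character vector of k-mers (consecutive overlap `k - 1`).
#' @param k The k-mer size.
#' @return A single DNA string.
#' @examples
#' spell_path(c("ACG", "CGT", "GTA"), k = 3)  # "ACGTA"
#' @export
spell_path <- function(path, k) {
  stopifnot(length(path) >= 1L, all(nchar(path) == k))
  if (length(path) > 1L) {
    ok <- substr(path[-length(path)], 2L, k) ==
      substr(path[-1L], 1L, k - 1L)
    if (!all(ok)) stop("malformed path: consecutive k-mers must overlap by k - 1")
  }
  paste0(path[1L], paste(substr(path[-1L], k, k), collapse = ""))
}
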
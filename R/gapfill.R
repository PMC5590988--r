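#' Accepted length interval around an estimated gap length
#'
#' Builds the interval `[est_length - slack, est_length + slack]`, clamped
#' below at 0, whose midpoint is the estimated gap length whenever no
#' clamping occurs.
#'
#' @param est_length Estimated length of the missing sequence (nt).
#' @param slack Half-width of the accepted interval (nt).
#' @return Integer vector `c(lo, hi)`.
#' @examples
#' gap_interval(100, 10)  # 90 110
#' gap_interval(5, 10)    # 0 15
#' @export
gap_interval <- function(est_length, slack) {
  stopifnot(est_length >= 0, slack >= 0)
  c(lo = max(0L, as.integer(est_length) - as.integer(slack)),
    hi = as.integer(est_length) + as.integer(slack))
}

#' Default length slack for a gap of estimated length d
#'
#' `max(10, ceiling(0.1 * d))` nucleotides: tolerates the noise of
#' insert-size-based length estimates while keeping the dynamic program
#' small.
#'
#' @param est_length Estimated gap length (nt).
#' @return Integer slack.
#' @export
default_slack <- function(est_length) {
  max(10L, as.integer(ceiling(0.1 * est_length)))
}

#' Fill a gap between two flanking sequences
#'
#' Searches the de Bruijn graph for a path connecting the flanks whose
#' spelled sequence, restricted to the bases strictly between the original
#' flank boundaries, has length within `est_length` plus/minus `slack`.
#' Because flank edges may carry errors, the source and target k-mers are
#' also tried at offsets up to `fuzz` bases *into* each flank: offset `a`
#' uses the left-flank k-mer ending `a` bases before the boundary, offset
#' `b` the right-flank k-mer starting `b` bases after it.  A path of cost
#' `c` then spells `c - k - a - b` in-between bases (the k-mer overlap is
#' `k - 1`, so cost equals spelled extension).  The first success in the
#' deterministic order (`a + b` ascending, then `a` ascending) is returned;
#' among valid costs the one closest to the midpoint of the accepted cost
#' interval is taken, and traceback prefers the lexicographically smallest
#' predecessor k-mer.  Offset-skipped flank bases are restored from the
#' path, not from the (possibly erroneous) flank, but only bases strictly
#' between the original boundaries are reported as the insertion.
#'
#' @param graph A [kmer_graph()] built with the same `k` used to cut the
#'   flank k-mers.
#' @param left_flank,right_flank Flanking sequences; each must be at least
#'   `k + fuzz` long.
#' @param est_length Estimated length `d` of the missing sequence (nt).
#' @param slack Half-width of the accepted length interval; defaults to
#'   [default_slack()].
#' @param fuzz Maximum offset searched into each flank (default 10 nt).
#' @param max_cost Hard cap on dynamic-program layers; defaults to
#'   `est_length + slack + k + 2 * fuzz` (the largest accepted cost).
#' @return A list of class `gap_fill`: `found` (logical), `insertion` (the
#'   filled sequence, `NA` on failure), `spelled` (the full path sequence,
#'   source k-mer through target k-mer), `left_offset`, `right_offset`,
#'   `cost`, and `n_paths` (number of accepted-cost walks at the chosen
#'   offsets, saturated at `2^31 - 1`; 1 means the fill is unique).
#' @export
fill_gap <- function(graph, left_flank, right_flank, est_length,
                     slack = NULL, fuzz = 10L, max_cost = NULL) {
  stopifnot(inherits(graph, "kmer_graph"))
  if (is.null(slack)) slack <- default_slack(est_length)
  if (is.null(max_cost))
    max_cost <- as.integer(est_length) + as.integer(slack) + graph$k +
      2L * as.integer(fuzz)
  res <- .dbg_fill_gap(graph$ptr, as.character(left_flank),
                       as.character(right_flank), as.integer(est_length),
                       as.integer(slack), as.integer(fuzz),
                       as.integer(max_cost))
  res$est_length <- as.integer(est_length)
  res$slack <- as.integer(slack)
  res$fuzz <- as.integer(fuzz)
  class(res) <- "gap_fill"
  res
}

#' @method print gap_fill
#' @export
print.gap_fill <- function(x, ...) {
  if (isTRUE(x$found)) {
    cat(sprintf(
      "gap filled: %d nt (estimate %d +/- %d), offsets (%d, %d), %s path(s)\n",
      nchar(x$insertion), x$est_length, x$slack,
      x$left_offset, x$right_offset, format(x$n_paths)))
  } else {
    cat(sprintf("gap not filled (estimate %d +/- %d)\n",
                x$est_length, x$slack))
  }
  invisible(x)
}
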
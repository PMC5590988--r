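#' Levenshtein edit distance
#'
#' Minimum number of substitutions, insertions and deletions transforming
#' one sequence into the other (computed with [utils::adist()]).
#'
#' @param a,b Strings.
#' @return Integer edit distance.
#' @examples
#' edit_distance("kitten", "sitting")  # 3
#' @export
edit_distance <- function(a, b) {
  as.integer(adist(a, b)[1L, 1L])
}

#' Normalized edit-distance score of a genotyped insertion
#'
#' `score = ed(output, correct) / |correct|`: 0 for an output exactly equal
#' to the true insertion; 1 when the insertion was not genotyped (scored as
#' an empty output, so `ed = |correct|`) or was genotyped at the correct
#' length with entirely wrong content.  The denominator is always the true
#' sequence's length, so the score is not symmetric in its arguments, and it
#' can exceed 1 when the output is longer than the truth.
#'
#' @param output Called insertion sequence (`""` or `NA` when not genotyped).
#' @param correct True insertion sequence (must be non-empty).
#' @return A list of class `score_report`: `edit_distance`, `score`,
#'   `truth_length`.
#' @export
insertion_score <- function(output, correct) {
  if (is.na(correct) || nchar(correct) == 0L)
    stop("invalid truth: the correct sequence must be non-empty")
  if (is.na(output)) output <- ""
  ed <- edit_distance(output, correct)
  structure(list(edit_distance = ed,
                 score = ed / nchar(correct),
                 truth_length = nchar(correct)),
            class = "score_report")
}

#' Mean score by insertion-length bin
#'
#' Summarizes genotyping quality by true insertion length: per bin, the
#' mean normalized edit-distance score (ungenotyped calls scored as 1 via
#' an empty output) and the number of genotyped insertions.
#'
#' @param truth Character vector of true insertion sequences.
#' @param output Character vector of called sequences (`NA` or `""` for
#'   ungenotyped), parallel to `truth`.
#' @param bins Numeric break points for [cut()] on the truth lengths
#'   (default: 100 nt bins up to the maximum length).
#' @return Data frame with `bin`, `n`, `n_genotyped`, `mean_score`.
#' @export
summarize_by_length <- function(truth, output, bins = NULL) {
  stopifnot(length(truth) == length(output))
  len <- nchar(truth)
  if (is.null(bins))
    bins <- seq(0, 100 * ceiling(max(len) / 100), by = 100)
  scores <- vapply(seq_along(truth), function(i)
    insertion_score(output[i], truth[i])$score, 0)
  genotyped <- !is.na(output) & nchar(output) > 0L
  bin <- cut(len, bins, include.lowest = TRUE)
  out <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    n_genotyped = as.integer(tapply(genotyped, bin, sum, default = 0L)),
    mean_score = as.numeric(tapply(scores, bin, mean, default = NA_real_)),
    stringsAsFactors = FALSE)
  out[out$n > 0L, , drop = FALSE]
}

#' GapFiller-style baseline read filter
#'
#' Evaluation baseline: selects the unmapped reads from pairs whose mapped
#' mate aligns within a maximum distance of the gap.  The default maximum
#' distance is the upper insert-size bound `mu + z sigma`.  Only the mate's
#' start coordinate is used (the mate interval is allowed to begin up to one
#' read length before the distance window).
#'
#' @inheritParams filter_reads
#' @param max_distance Maximum distance (nt) of the mate alignment from the
#'   gap; default `model$max_insert`.
#' @return A `filter_result` (see [filter_reads()]).
#' @export
filter_reads_gapfiller <- function(alignments, gap, model,
                                   max_distance = NULL) {
  if (is.null(max_distance)) max_distance <- model$max_insert
  s <- gap[1]; e <- gap[2]
  l <- model$read_length
  mapped <- alignments$mapped %in% TRUE
  mate_ok <- alignments$mate_mapped %in% TRUE & !is.na(alignments$mate_start)
  near <- mate_ok & alignments$mate_start >= s - max_distance - l &
    alignments$mate_start <= e + max_distance
  sel <- which(!mapped & near)
  ids <- unique(alignments$read_id[sel])
  region_len <- (e - s) + 2 * l
  structure(
    list(selected_ids = ids, selected_idx = sel,
         realized_coverage = if (region_len > 0)
           length(sel) * l / region_len else NA_real_,
         fallback_fired = FALSE, n_skipped_mate_info = 0L,
         gap = gap, region = c(s - l, e + l)),
    class = "filter_result")
}
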
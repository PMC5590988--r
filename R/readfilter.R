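#' Paired-end insert-size model
#'
#' Holds the read length and the Normal insert-size distribution
#' (mean `mu`, standard deviation `sigma`; insert size is the inner mate
#' distance, so a fragment spans `insert + 2 * read_length`), together
#' with the derived min/max insert bounds at the given
#' two-sided confidence level: `P(|X - mu| >= z sigma) <= 1 - confidence`
#' gives bounds `mu +/- z sigma` with `z = 1.96` at 95%.
#'
#' @param read_length Read length (nt).
#' @param mean_insert Mean insert size `mu` (nt).
#' @param sd_insert Standard deviation `sigma` of the insert size (nt).
#' @param confidence Two-sided confidence level for the bounds (default 0.95).
#' @return An object of class `insert_size_model` with fields `read_length`,
#'   `mean_insert`, `sd_insert`, `confidence`, `z`, `min_insert`,
#'   `max_insert`.
#' @examples
#' m <- insert_size_model(100, 1500, 150)
#' insert_size_bounds(m)  # 1206 1794
#' @export
insert_size_model <- function(read_length, mean_insert, sd_insert,
                              confidence = 0.95) {
  stopifnot(read_length > 0, sd_insert >= 0,
            confidence > 0, confidence < 1)
  z <- qnorm(1 - (1 - confidence) / 2)
  lo <- floor(mean_insert - z * sd_insert)
  hi <- ceiling(mean_insert + z * sd_insert)
  if (lo < 0) {
    warning("minimum insert size below 0; clamped")
    lo <- 0
  }
  structure(
    list(read_length = as.integer(read_length),
         mean_insert = mean_insert, sd_insert = sd_insert,
         confidence = confidence, z = z,
         min_insert = as.integer(lo), max_insert = as.integer(hi)),
    class = "insert_size_model")
}

#' @rdname insert_size_model
#' @param model An `insert_size_model`.
#' @export
insert_size_bounds <- function(model) {
  stopifnot(inherits(model, "insert_size_model"))
  c(min = model$min_insert, max = model$max_insert)
}

#' Mate regions for a gap
#'
#' For a gap `[s..e]` and an insert-size model, the regions where a read
#' must start for its mate to fall in the gap:
#' `S_left = [s - (max + 2l) .. e - (min + l)]` and
#' `S_right = [s + (min + l) .. e + (max + l)]`, with `l` the read length
#' and min/max the insert-size bounds.  Coordinates are clamped below at 0;
#' an interval inverted after clamping is empty.
#'
#' @param gap Numeric `c(s, e)`, 0-based interval of the gap.
#' @param model An [insert_size_model()].
#' @return List with integer intervals `left` and `right` (`c(lo, hi)`;
#'   `hi < lo` marks an empty region).
#' @export
mate_regions <- function(gap, model) {
  stopifnot(length(gap) == 2L, gap[1] <= gap[2],
            inherits(model, "insert_size_model"))
  s <- gap[1]; e <- gap[2]
  l <- model$read_length
  mn <- model$min_insert; mx <- model$max_insert
  # clamp lower bounds at 0; an upper bound left negative (or below the
  # clamped lower bound) marks an empty region
  left <- c(lo = max(0, s - (mx + 2 * l)), hi = e - (mn + l))
  right <- c(lo = max(0, s + (mn + l)), hi = e + (mx + l))
  list(left = stats::setNames(as.integer(round(left)), c("lo", "hi")),
       right = stats::setNames(as.integer(round(right)), c("lo", "hi")))
}

in_region <- function(x, region) {
  region[2] >= region[1] & x >= region[1] & x <= region[2]
}

#' Select the reads likely to cover a gap
#'
#' Implements the insert-size read-filtering scheme: a read is selected if
#' (i) it is mapped and its alignment interval overlaps the gap by at least
#' one base, or (ii) it is unmapped but its mapped mate starts inside one of
#' the [mate_regions()] (mate rescue).  Pairs with both ends unmapped are
#' only reachable through [apply_unmapped_fallback()].  Orientation is
#' ignored; only the mate's start coordinate is used.
#'
#' The realized fold coverage of the selection is
#' `n_selected * read_length / region_length` with the region taken as the
#' gap extended by one read length on each side (reads partially overlapping
#' the gap still contribute).
#'
#' @param alignments Data frame with one row per read: columns `read_id`,
#'   `mapped` (logical), `start`, `end` (0-based half-open, `NA` when
#'   unmapped), `mate_mapped` (logical), `mate_start`.  Rows with missing
#'   mate information are skipped for mate rescue (a count is reported).
#' @param gap Numeric `c(s, e)`, 0-based gap interval.
#' @param model An [insert_size_model()].
#' @return An object of class `filter_result`: `selected_ids`,
#'   `selected_idx` (row indices into `alignments`), `realized_coverage`
#'   (pre-fallback fold coverage over the extended region),
#'   `fallback_fired` (`FALSE` here), `n_skipped_mate_info`, `gap`, `region`.
#' @export
filter_reads <- function(alignments, gap, model) {
  stopifnot(is.data.frame(alignments),
            all(c("read_id", "mapped", "start", "end",
                  "mate_mapped", "mate_start") %in% names(alignments)))
  s <- gap[1]; e <- gap[2]
  l <- model$read_length

  mapped <- alignments$mapped %in% TRUE
  overlap <- mapped & !is.na(alignments$start) & !is.na(alignments$end) &
    alignments$start < e & alignments$end > s

  regions <- mate_regions(gap, model)
  mate_ok <- alignments$mate_mapped %in% TRUE & !is.na(alignments$mate_start)
  skipped <- sum(!mapped & is.na(alignments$mate_mapped))
  rescue <- !mapped & mate_ok &
    (in_region(alignments$mate_start, regions$left) |
       in_region(alignments$mate_start, regions$right))

  sel <- which(overlap | rescue)
  ids <- unique(alignments$read_id[sel])
  region_len <- (e - s) + 2 * l
  cov <- if (region_len > 0) length(sel) * l / region_len else NA_real_
  structure(
    list(selected_ids = ids, selected_idx = sel,
         realized_coverage = cov, fallback_fired = FALSE,
         n_skipped_mate_info = skipped,
         gap = gap, region = c(s - l, e + l)),
    class = "filter_result")
}

#' Add all unmapped reads when filtered coverage is too low
#'
#' When the realized fold coverage of the filtered set falls below
#' `threshold`, the filter is likely missing unmapped reads from the
#' insertion, so all unmapped reads are unioned into the selection.  The
#' threshold should be close to but smaller than the library coverage
#' (e.g. 25 for 30x data).  `realized_coverage` keeps the pre-fallback
#' value that was compared against the threshold.
#'
#' @param result A [filter_reads()] result.
#' @param unmapped_ids Read identifiers of all unmapped reads.
#' @param threshold Fold-coverage threshold (`>= 0`; 0 never fires).
#' @param unmapped_idx Optional row indices matching `unmapped_ids`.
#' @return The updated `filter_result` with `fallback_fired` set accordingly.
#' @export
apply_unmapped_fallback <- function(result, unmapped_ids, threshold,
                                    unmapped_idx = NULL) {
  stopifnot(inherits(result, "filter_result"), threshold >= 0)
  if (!is.na(result$realized_coverage) &&
      result$realized_coverage < threshold) {
    result$selected_ids <- unique(c(result$selected_ids, unmapped_ids))
    if (!is.null(unmapped_idx))
      result$selected_idx <- sort(unique(c(result$selected_idx, unmapped_idx)))
    result$fallback_fired <- TRUE
  }
  result
}

#' Precision and recall of a read selection
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)` of the
#' selected read set against a truth set.  An empty denominator yields `NA`
#' (undefined), not 0.
#'
#' @param selected,truth Character vectors of read identifiers (subsets of
#'   `universe`).
#' @param universe All read identifiers under consideration.
#' @return Named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(selected, truth, universe) {
  selected <- unique(selected); truth <- unique(truth)
  stopifnot(all(selected %in% universe), all(truth %in% universe))
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
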
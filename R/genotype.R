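#' Pipeline parameters for insertion genotyping
#'
#' Central tunables of the genotyping pipeline.  `k` defaults to 31 (the
#' largest k-mer fitting the packed representation, standard for 100 bp
#' reads).  The unmapped-read coverage threshold follows the guidance that
#' it should be close to but smaller than the library coverage: when
#' `coverage` is supplied the default is `floor(0.85 * coverage)` (10 at
#' 15x would be a stricter choice; 25 at 30x, 45 at 50x agree with this
#' rule), otherwise 25.
#'
#' @param k K-mer size (2..31).
#' @param min_abundance Minimum k-mer abundance for graph construction
#'   (2 suppresses singleton error k-mers; use 1 for error-free data).
#' @param slack Half-width of the accepted insertion-length interval;
#'   `NULL` means [default_slack()] per site.
#' @param fuzz Maximum flank offset searched (nt).
#' @param flank_window Length of reference sequence cut on each side of the
#'   breakpoint for the fuzz search; `NULL` means `2 * read_length` (or 200).
#' @param coverage Expected fold coverage of the read set, used only to
#'   derive `threshold` when that is `NULL`.
#' @param threshold Fold-coverage threshold for the unmapped-read fallback.
#' @param max_cost Cap on dynamic-program layers; `NULL` for the
#'   [fill_gap()] default.
#' @return A list of class `run_params`.
#' @export
run_params <- function(k = 31L, min_abundance = 2L, slack = NULL,
                       fuzz = 10L, flank_window = NULL, coverage = NULL,
                       threshold = NULL, max_cost = NULL) {
  if (is.null(threshold))
    threshold <- if (!is.null(coverage)) floor(0.85 * coverage) else 25
  structure(list(k = as.integer(k), min_abundance = as.integer(min_abundance),
                 slack = slack, fuzz = as.integer(fuzz),
                 flank_window = flank_window, coverage = coverage,
                 threshold = threshold, max_cost = max_cost),
            class = "run_params")
}

#' Insertion sites table
#'
#' Validates and normalizes a table of insertion sites.  The breakpoint `p`
#' is 0-based: the insertion lies between reference bases `p - 1` and `p`
#' (half-open slice notation `R[p-k..p]` / `R[p..p+k]` for the flanking
#' k-mers).  File readers convert from the 1-based VCF convention.
#'
#' @param chrom Reference sequence names.
#' @param breakpoint 0-based breakpoint positions.
#' @param est_length Estimated insertion lengths (nt).
#' @param id Site labels (defaults to `ins1`, `ins2`, ...).
#' @return A data frame of class `insertion_sites`.
#' @export
insertion_sites <- function(chrom, breakpoint, est_length,
                            id = sprintf("ins%d", seq_along(breakpoint))) {
  stopifnot(length(chrom) == length(breakpoint),
            length(est_length) == length(breakpoint),
            all(est_length >= 0), all(breakpoint >= 0))
  out <- data.frame(chrom = as.character(chrom),
                    breakpoint = as.integer(breakpoint),
                    est_length = as.integer(est_length),
                    id = as.character(id),
                    stringsAsFactors = FALSE)
  class(out) <- c("insertion_sites", "data.frame")
  out
}

#' Extract the flanking k-mers of a breakpoint
#'
#' Returns `s = R[p-k..p]` (the k bases ending at the breakpoint) and
#' `t = R[p..p+k]` (the k bases starting at it), 0-based half-open.
#'
#' @param reference Reference sequence (single string).
#' @param p 0-based breakpoint, with `k <= p <= nchar(reference) - k`.
#' @param k K-mer size.
#' @return Named character vector `c(s = ..., t = ...)`.
#' @examples
#' extract_flanks("ACGTACGTAC", p = 5, k = 3)  # s = "GTA", t = "CGT"
#' @export
extract_flanks <- function(reference, p, k) {
  n <- nchar(reference)
  if (p < k || p > n - k)
    stop("breakpoint too close to contig end")
  s <- substr(reference, p - k + 1L, p)
  t <- substr(reference, p + 1L, p + k)
  if (grepl("[^ACGTacgt]", s) || grepl("[^ACGTacgt]", t))
    stop("ambiguous flank: N within the flanking k-mers")
  c(s = s, t = t)
}

# Project a reference coordinate into the gapped coordinate system where a
# gap of length d occupies [p, p + d): positions at or beyond the breakpoint
# shift right by d.  Exclusive end coordinates shift only when strictly
# beyond the breakpoint (a read ending at p abuts the gap, not overlaps it).
gapped_coord <- function(x, p, d, exclusive = FALSE) {
  if (exclusive) x + d * (x > p) else x + d * (x >= p)
}

#' Genotype one insertion site
#'
#' Cuts flank windows around the breakpoint, restricts the read set with the
#' insert-size filter (when alignments are supplied), builds a site-local
#' de Bruijn graph, and fills the gap.  Filtering works in the gapped
#' coordinate system in which the insertion occupies `[p, p + d)`:
#' alignment coordinates at or beyond the breakpoint are shifted by `d`,
#' matching the view of a reference with a gap of the estimated length
#' inserted at the breakpoint.
#'
#' @param site One-row [insertion_sites()] data frame (or a list with
#'   `breakpoint`, `est_length`, `id`).
#' @param reference Reference sequence string.
#' @param reads Character vector of read sequences, parallel to the rows of
#'   `alignments` when those are given.
#' @param alignments Data frame as in [filter_reads()], or `NULL` to build
#'   the graph from all reads.
#' @param model An [insert_size_model()]; required with `alignments`.
#' @param params A [run_params()] list.
#' @param graph Optional prebuilt global [kmer_graph()] (used when
#'   `alignments` is `NULL`; avoids rebuilding across sites).
#' @return A list of class `genotype_call`: `site`, `status`
#'   (`"filled"`/`"not_filled"`), `insertion`, `fill` (the [fill_gap()]
#'   result), and `filter` (a [filter_reads()] summary or `NULL`).
#' @export
genotype_site <- function(site, reference, reads, alignments = NULL,
                          model = NULL, params = run_params(),
                          graph = NULL) {
  p <- as.integer(site$breakpoint)
  d <- as.integer(site$est_length)
  k <- params$k
  n <- nchar(reference)
  if (p < k || p > n - k) stop("breakpoint too close to contig end")

  w <- params$flank_window
  if (is.null(w)) w <- if (!is.null(model)) 2L * model$read_length else 200L
  wl <- min(w, p)
  wr <- min(w, n - p)
  fuzz <- min(params$fuzz, wl - k, wr - k)
  if (fuzz < 0L) stop("breakpoint too close to contig end for the flank window")
  left_flank <- substr(reference, p - wl + 1L, p)
  right_flank <- substr(reference, p + 1L, p + wr)

  filt <- NULL
  if (!is.null(alignments)) {
    stopifnot(!is.null(model), length(reads) == nrow(alignments))
    gapped <- alignments
    gapped$start <- gapped_coord(alignments$start, p, d)
    gapped$end <- gapped_coord(alignments$end, p, d, exclusive = TRUE)
    gapped$mate_start <- gapped_coord(alignments$mate_start, p, d)
    filt <- filter_reads(gapped, gap = c(p, p + d), model = model)
    unmapped_idx <- which(!(alignments$mapped %in% TRUE))
    filt <- apply_unmapped_fallback(
      filt, alignments$read_id[unmapped_idx], params$threshold,
      unmapped_idx = unmapped_idx)
    site_reads <- reads[filt$selected_idx]
    g <- tryCatch(
      kmer_graph(site_reads, k, min_abundance = params$min_abundance),
      error = function(e) NULL)
  } else {
    g <- if (!is.null(graph)) graph
         else kmer_graph(reads, k, min_abundance = params$min_abundance)
  }

  fill <- if (is.null(g)) NULL else
    fill_gap(g, left_flank, right_flank, est_length = d,
             slack = params$slack, fuzz = fuzz, max_cost = params$max_cost)
  filled <- !is.null(fill) && isTRUE(fill$found)
  structure(
    list(site = site,
         status = if (filled) "filled" else "not_filled",
         insertion = if (filled) fill$insertion else NA_character_,
         fill = fill, filter = filt),
    class = "genotype_call")
}

#' Genotype a list of insertion sites
#'
#' Runs [genotype_site()] for every site and assembles a per-site report.
#' Sites closer together than twice the flank window interact (their flank
#' windows overlap); they are still processed independently, with a
#' warning.  Without alignments a single global graph over all reads is
#' built once and shared.
#'
#' @inheritParams genotype_site
#' @param sites An [insertion_sites()] data frame.
#' @return A data frame of class `genotype_calls` with one row per site:
#'   `id`, `chrom`, `breakpoint`, `est_length`, `status`, `insertion`,
#'   `length`, `n_paths`, `left_offset`, `right_offset`, `coverage`
#'   (pre-fallback realized coverage), `fallback`, `n_reads_used`.  The
#'   individual call objects are attached as attribute `"calls"`.
#' @export
genotype_all <- function(sites, reference, reads, alignments = NULL,
                         model = NULL, params = run_params()) {
  stopifnot(is.data.frame(sites))
  n <- nrow(sites)
  w <- params$flank_window
  if (is.null(w)) w <- if (!is.null(model)) 2L * model$read_length else 200L
  if (n > 1L) {
    bp <- sort(sites$breakpoint)
    if (any(diff(bp) < 2L * w))
      warning("sites closer than twice the flank window; processed independently")
  }
  graph <- NULL
  if (is.null(alignments) && n > 0L)
    graph <- kmer_graph(reads, params$k, min_abundance = params$min_abundance)

  calls <- vector("list", n)
  for (i in seq_len(n)) {
    calls[[i]] <- genotype_site(sites[i, ], reference, reads,
                                alignments = alignments, model = model,
                                params = params, graph = graph)
  }
  report <- data.frame(
    id = sites$id,
    chrom = sites$chrom,
    breakpoint = sites$breakpoint,
    est_length = sites$est_length,
    status = vapply(calls, `[[`, "", "status"),
    insertion = vapply(calls, `[[`, "", "insertion"),
    stringsAsFactors = FALSE)
  report$length <- ifelse(is.na(report$insertion), NA_integer_,
                          nchar(report$insertion))
  report$n_paths <- vapply(calls, function(x)
    if (is.null(x$fill)) 0 else x$fill$n_paths, 0)
  report$left_offset <- vapply(calls, function(x)
    if (is.null(x$fill)) NA_integer_ else x$fill$left_offset, 0L)
  report$right_offset <- vapply(calls, function(x)
    if (is.null(x$fill)) NA_integer_ else x$fill$right_offset, 0L)
  report$coverage <- vapply(calls, function(x)
    if (is.null(x$filter)) NA_real_ else x$filter$realized_coverage, 0)
  report$fallback <- vapply(calls, function(x)
    if (is.null(x$filter)) NA else x$filter$fallback_fired, NA)
  report$n_reads_used <- vapply(calls, function(x)
    if (is.null(x$filter)) length(reads) else length(x$filter$selected_idx),
    0L)
  attr(report, "calls") <- calls
  class(report) <- c("genotype_calls", "data.frame")
  report
}

#' Splice filled insertions into the reference (donor reconstruction)
#'
#' Inserts every filled call's sequence at its breakpoint, producing the
#' inferred donor sequence.  Sites with `status != "filled"` are skipped.
#'
#' @param reference Reference sequence string.
#' @param calls A [genotype_all()] report (or any data frame with
#'   `breakpoint`, `status`, `insertion`).
#' @return A single donor sequence string.
#' @export
splice_insertions <- function(reference, calls) {
  keep <- calls$status == "filled" & !is.na(calls$insertion)
  bp <- calls$breakpoint[keep]
  ins <- calls$insertion[keep]
  o <- order(bp)
  bp <- bp[o]; ins <- ins[o]
  pieces <- character(2L * length(bp) + 1L)
  prev <- 0L
  for (j in seq_along(bp)) {
    pieces[2L * j - 1L] <- substr(reference, prev + 1L, bp[j])
    pieces[2L * j] <- ins[j]
    prev <- bp[j]
  }
  pieces[2L * length(bp) + 1L] <- substr(reference, prev + 1L,
                                         nchar(reference))
  paste(pieces, collapse = "")
}
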
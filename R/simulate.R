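#' Simulation configuration
#'
#' Bundles the parameters of the synthetic insertion-genotyping experiment:
#' a uniform-random reference, `n_insertions` planted random insertions with
#' lengths uniform in `length_range`, and error-free (by default) paired-end
#' reads of fixed length at the given fold coverage with insert sizes
#' (inner mate distance; the fragment spans `insert + 2 * read_length`)
#' drawn from Normal(`mean_insert`, `sd_insert`).  The
#' defaults mirror a standard desk-scale resequencing simulation: 100
#' insertions of 10-1000 nt in a 1 Mb reference, 100 bp reads at 30x with a
#' 1500 +/- 150 nt jumping library (150/15 and 3000/300 are the companion
#' short- and long-insert libraries).
#'
#' @param reference_length Reference length (nt).
#' @param n_insertions Number of planted insertions.
#' @param length_range `c(lo, hi)` insertion lengths, drawn uniformly.
#' @param read_length Read length (nt).
#' @param coverage Fold coverage of the read set over the donor.
#' @param mean_insert,sd_insert Insert-size distribution (inner mate
#'   distance).
#' @param error_rate Per-base substitution error rate of the reads.
#' @param min_separation Minimum distance between breakpoints; default
#'   `2 * (mean_insert + 2 * read_length + 4 * sd_insert)` so neighbouring
#'   filters do not interact.
#' @param seed Integer seed; all randomness of the dataset flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(reference_length = 1e6, n_insertions = 100L,
                       length_range = c(10L, 1000L), read_length = 100L,
                       coverage = 30, mean_insert = 1500, sd_insert = 150,
                       error_rate = 0, min_separation = NULL, seed = 1L) {
  stopifnot(length_range[1] >= 1, coverage > 0, sd_insert >= 0)
  if (is.null(min_separation))
    min_separation <- 2 * (mean_insert + 2 * read_length + 4 * sd_insert)
  structure(list(reference_length = as.integer(reference_length),
                 n_insertions = as.integer(n_insertions),
                 length_range = as.integer(length_range),
                 read_length = as.integer(read_length),
                 coverage = coverage, mean_insert = mean_insert,
                 sd_insert = sd_insert, error_rate = error_rate,
                 min_separation = as.integer(min_separation),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Uniform random DNA sequence
#'
#' @param length Sequence length (nt), at least 1.
#' @param seed Optional seed for reproducibility.
#' @return A single DNA string with i.i.d. uniform A/C/G/T bases.
#' @export
make_reference <- function(length, seed = NULL) {
  stopifnot(length >= 1)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

#' Plant random insertions into a reference
#'
#' Draws insertion lengths uniformly from `config$length_range` and
#' breakpoints uniformly among all placements with pairwise separation at
#' least `config$min_separation` (and the same margin to the sequence
#' ends), then splices random sequences in.  The sites carry the exact
#' planted lengths as their length "estimates".
#'
#' @param reference Reference sequence string.
#' @param config A [sim_config()]; only the insertion-related fields are
#'   used.
#' @return List with `donor` (the reference with insertions), `sites` (an
#'   [insertion_sites()] table on the reference), and `truth` (data frame
#'   with `id`, `breakpoint` (reference), `donor_start`, `length`, `seq`).
#' @export
plant_insertions <- function(reference, config) {
  n <- config$n_insertions
  L <- nchar(reference)
  sep <- config$min_separation
  if (n == 0L) {
    sites <- insertion_sites(character(0), integer(0), integer(0),
                             id = character(0))
    return(list(donor = reference, sites = sites,
                truth = data.frame(id = character(0), breakpoint = integer(0),
                                   donor_start = integer(0),
                                   length = integer(0), seq = character(0),
                                   stringsAsFactors = FALSE)))
  }
  # uniform placement conditional on all gaps >= sep: sample in the
  # compacted space and re-expand
  L_eff <- L - 2 * sep - (n - 1) * sep
  if (L_eff < n)
    stop("reference too short for ", n, " insertions separated by ", sep)
  p <- sort(sample.int(L_eff, n)) + sep + (seq_len(n) - 1L) * sep
  len <- sample(config$length_range[1]:config$length_range[2], n,
                replace = TRUE)
  seqs <- vapply(len, function(m)
    paste(sample(c("A", "C", "G", "T"), m, replace = TRUE), collapse = ""),
    "")
  donor_start <- p + c(0L, cumsum(len)[-n])

  pieces <- character(2L * n + 1L)
  prev <- 0L
  for (j in seq_len(n)) {
    pieces[2L * j - 1L] <- substr(reference, prev + 1L, p[j])
    pieces[2L * j] <- seqs[j]
    prev <- p[j]
  }
  pieces[2L * n + 1L] <- substr(reference, prev + 1L, L)
  donor <- paste(pieces, collapse = "")

  ids <- sprintf("ins%03d", seq_len(n))
  list(donor = donor,
       sites = insertion_sites(rep("ref", n), p, len, id = ids),
       truth = data.frame(id = ids, breakpoint = as.integer(p),
                          donor_start = as.integer(donor_start),
                          length = as.integer(len), seq = seqs,
                          stringsAsFactors = FALSE))
}

# substitute random different bases at a given per-base rate
add_read_errors <- function(seqs, rate) {
  l <- nchar(seqs[1])
  n <- length(seqs)
  hits <- which(runif(n * l) < rate)
  if (length(hits) == 0L) return(seqs)
  ri <- (hits - 1L) %/% l + 1L
  pos <- (hits - 1L) %% l + 1L
  for (j in seq_along(hits)) {
    old <- substr(seqs[ri[j]], pos[j], pos[j])
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(seqs[ri[j]], pos[j], pos[j]) <- new
  }
  seqs
}

#' Simulate paired-end reads from a donor sequence
#'
#' Fragments start uniformly on the donor; insert sizes (inner mate
#' distance) are Normal(`mean_insert`, `sd_insert`) rounded and truncated
#' below at 0, so fragments span `insert + 2 * read_length` (capped at the
#' donor length).  The first mate is the
#' fragment's leading `read_length` bases; the second mate is the reverse
#' complement of its trailing bases.  `ceiling(coverage * L / (2 l))` pairs
#' are generated.  Optional uniform substitution errors.
#'
#' @param donor Donor sequence string.
#' @param config A [sim_config()]; read-related fields are used.
#' @param id_prefix Prefix of read identifiers (`<prefix>N/1`, `<prefix>N/2`).
#' @return List with `reads` (named character vector, rows interleaved
#'   mate1/mate2 per pair) and `truth` (data frame with `read_id`,
#'   `pair_id`, `start`, `end` 0-based half-open donor coordinates,
#'   `strand`, `insert` = realized inner insert size of the pair).
#' @export
simulate_reads <- function(donor, config, id_prefix = "read") {
  l <- config$read_length
  L <- nchar(donor)
  mu <- config$mean_insert
  sigma <- config$sd_insert
  if (L < 2 * l) stop("donor shorter than one read pair")
  n_pairs <- as.integer(ceiling(config$coverage * L / (2 * l)))
  # insert = inner mate distance; fragment spans insert + 2 reads
  ins <- pmax(0, round(rnorm(n_pairs, mu, sigma)))
  fr <- pmin(ins + 2 * l, L)
  ins <- fr - 2 * l
  f <- floor(runif(n_pairs) * (L - fr + 1))

  r1 <- substring(donor, f + 1, f + l)
  r2 <- revcomp(substring(donor, f + fr - l + 1, f + fr))
  if (config$error_rate > 0) {
    r1 <- add_read_errors(r1, config$error_rate)
    r2 <- add_read_errors(r2, config$error_rate)
  }
  pair_id <- sprintf("%s%06d", id_prefix, seq_len(n_pairs))
  id1 <- paste0(pair_id, "/1")
  id2 <- paste0(pair_id, "/2")

  # interleave mate1/mate2
  idx <- rep(seq_len(n_pairs), each = 2L)
  is2 <- rep(c(FALSE, TRUE), n_pairs)
  reads <- ifelse(is2, r2[idx], r1[idx])
  names(reads) <- ifelse(is2, id2[idx], id1[idx])
  truth <- data.frame(
    read_id = names(reads),
    pair_id = pair_id[idx],
    start = as.integer(ifelse(is2, f[idx] + fr[idx] - l, f[idx])),
    end = as.integer(ifelse(is2, f[idx] + fr[idx], f[idx] + l)),
    strand = ifelse(is2, "-", "+"),
    insert = as.integer(ins[idx]),
    stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Project true read positions onto the reference (truth-mode alignments)
#'
#' Emits alignment records from the simulator's ground truth without
#' running an aligner: a read maps iff its donor interval lies entirely
#' within a reference-derived segment; reads inside an insertion or
#' crossing a breakpoint by at least one base are unmapped (a conservative
#' stand-in for an aligner's soft clipping).  Mapped coordinates are the
#' donor coordinates minus the planted length preceding the segment.
#'
#' @param read_truth The `truth` data frame from [simulate_reads()].
#' @param insertion_truth The `truth` data frame from [plant_insertions()].
#' @return Alignment data frame as consumed by [filter_reads()]:
#'   `read_id`, `pair_id`, `mapped`, `start`, `end` (0-based half-open
#'   reference coordinates, `NA` when unmapped), `mate_mapped`,
#'   `mate_start`, `strand`.
#' @export
truth_alignments <- function(read_truth, insertion_truth) {
  q <- insertion_truth$donor_start
  d <- insertion_truth$length
  o <- order(q)
  q <- q[o]; d <- d[o]
  m <- length(q)
  # donor blocks: [0,q1) ref, [q1,q1+d1) ins, [q1+d1,q2) ref, ...
  starts <- if (m > 0) c(0, as.vector(rbind(q, q + d))) else 0
  ins_before <- c(0L, cumsum(d))  # for ref block j (odd), (j+1)/2 - 1 + 1
  x <- read_truth$start
  y <- read_truth$end
  bx <- findInterval(x, starts)
  by <- findInterval(y - 1L, starts)
  is_ref_block <- bx %% 2L == 1L
  mapped <- (bx == by) & is_ref_block
  shift <- integer(length(x))
  shift[is_ref_block] <- ins_before[(bx[is_ref_block] + 1L) %/% 2L]
  ref_start <- ifelse(mapped, x - shift, NA_integer_)
  ref_end <- ifelse(mapped, y - shift, NA_integer_)

  # mates are the adjacent interleaved rows
  n <- nrow(read_truth)
  mate <- seq_len(n) + rep(c(1L, -1L), n %/% 2L)
  data.frame(
    read_id = read_truth$read_id,
    pair_id = read_truth$pair_id,
    mapped = mapped,
    start = as.integer(ref_start),
    end = as.integer(ref_end),
    mate_mapped = mapped[mate],
    mate_start = as.integer(ref_start[mate]),
    strand = read_truth$strand,
    stringsAsFactors = FALSE)
}

#' Read identifiers truly covering an insertion
#'
#' The evaluation truth set for read filtering: reads whose true donor
#' interval overlaps the planted insertion by at least one base.
#'
#' @param read_truth The `truth` data frame from [simulate_reads()].
#' @param insertion One row of the [plant_insertions()] `truth` table.
#' @return Character vector of read identifiers.
#' @export
truth_reads_for_insertion <- function(read_truth, insertion) {
  q <- insertion$donor_start
  d <- insertion$length
  read_truth$read_id[read_truth$start < q + d & read_truth$end > q]
}

#' Generate a complete synthetic insertion-genotyping dataset
#'
#' Runs [make_reference()], [plant_insertions()], [simulate_reads()] and
#' [truth_alignments()] under a single seed.
#'
#' @param config A [sim_config()].
#' @return List with `reference`, `donor`, `sites`, `insertion_truth`,
#'   `reads`, `read_truth`, `alignments`, `config`.
#' @export
simulate_insertion_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  reference <- make_reference(config$reference_length)
  planted <- plant_insertions(reference, config)
  rd <- simulate_reads(planted$donor, config)
  aln <- truth_alignments(rd$truth, planted$truth)
  list(reference = reference, donor = planted$donor,
       sites = planted$sites, insertion_truth = planted$truth,
       reads = rd$reads, read_truth = rd$truth,
       alignments = aln, config = config)
}
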
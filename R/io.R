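#' Read and write sequence files
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is what the rest of the pipeline consumes.
#'
#' @param path File path.
#' @return `read_fasta()`/`read_fastq()`: named character vector of
#'   sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read insertion sites from VCF or TSV
#'
#' VCF: one site per record with `INFO/SVLEN` giving the estimated
#' insertion length; `POS` (1-based, base immediately left of the
#' insertion) maps to the 0-based breakpoint `p = POS`.  TSV: four columns
#' `chrom`, `pos` (1-based as in VCF), `id`, `length`, no header.
#'
#' @param path File path (`.vcf` or anything else treated as TSV).
#' @return An [insertion_sites()] data frame.
#' @export
read_sites <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
    if (anyNA(svlen))
      stop("every VCF record needs INFO/SVLEN with the estimated length")
    id <- fix[, "ID"]
    id[is.na(id) | id == "."] <- sprintf("ins%d", which(is.na(id) | id == "."))
    insertion_sites(fix[, "CHROM"], as.integer(fix[, "POS"]),
                    abs(svlen), id = id)
  } else {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "pos", "id", "length"),
                      stringsAsFactors = FALSE)
    insertion_sites(tab$chrom, tab$pos, tab$length, id = tab$id)
  }
}

#' Write insertion sites or genotype calls as VCF
#'
#' Emits a minimal VCF 4.2.  For filled calls the ALT allele is the
#' anchor base followed by the insertion sequence; unfilled sites get the
#' symbolic allele `<INS>`.  `INFO` carries `SVTYPE=INS;SVLEN=<length>`.
#'
#' @param calls A [genotype_all()] report or [insertion_sites()] table.
#' @param reference Reference sequence string (for the anchor base).
#' @param path Output path.
#' @param contig Contig name written in the header (default: first `chrom`).
#' @export
write_sites_vcf <- function(calls, reference, path,
                            contig = calls$chrom[1]) {
  p <- calls$breakpoint
  refbase <- substring(reference, p, p)  # 1-based char p = base before insertion
  filled <- if ("status" %in% names(calls))
    calls$status == "filled" & !is.na(calls$insertion) else
      rep(FALSE, nrow(calls))
  alt <- ifelse(filled, paste0(refbase, calls$insertion), "<INS>")
  len <- if ("length" %in% names(calls))
    ifelse(is.na(calls$length), calls$est_length, calls$length) else
      calls$est_length
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=insfill",
    sprintf("##contig=<ID=%s,length=%d>", contig, nchar(reference)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the insertion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tSVTYPE=INS;SVLEN=%d",
                  calls$chrom, p, calls$id, refbase, alt,
                  ifelse(filled, "PASS", "."), len)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' Uses Rsamtools (SAM text is first converted with [Rsamtools::asBam()]).
#' Only the fields the filtering scheme needs are extracted; coordinates
#' are converted to 0-based half-open.  Read identifiers get `/1`/`/2`
#' suffixes from the first/second-of-pair flags.
#'
#' @param path SAM or BAM file.
#' @param read_length Fallback read length when a record has no sequence.
#' @return Alignment data frame as consumed by [filter_reads()].
#' @export
read_alignments <- function(path, read_length = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "qwidth", "mrnm", "mpos"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  paired <- bitwAnd(flag, 1L) > 0L
  first <- bitwAnd(flag, 64L) > 0L
  suffix <- ifelse(!paired, "", ifelse(first, "/1", "/2"))
  mapped <- bitwAnd(flag, 4L) == 0L
  mate_mapped <- ifelse(paired, bitwAnd(flag, 8L) == 0L, NA)
  qw <- b$qwidth
  if (!is.null(read_length)) qw[is.na(qw)] <- read_length
  data.frame(
    read_id = paste0(b$qname, suffix),
    pair_id = b$qname,
    mapped = mapped,
    start = ifelse(mapped, b$pos - 1L, NA_integer_),
    end = ifelse(mapped, b$pos - 1L + qw, NA_integer_),
    mate_mapped = mate_mapped,
    mate_start = ifelse(mate_mapped %in% TRUE, b$mpos - 1L, NA_integer_),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    stringsAsFactors = FALSE)
}

#' Write alignments as SAM text
#'
#' Emits the minimal valid SAM the pipeline uses (one reference sequence,
#' ungapped `<len>M` alignments, no TLEN).  Useful to export truth-mode
#' alignments for external tools and for round-tripping through
#' [read_alignments()].
#'
#' @param alignments Alignment data frame (see [filter_reads()]); a
#'   `strand` column is honoured if present.
#' @param path Output path.
#' @param refname,reflen Name and length of the single reference sequence.
#' @param seqs Optional named character vector of read sequences (names =
#'   `read_id`); `*` is written otherwise.
#' @export
write_sam <- function(alignments, path, refname = "ref", reflen,
                      seqs = NULL) {
  a <- alignments
  n <- nrow(a)
  suffix <- sub("^.*(/[12])$", "\\1", a$read_id)
  is1 <- suffix == "/1"
  is2 <- suffix == "/2"
  flag <- rep(0L, n)
  paired <- is1 | is2
  flag <- flag + ifelse(paired, 1L, 0L) + ifelse(is1, 64L, 0L) +
    ifelse(is2, 128L, 0L)
  flag <- flag + ifelse(a$mapped %in% TRUE, 0L, 4L)
  flag <- flag + ifelse(paired & !(a$mate_mapped %in% TRUE), 8L, 0L)
  if ("strand" %in% names(a))
    flag <- flag + ifelse(a$strand == "-" & a$mapped %in% TRUE, 16L, 0L)
  mapped <- a$mapped %in% TRUE
  sq <- if (is.null(seqs)) rep("*", n) else unname(seqs[a$read_id])
  qual <- ifelse(sq == "*", "*", strrep("I", nchar(sq)))
  qname <- if ("pair_id" %in% names(a)) a$pair_id else
    sub("/[12]$", "", a$read_id)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
    qname, flag,
    ifelse(mapped, refname, "*"),
    ifelse(mapped, a$start + 1L, 0L),
    ifelse(mapped, 60L, 0L),
    ifelse(mapped, paste0(a$end - a$start, "M"), "*"),
    ifelse(a$mate_mapped %in% TRUE, refname, "*"),
    ifelse(a$mate_mapped %in% TRUE, a$mate_start + 1L, 0L),
    sq, qual)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", refname, as.integer(reflen)))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write the per-site genotyping report as TSV
#'
#' @param calls A [genotype_all()] report.
#' @param path Output path.
#' @export
write_genotype_report <- function(calls, path) {
  out <- as.data.frame(calls)
  attr(out, "calls") <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
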
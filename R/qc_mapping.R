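#' Quality-filter a read set
#'
#' Two-stage removal mirroring standard short-read pre-processing: first drop
#' reads whose fraction of N bases is strictly greater than `max_n_fraction`
#' (default 10%), then drop reads in which the fraction of bases with quality
#' at or below `q_threshold` is strictly greater than `lowq_fraction`
#' (default: more than 50% of bases at Q <= 5). Survivor order is preserved.
#'
#' @param reads A `read_set` (see [simulate_reads()], [read_fastq()]).
#' @param max_n_fraction Maximum tolerated N fraction (in `(0, 1]`).
#' @param lowq_fraction Maximum tolerated low-quality base fraction.
#' @param q_threshold Phred score at or below which a base counts as
#'   low quality.
#' @return A list with `reads` (the filtered `read_set`) and `report`, a
#'   one-row data.frame of class `qc_report` with columns `input`,
#'   `removed_polyN`, `removed_lowq`, `retained` (which always sum up) and
#'   the thresholds used.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 500), collapse = "")))
#' rs <- simulate_reads(ref, depth = 2, read_length = 50, seed = 1,
#'                      contaminate = list(poly_n = 0.2))
#' filter_reads(rs)$report
#' @export
filter_reads <- function(reads, max_n_fraction = 0.10, lowq_fraction = 0.50,
                         q_threshold = 5L) {
  stopifnot(inherits(reads, "read_set"))
  if (max_n_fraction <= 0 || max_n_fraction > 1 ||
      lowq_fraction <= 0 || lowq_fraction > 1)
    stop("fractions must be in (0, 1]")
  n <- length(reads$seqs)
  if (n == 0) {
    report <- data.frame(input = 0L, removed_polyN = 0L, removed_lowq = 0L,
                         retained = 0L, max_n_fraction = max_n_fraction,
                         lowq_fraction = lowq_fraction,
                         q_threshold = as.integer(q_threshold))
    class(report) <- c("qc_report", "data.frame")
    return(list(reads = reads, report = report))
  }
  w <- Biostrings::width(reads$seqs)
  n_frac <- as.vector(Biostrings::letterFrequency(reads$seqs, "N")) / w
  polyn <- n_frac > max_n_fraction

  # bases at quality <= q_threshold have Phred+33 characters 33..(33+q)
  low_chars <- strsplit(rawToChar(as.raw(33:(33 + as.integer(q_threshold)))),
                        "", fixed = TRUE)[[1L]]
  lf <- Biostrings::letterFrequency(reads$quals, low_chars)
  lowq_frac <- rowSums(lf) / w
  lowq <- !polyn & lowq_frac > lowq_fraction

  keep <- !polyn & !lowq
  out <- reads
  out$seqs <- reads$seqs[keep]
  out$quals <- reads$quals[keep]
  report <- data.frame(input = n, removed_polyN = sum(polyn),
                       removed_lowq = sum(lowq), retained = sum(keep),
                       max_n_fraction = max_n_fraction,
                       lowq_fraction = lowq_fraction,
                       q_threshold = as.integer(q_threshold))
  class(report) <- c("qc_report", "data.frame")
  list(reads = out, report = report)
}

#' k-mer multiplicity histogram of a read set
#'
#' Counts canonical k-mers (a k-mer and its reverse complement are the same
#' species) across all reads and tabulates how many distinct k-mers occur at
#' each multiplicity. k-mers containing non-ACGT letters are skipped.
#'
#' @param reads A `read_set`, `DNAStringSet`, or character vector.
#' @param k Odd k-mer size between 11 and 31 (default 21).
#' @return An object of class `kmer_histogram`: list with `k`, `histogram`
#'   (data.frame `multiplicity`, `count`), `distinct` and `total` (total
#'   k-mer occurrences; equals `sum(multiplicity * count)`).
#' @seealso [estimate_genome_size()]
#' @export
kmer_histogram <- function(reads, k = 21L) {
  if (k %% 2 != 1 || k < 11 || k > 31) stop("'k' must be odd and in 11..31")
  seqs <- if (inherits(reads, "read_set")) as.character(reads$seqs)
          else as.character(reads)
  if (length(seqs) == 0) stop("'reads' must be non-empty")
  if (k > max(nchar(seqs))) stop("'k' exceeds the read length")
  res <- cpp_kmer_hist(seqs, as.integer(k))
  structure(list(k = as.integer(k),
                 histogram = data.frame(multiplicity = res$multiplicity,
                                        count = res$count),
                 distinct = res$distinct, total = res$total),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("k-mer histogram (k =", x$k, "):", format(x$distinct, big.mark = ","),
      "distinct /", format(x$total, big.mark = ","), "total occurrences\n")
  invisible(x)
}

#' Genome-size estimate from a k-mer histogram
#'
#' The classical k-mer spectrum estimator: locate the error trough (the first
#' local minimum of the count-vs-multiplicity curve, present when sequencing
#' errors create a spike of low-multiplicity k-mers), take the homozygous
#' coverage peak as the modal multiplicity beyond the trough - refined to the
#' count-weighted mean multiplicity within a window of half to one-and-a-half
#' times the mode, which is robust to bin-level sampling noise and excludes
#' the two-copy repeat shoulder - and divide the total k-mer occurrences
#' above the trough by the peak depth.
#'
#' @param histogram A [kmer_histogram()] result.
#' @return A list with `genome_size` (bp, `NA` if undetermined), `peak`
#'   (refined k-mer coverage at the homozygous peak), `mode` (raw modal
#'   multiplicity), `trough` (multiplicity of the error trough; 0 when no
#'   error component is detectable) and `determined`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGTT", 2000), collapse = "")))
#' rs <- simulate_reads(ref, depth = 20, read_length = 100, error_rate = 0, seed = 1)
#' estimate_genome_size(kmer_histogram(rs))
#' @export
estimate_genome_size <- function(histogram) {
  stopifnot(inherits(histogram, "kmer_histogram"))
  h <- histogram$histogram
  # dense counts over multiplicities 1..max
  mmax <- max(h$multiplicity)
  counts <- numeric(mmax)
  counts[h$multiplicity] <- h$count
  undetermined <- list(genome_size = NA_real_, peak = NA_real_,
                       mode = NA_integer_, trough = NA_integer_,
                       determined = FALSE)
  if (mmax < 2 || length(unique(counts)) == 1L) return(undetermined)
  trough <- 0L
  if (counts[1L] > counts[2L]) {     # error spike present: find first local min
    i <- 2L
    while (i < mmax && counts[i + 1L] < counts[i]) i <- i + 1L
    if (i >= mmax) return(undetermined)   # monotone decreasing: no peak
    trough <- i
  }
  above <- seq.int(trough + 1L, mmax)
  mode <- above[which.max(counts[above])]
  if (counts[mode] == 0) return(undetermined)
  peak <- as.numeric(mode)
  for (iter in 1:10) {               # recenter the window until stable
    win <- seq.int(max(trough + 1L, ceiling(peak / 2)),
                   min(mmax, floor(1.5 * peak)))
    new_peak <- sum(win * counts[win]) / sum(counts[win])
    if (abs(new_peak - peak) < 1e-6) break
    peak <- new_peak
  }
  total_above <- sum(above * counts[above])
  list(genome_size = total_above / peak, peak = peak,
       mode = as.integer(mode), trough = as.integer(trough),
       determined = TRUE)
}

#' Build a seed index over reference contigs
#'
#' Light container pairing the reference with the exact-seed length used by
#' [map_reads()]. The seed rule is part of the mapper's public contract: a
#' read is placed at a position only if at least one of its `seed_k`-mers
#' matches the reference there exactly, then the full-length ungapped
#' extension must stay within the mismatch budget.
#'
#' @param reference Named `DNAStringSet` (or character vector) of contigs.
#' @param seed_k Exact-seed length (default 31).
#' @return An object of class `read_index`.
#' @export
build_index <- function(reference, seed_k = 31L) {
  ref <- if (methods::is(reference, "DNAStringSet")) as.character(reference)
         else as.character(reference)
  if (is.null(names(ref)) || any(names(ref) == ""))
    stop("reference contigs must be named")
  if (seed_k < 11 || seed_k > 32) stop("'seed_k' must be in 11..32")
  if (any(nchar(ref) < seed_k))
    stop("all reference contigs must be at least seed_k long")
  structure(list(ref = ref, seed_k = as.integer(seed_k)),
            class = "read_index")
}

#' Map reads to a reference with the exact-seed ungapped mapper
#'
#' End-to-end, ungapped, all-hits mapping: a read is reported at every
#' position (both strands) where some exact `seed_k`-mer anchors it and the
#' full-length Hamming distance is at most `max_mismatches`. Multi-mapping
#' reads report all sites, which is deliberately conservative for
#' coverage-subtraction screening (a candidate is discarded if any opposite
#' library read can be placed on it anywhere). Reads shorter than the seed
#' are skipped and counted, not fatal.
#'
#' @param reads A `read_set`, `DNAStringSet`, or character vector.
#' @param index A [build_index()] result.
#' @param max_mismatches Full-length substitution budget (default 5).
#' @return A data.frame of class `alignments` with columns `read` (name),
#'   `contig`, `start` (0-based), `strand`, `mismatches`, `length`, plus
#'   attributes `n_reads` and `n_skipped`.
#' @export
map_reads <- function(reads, index, max_mismatches = 5L) {
  stopifnot(inherits(index, "read_index"))
  seqs <- if (inherits(reads, "read_set")) as.character(reads$seqs)
          else as.character(reads)
  if (is.null(names(seqs)) && !is.null(names(reads)))
    names(seqs) <- names(reads)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("read_%d", seq_along(seqs))
  res <- cpp_map_reads(index$ref, unname(seqs), index$seed_k,
                       as.integer(max_mismatches))
  out <- data.frame(read = names(seqs)[res$read],
                    contig = names(index$ref)[res$contig],
                    start = res$start, strand = res$strand,
                    mismatches = res$mismatches, length = res$length,
                    stringsAsFactors = FALSE)
  attr(out, "n_reads") <- length(seqs)
  attr(out, "n_skipped") <- res$skipped
  class(out) <- c("alignments", "data.frame")
  out
}

#' Import alignments from SAM/BAM
#'
#' Maps mapped records to the internal alignment table; secondary and
#' supplementary records are ignored by default. Ungapped placements are
#' assumed: the aligned length is taken from the read width.
#'
#' @param path SAM or BAM file; SAM is converted on the fly.
#' @param reference Named `DNAStringSet`/character of the contigs the
#'   alignments refer to (used to validate bounds).
#' @param include_secondary If `TRUE`, keep secondary/supplementary records.
#' @return An `alignments` data.frame as from [map_reads()].
#' @export
import_alignments <- function(path, reference, include_secondary = FALSE) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  if (!include_secondary)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
  prm <- Rsamtools::ScanBamParam(flag = flag,
                                 what = c("qname", "rname", "pos", "strand",
                                          "seq"))
  rec <- Rsamtools::scanBam(bam, param = prm)[[1L]]
  len <- Biostrings::width(rec$seq)
  out <- data.frame(read = rec$qname, contig = as.character(rec$rname),
                    start = rec$pos - 1L,
                    strand = as.character(rec$strand),
                    mismatches = NA_integer_, length = len,
                    stringsAsFactors = FALSE)
  ref_len <- stats::setNames(nchar(as.character(reference)),
                             names(reference))
  if (any(!out$contig %in% names(ref_len)))
    stop("alignments reference unknown contigs")
  if (any(out$start < 0 | out$start + out$length > ref_len[out$contig]))
    stop("alignment overhangs contig end")
  class(out) <- c("alignments", "data.frame")
  out
}

#' Per-contig coverage track from an alignment table
#'
#' Depth is incremented over the half-open interval
#' `[start, start + length)` of every alignment, so the total depth mass
#' equals the total aligned bases. Every reference contig appears in the
#' track (all-zero when unaligned).
#'
#' @param alignments An `alignments` data.frame.
#' @param reference Named `DNAStringSet`/character of contigs.
#' @param id Library identifier carried on the track.
#' @param sex Optional sex annotation of the source library (used by
#'   [pool_filter()] to validate pool/target pairing).
#' @return An object of class `coverage_track`: list with `depth` (an
#'   `IRanges::RleList`, one run-length-encoded integer vector per contig),
#'   `id` and `sex`.
#' @export
coverage_track <- function(alignments, reference, id = "lib", sex = NA_character_) {
  ref_len <- stats::setNames(nchar(as.character(reference)), names(reference))
  if (nrow(alignments) > 0) {
    if (any(!alignments$contig %in% names(ref_len)))
      stop("alignments reference unknown contigs")
    if (any(alignments$start < 0 |
            alignments$start + alignments$length > ref_len[alignments$contig]))
      stop("alignment overhangs contig end")
  }
  depth <- lapply(names(ref_len), function(ctg) {
    sel <- alignments$contig == ctg
    if (!any(sel)) return(S4Vectors::Rle(0L, ref_len[[ctg]]))
    ir <- IRanges::IRanges(start = alignments$start[sel] + 1L,
                           width = alignments$length[sel])
    IRanges::coverage(ir, width = ref_len[[ctg]])
  })
  names(depth) <- names(ref_len)
  structure(list(depth = methods::as(depth, "SimpleRleList"),
                 id = id, sex = sex),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$depth, function(d) sum(as.numeric(S4Vectors::runValue(d)) *
                                               S4Vectors::runLength(d)), numeric(1)))
  cat("Coverage track", x$id,
      if (!is.na(x$sex)) paste0("(", x$sex, ")") else "",
      "-", length(x$depth), "contig(s),", format(tot, big.mark = ","),
      "aligned bases\n")
  invisible(x)
}
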
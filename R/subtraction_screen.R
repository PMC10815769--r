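.track_lengths <- function(track) {
  vapply(track$depth, length, numeric(1))
}

.check_same_reference <- function(tracks) {
  ref <- .track_lengths(tracks[[1L]])
  for (t in tracks[-1L]) {
    l <- .track_lengths(t)
    if (!identical(names(l), names(ref)) || !identical(unname(l), unname(ref)))
      stop("coverage tracks computed over mismatched references")
  }
  ref
}

.screen_seqinfo <- function(lens) {
  GenomeInfoDb::Seqinfo(seqnames = names(lens), seqlengths = as.integer(lens))
}

.covered_ranges <- function(track, min_depth = 1L) {
  # per-contig IRangesList of positions with depth >= min_depth
  methods::as(lapply(track$depth, function(d) {
    IRanges::ranges(IRanges::slice(d, lower = min_depth, rangesOnly = FALSE))
  }), "SimpleIRangesList")
}

.ranges_to_granges <- function(irl, lens) {
  si <- .screen_seqinfo(lens)
  n <- vapply(irl, length, integer(1))
  if (sum(n) == 0) return(GenomicRanges::GRanges(seqinfo = si))
  GenomicRanges::GRanges(
    seqnames = rep(names(irl), n),
    ranges = unlist(methods::as(irl, "SimpleIRangesList"), use.names = FALSE),
    seqinfo = si)
}

.with_stage <- function(gr, stage) {
  prov <- S4Vectors::mcols(gr)$provenance
  S4Vectors::mcols(gr)$provenance <-
    if (length(gr) == 0) character(0)
    else if (is.null(prov)) rep(stage, length(gr))
    else paste(prov, stage, sep = ";")
  gr
}

#' Regions covered in every same-sex library
#'
#' First stage of the subtraction screen: the "common sequences" of one sex.
#' At `sequence` granularity (the scaffold-level reading, default) a whole
#' contig is kept when every library covers at least `covered_fraction` of
#' its bases at depth `>= min_depth`. At `interval` granularity the per-base
#' covered sets of all libraries are intersected and emitted as maximal
#' intervals - the right choice when contigs are chromosome-scale.
#'
#' @param tracks List of [coverage_track()]s of same-sex libraries over one
#'   shared reference.
#' @param min_depth Minimum per-base depth for a base to count as covered.
#' @param covered_fraction Minimum covered fraction per contig
#'   (`sequence` granularity only).
#' @param granularity `"sequence"` or `"interval"`.
#' @return A `GRanges` of candidate intervals (0-based half-open when
#'   exported; `GRanges` itself is 1-based closed internally) with a
#'   `provenance` metadata column.
#' @export
common_regions <- function(tracks, min_depth = 1L, covered_fraction = 0.5,
                           granularity = c("sequence", "interval")) {
  granularity <- match.arg(granularity)
  if (length(tracks) < 1L) stop("at least one coverage track is required")
  lens <- .check_same_reference(tracks)
  si <- .screen_seqinfo(lens)

  gr <- if (granularity == "sequence") {
    keep <- vapply(names(lens), function(ctg) {
      all(vapply(tracks, function(t) {
        d <- t$depth[[ctg]]
        sum(S4Vectors::runLength(d)[S4Vectors::runValue(d) >= min_depth]) >=
          covered_fraction * length(d)
      }, logical(1)))
    }, logical(1))
    if (!any(keep)) GenomicRanges::GRanges(seqinfo = si)
    else GenomicRanges::GRanges(names(lens)[keep],
                                IRanges::IRanges(1L, lens[keep]), seqinfo = si)
  } else {
    cov <- lapply(tracks, .covered_ranges, min_depth = min_depth)
    inter <- Reduce(function(a, b) {
      methods::as(mapply(IRanges::intersect, a, b, SIMPLIFY = FALSE),
                  "SimpleIRangesList")
    }, cov)
    .ranges_to_granges(inter, lens)
  }
  .with_stage(sort(gr), "common")
}

#' Strict zero-coverage subtraction against opposite-sex libraries
#'
#' Removes every base covered by at least `min_reads` reads (default 1: any
#' single read disqualifies) in any of the opposite-sex libraries. At
#' `sequence` granularity a contig-level candidate is discarded entirely if
#' any opposite-sex read maps anywhere on that contig.
#'
#' @param regions `GRanges` of candidate intervals.
#' @param tracks List of opposite-sex [coverage_track()]s on the same
#'   reference.
#' @param min_reads Per-base read count that disqualifies (default 1).
#' @param granularity `"interval"` or `"sequence"`.
#' @param stage Provenance label recorded on survivors.
#' @return Filtered `GRanges`.
#' @export
subtract_covered <- function(regions, tracks, min_reads = 1L,
                             granularity = c("interval", "sequence"),
                             stage = "subtract") {
  granularity <- match.arg(granularity)
  if (length(tracks) == 0L) return(regions)
  lens <- .check_same_reference(tracks)
  if (length(regions) > 0 &&
      !all(as.character(GenomicRanges::seqnames(regions)) %in% names(lens)))
    stop("regions and coverage tracks refer to different references")

  out <- if (granularity == "sequence") {
    dirty <- names(lens)[vapply(names(lens), function(ctg) {
      any(vapply(tracks, function(t) {
        max(S4Vectors::runValue(t$depth[[ctg]])) >= min_reads
      }, logical(1)))
    }, logical(1))]
    regions[!as.character(GenomicRanges::seqnames(regions)) %in% dirty]
  } else {
    covered <- Reduce(GenomicRanges::union, lapply(tracks, function(t) {
      .ranges_to_granges(.covered_ranges(t, min_reads), lens)
    }))
    GenomicRanges::setdiff(regions, covered)
  }
  .with_stage(sort(out), stage)
}

#' Subtract coverage of the single-sex mixed pool
#'
#' Same strict zero-coverage rule as [subtract_covered()], applied to the
#' pooled library of many homogametic-sex individuals. Any pool coverage
#' over a candidate disproves its sex specificity, which is what removes
#' autosomal pseudo markers that slipped through the small per-sex groups:
#' a trap locus with absent-allele frequency q survives a pool of N
#' individuals only with probability `q^(2N)`.
#'
#' @param regions `GRanges` of candidates.
#' @param pool_track [coverage_track()] of the pool library; its `sex` must
#'   be the homogametic sex for the target (`male` for female-specific
#'   candidates, `female` for male-specific).
#' @param target `"female"` or `"male"`: which sex the candidates are
#'   specific to.
#' @param min_reads,granularity As in [subtract_covered()].
#' @return Filtered `GRanges`.
#' @export
pool_filter <- function(regions, pool_track, target = c("female", "male"),
                        min_reads = 1L,
                        granularity = c("interval", "sequence")) {
  target <- match.arg(target)
  granularity <- match.arg(granularity)
  required <- if (target == "female") "male" else "female"
  if (!is.na(pool_track$sex) && pool_track$sex != required)
    stop("pool sex '", pool_track$sex, "' does not match the homogametic sex '",
         required, "' required for ", target, "-specific candidates")
  subtract_covered(regions, list(pool_track), min_reads = min_reads,
                   granularity = granularity, stage = "pool")
}

#' Sequence-composition filters on candidate regions
#'
#' Drops candidates that are poor marker substrates: regions whose N-base
#' fraction exceeds `max_n_fraction`; repetitive regions, defined as those
#' in which more than `max_repeat_fraction` of constituent canonical
#' `repeat_k`-mers occur two or more times in the whole reference; and
#' regions shorter than `min_length`. Survivors carry the full stage
#' provenance; the dropped regions (with the filter that fired) are attached
#' as attribute `"dropped"`.
#'
#' @param regions `GRanges` of candidates.
#' @param reference Named `DNAStringSet` the candidates index into.
#' @param max_n_fraction Maximum N fraction (default 0.1).
#' @param max_repeat_fraction Maximum repeated-k-mer fraction (default 0.5).
#' @param repeat_k k-mer size for the repeat test (default 21).
#' @param min_length Minimum region length in bp (default 200).
#' @return `GRanges` of retained regions (class unchanged), with attribute
#'   `"dropped"`: a `GRanges` whose `reason` metadata column names the
#'   filter that fired (`"N-content"`, `"repeat"` or `"min-length"`).
#' @export
composition_filters <- function(regions, reference, max_n_fraction = 0.1,
                                max_repeat_fraction = 0.5, repeat_k = 21L,
                                min_length = 200L) {
  ref_chr <- as.character(reference)
  if (length(regions) == 0) {
    out <- .with_stage(regions, "composition")
    attr(out, "dropped") <- regions
    return(out)
  }
  seqs <- candidate_sequences(regions, reference)
  n_frac <- as.vector(Biostrings::letterFrequency(seqs, "N")) /
    Biostrings::width(seqs)
  repeat_frac <- vapply(as.character(seqs), function(s) {
    if (nchar(s) < repeat_k) return(1)
    counts <- cpp_kmer_ref_counts(s, unname(ref_chr), as.integer(repeat_k))
    valid <- counts >= 0
    if (!any(valid)) return(1)
    mean(counts[valid] >= 2L)
  }, numeric(1), USE.NAMES = FALSE)

  reason <- rep(NA_character_, length(regions))
  reason[n_frac > max_n_fraction] <- "N-content"
  reason[is.na(reason) & repeat_frac > max_repeat_fraction] <- "repeat"
  reason[is.na(reason) & GenomicRanges::width(regions) < min_length] <- "min-length"

  keep <- is.na(reason)
  dropped <- regions[!keep]
  S4Vectors::mcols(dropped)$reason <- reason[!keep]
  out <- .with_stage(regions[keep], "composition")
  attr(out, "dropped") <- dropped
  out
}

#' Extract candidate sequences from the reference
#'
#' @param regions `GRanges`.
#' @param reference Named `DNAStringSet`.
#' @return `DNAStringSet` named `contig:start-end` (0-based half-open).
#' @export
candidate_sequences <- function(regions, reference) {
  if (length(regions) == 0) return(Biostrings::DNAStringSet())
  ctg <- as.character(GenomicRanges::seqnames(regions))
  if (!all(ctg %in% names(reference)))
    stop("regions reference contigs absent from the reference")
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(i) {
    as.character(Biostrings::subseq(reference[[ctg[i]]],
                                    start = GenomicRanges::start(regions)[i],
                                    end = GenomicRanges::end(regions)[i]))
  }, character(1)))
  names(seqs) <- sprintf("%s:%d-%d", ctg,
                         GenomicRanges::start(regions) - 1L,
                         GenomicRanges::end(regions))
  seqs
}

#' Summary statistics of a screened candidate set
#'
#' @param female,male `GRanges` of final female- and male-specific
#'   candidates (either may be empty).
#' @param attrition Optional data.frame of per-stage counts to carry along.
#' @return An object of class `screen_summary`: data.frame with one row per
#'   sex (`target`, `count`, `total_bp`, `mean_bp`), the attrition table as
#'   attribute `"attrition"`.
#' @examples
#' gr <- GenomicRanges::GRanges("w", IRanges::IRanges(1, 2951))
#' summarize_screen(rep(gr, 1735), GenomicRanges::GRanges())
#' @export
summarize_screen <- function(female, male, attrition = NULL) {
  row <- function(target, gr) {
    w <- GenomicRanges::width(gr)
    data.frame(target = target, count = length(gr),
               total_bp = sum(as.numeric(w)),
               mean_bp = if (length(gr)) sum(as.numeric(w)) / length(gr) else NA_real_)
  }
  out <- rbind(row("female-specific", female), row("male-specific", male))
  attr(out, "attrition") <- attrition
  class(out) <- c("screen_summary", "data.frame")
  out
}

#' Infer the sex-determination system from screened totals
#'
#' Compares the total female- and male-specific base pairs: a female excess
#' of at least `ratio_threshold` implies female heterogamety (ZW), the
#' mirror implies XY, anything in between is undetermined. A `pseudocount`
#' of 1 bp on both totals keeps the ratio defined when one sex yields
#' nothing - the expected final state for a true ZW species, where no
#' male-specific sequence survives.
#'
#' @param summary A [summarize_screen()] result.
#' @param ratio_threshold Fold-difference needed to call a system (default 5).
#' @param pseudocount Base pairs added to both totals (default 1).
#' @return An object of class `system_call`: list with `system` (`"ZW"`,
#'   `"XY"` or `"undetermined"`), `female_bp`, `male_bp`, `ratio` and
#'   `ratio_threshold`.
#' @export
infer_system <- function(summary, ratio_threshold = 5, pseudocount = 1) {
  stopifnot(inherits(summary, "screen_summary"))
  f <- summary$total_bp[summary$target == "female-specific"]
  m <- summary$total_bp[summary$target == "male-specific"]
  ratio <- (f + pseudocount) / (m + pseudocount)
  system <- if (ratio >= ratio_threshold) "ZW"
            else if (ratio <= 1 / ratio_threshold) "XY"
            else "undetermined"
  structure(list(system = system, female_bp = f, male_bp = m,
                 ratio = ratio, ratio_threshold = ratio_threshold),
            class = "system_call")
}

#' @export
print.system_call <- function(x, ...) {
  cat("Inferred sex-determination system:", x$system, "\n")
  cat(sprintf("  female-specific %.0f bp vs male-specific %.0f bp (ratio %.2f, threshold %g)\n",
              x$female_bp, x$male_bp, x$ratio, x$ratio_threshold))
  invisible(x)
}

#' Export screened candidates as BED, FASTA and a TSV report
#'
#' BED coordinates are 0-based half-open; FASTA records are named
#' `contig:start-end` in the same convention and their sequences equal the
#' corresponding reference slices.
#'
#' @param candidates `GRanges` of final candidates.
#' @param reference Named `DNAStringSet`.
#' @param prefix Output path prefix; writes `<prefix>.bed`, `<prefix>.fasta`
#'   and `<prefix>.tsv`.
#' @param summary Optional [summarize_screen()] result mirrored into the TSV.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_candidates <- function(candidates, reference, prefix, summary = NULL) {
  bed <- paste0(prefix, ".bed")
  fasta <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  rtracklayer::export(candidates, bed, format = "BED")
  Biostrings::writeXStringSet(candidate_sequences(candidates, reference),
                              fasta, width = 60L)
  tab <- if (!is.null(summary)) as.data.frame(summary) else {
    data.frame(target = NA_character_, count = length(candidates),
               total_bp = sum(as.numeric(GenomicRanges::width(candidates))),
               mean_bp = if (length(candidates))
                 mean(GenomicRanges::width(candidates)) else NA_real_)
  }
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed, fasta = fasta, tsv = tsv))
}

#' Interval Jaccard index between two region sets
#'
#' Base-pair overlap of the union/intersection, ignoring strand - the
#' recovery statistic used to compare screened candidates with the synthetic
#' ground truth.
#'
#' @param a,b `GRanges`.
#' @return A number in `[0, 1]` (1 when both are empty).
#' @export
interval_jaccard <- function(a, b) {
  a <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  b <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  if (length(a) == 0 && length(b) == 0) return(1)
  inter <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE))))
  uni <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::union(a, b, ignore.strand = TRUE))))
  inter / uni
}

#' Empirical removal probability of a forced trap locus by the pool filter
#'
#' Genotype-level simulation of the pool stage acting on a pseudo marker
#' that survived the per-sex groups: a pool of `N` Hardy-Weinberg
#' individuals removes the trap as soon as any member carries at least one
#' presence allele, so the removal probability is `1 - q^(2N)` with
#' `q = 1 - p`. Used to verify the pool-filter law.
#'
#' @param p Presence-allele frequency.
#' @param N Pool size.
#' @param replicates Number of simulated pools.
#' @param seed Integer seed.
#' @return List with `removal_rate` (empirical), `expected`
#'   (`1 - (1-p)^(2N)`), `replicates`, `p`, `N`.
#' @export
simulate_trap_removal <- function(p, N, replicates = 1e4, seed) {
  stopifnot(p >= 0, p <= 1, N >= 1, replicates >= 1)
  if (missing(seed)) stop("'seed' is required")
  withr::with_seed(seed, {
    carriers <- stats::rbinom(replicates, 2L * N, p)
    list(removal_rate = mean(carriers > 0L),
         expected = 1 - (1 - p)^(2 * N),
         replicates = as.integer(replicates), p = p, N = as.integer(N))
  })
}

#' Run the full subtraction screen for one target sex
#'
#' Convenience orchestration of the Fig-style workflow for one direction:
#' same-sex common regions, zero-coverage subtraction against the
#' opposite-sex libraries, optional pool subtraction, then composition
#' filters. Records the stage-by-stage attrition.
#'
#' @param same_tracks,opposite_tracks Lists of [coverage_track()]s over the
#'   target-sex reference.
#' @param reference Named `DNAStringSet` (the target-sex reference).
#' @param target `"female"` or `"male"`.
#' @param pool_track Optional pool [coverage_track()].
#' @param granularity `"interval"` or `"sequence"`.
#' @param min_depth,covered_fraction Passed to [common_regions()].
#' @param min_reads Passed to the subtraction stages.
#' @param max_n_fraction,max_repeat_fraction,repeat_k,min_length Passed to
#'   [composition_filters()].
#' @return List with `candidates` (`GRanges`), `attrition` (data.frame of
#'   `stage`, `count`, `total_bp`) and `dropped` (composition-filter
#'   casualties).
#' @export
screen_candidates <- function(same_tracks, opposite_tracks, reference,
                              target = c("female", "male"),
                              pool_track = NULL,
                              granularity = c("interval", "sequence"),
                              min_depth = 1L, covered_fraction = 0.5,
                              min_reads = 1L, max_n_fraction = 0.1,
                              max_repeat_fraction = 0.5, repeat_k = 21L,
                              min_length = 200L) {
  target <- match.arg(target)
  granularity <- match.arg(granularity)
  steps <- list()
  gr <- common_regions(same_tracks, min_depth = min_depth,
                       covered_fraction = covered_fraction,
                       granularity = granularity)
  steps[["common"]] <- gr
  gr <- subtract_covered(gr, opposite_tracks, min_reads = min_reads,
                         granularity = granularity)
  steps[["subtract"]] <- gr
  if (!is.null(pool_track)) {
    gr <- pool_filter(gr, pool_track, target = target, min_reads = min_reads,
                      granularity = granularity)
    steps[["pool"]] <- gr
  }
  gr <- composition_filters(gr, reference, max_n_fraction = max_n_fraction,
                            max_repeat_fraction = max_repeat_fraction,
                            repeat_k = repeat_k, min_length = min_length)
  steps[["composition"]] <- gr
  attrition <- data.frame(
    stage = names(steps),
    count = vapply(steps, length, integer(1)),
    total_bp = vapply(steps, function(g)
      sum(as.numeric(GenomicRanges::width(g))), numeric(1)),
    row.names = NULL)
  list(candidates = gr, attrition = attrition,
       dropped = attr(gr, "dropped"))
}
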
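# build a coverage track directly from interval specs: list(c(start0, end0))
track_from_intervals <- function(ref, intervals, id = "lib", sex = NA_character_,
                                 depth = 1L) {
  aln <- if (length(intervals)) do.call(rbind, lapply(intervals, function(iv) {
    data.frame(read = "x", contig = names(ref)[1], start = iv[1], strand = "+",
               mismatches = 0L, length = iv[2] - iv[1])
  })) else data.frame(read = character(0), contig = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), length = integer(0))
  coverage_track(aln, ref, id = id, sex = sex)
}

test_that("common regions intersect covered sets per granularity", {
  ref <- Biostrings::DNAStringSet(c(c1 = strrep("A", 250)))
  t1 <- track_from_intervals(ref, list(c(0, 100)))
  t2 <- track_from_intervals(ref, list(c(50, 150)))
  t3 <- track_from_intervals(ref, list(c(80, 200)))
  gr <- common_regions(list(t1, t2, t3), granularity = "interval")
  expect_identical(GenomicRanges::start(gr), 81L)   # 0-based [80,100)
  expect_identical(GenomicRanges::end(gr), 100L)
  # one empty library empties the intersection
  t0 <- track_from_intervals(ref, list())
  expect_identical(length(common_regions(list(t1, t0),
                                         granularity = "interval")), 0L)
  # full coverage in all libraries keeps whole contigs in sequence mode
  tf <- track_from_intervals(ref, list(c(0, 250)))
  gs <- common_regions(list(tf, tf), granularity = "sequence")
  expect_identical(GenomicRanges::width(gs), 250L)
  # sequence mode enforces the covered fraction per library
  th <- track_from_intervals(ref, list(c(0, 100)))   # 40% covered
  expect_identical(length(common_regions(list(th), covered_fraction = 0.5,
                                         granularity = "sequence")), 0L)
  expect_identical(length(common_regions(list(th), covered_fraction = 0.3,
                                         granularity = "sequence")), 1L)
  # mismatched references error
  ref2 <- Biostrings::DNAStringSet(c(other = strrep("A", 100)))
  t_other <- track_from_intervals(ref2, list(c(0, 50)))
  expect_error(common_regions(list(t1, t_other)), "mismatched")
})

test_that("zero-coverage subtraction is strict and granular", {
  ref <- Biostrings::DNAStringSet(c(c1 = strrep("A", 250)))
  cand <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 100),
                                 seqinfo = GenomeInfoDb::Seqinfo("c1", 250L))
  opp <- track_from_intervals(ref, list(c(40, 60)))
  res <- subtract_covered(cand, list(opp), granularity = "interval")
  expect_identical(GenomicRanges::start(res), c(1L, 61L))
  expect_identical(GenomicRanges::end(res), c(40L, 100L))
  # empty opposite library: identity
  res_id <- subtract_covered(cand, list(track_from_intervals(ref, list())),
                             granularity = "interval")
  expect_identical(GenomicRanges::ranges(res_id), GenomicRanges::ranges(cand))
  # sequence mode: one opposite read removes the whole contig
  res_seq <- subtract_covered(cand, list(opp), granularity = "sequence")
  expect_identical(length(res_seq), 0L)
})

test_that("pool filter enforces pool sex and removes covered candidates", {
  ref <- Biostrings::DNAStringSet(c(c1 = strrep("A", 250)))
  cand <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 200),
                                 seqinfo = GenomeInfoDb::Seqinfo("c1", 250L))
  pool_m <- track_from_intervals(ref, list(c(100, 150)), sex = "male")
  res <- pool_filter(cand, pool_m, target = "female")
  expect_identical(sum(GenomicRanges::width(res)), 150L)
  expect_error(pool_filter(cand, pool_m, target = "male"), "homogametic")
  # empty pool track: identity
  pool_empty <- track_from_intervals(ref, list(), sex = "male")
  res2 <- pool_filter(cand, pool_empty, target = "female")
  expect_identical(sum(GenomicRanges::width(res2)), 200L)
})

test_that("pool removal of a forced trap follows the 1 - q^(2N) law", {
  for (p in c(0.2, 0.5, 0.8)) {
    for (N in c(5L, 15L)) {
      sim <- simulate_trap_removal(p, N, replicates = 1e4,
                                   seed = round(1000 * p) + N)
      expect_equal(sim$expected, 1 - (1 - p)^(2 * N))
      se <- sqrt(sim$expected * (1 - sim$expected) / sim$replicates)
      expect_lte(abs(sim$removal_rate - sim$expected), 3 * se + 1e-12)
    }
  }
})

test_that("a forced trap surviving the 3v3 screen is removed by the pool reads", {
  spec <- build_genome_spec(list(autosome_length = 20000L,
                                 sex_shared_length = 5000L,
                                 unique_lengths = 600L, n_traps = 1L,
                                 trap_p_range = c(0.5, 0.5)), seed = 21)
  pop <- simulate_population(spec, 3, 3, pool_size = 10, seed = 22,
                             force_trap = TRUE)
  # at p = 0.5 a pool of 10 lacks allele A with probability 2^-20
  fref <- reference_genome(pop, "female")
  idx <- build_index(fref)
  track_for <- function(ind_or_pool, id, sex, depth) {
    rs <- simulate_reads(ind_or_pool, depth = depth, seed = 100 + nchar(id),
                         id = id)
    coverage_track(map_reads(rs, idx), fref, id = id, sex = sex)
  }
  sexes <- vapply(pop$individuals, function(i) i$sex, character(1))
  f_tracks <- lapply(which(sexes == "female"), function(i)
    track_for(pop$individuals[[i]], paste0("f", i), "female", 20))
  m_tracks <- lapply(which(sexes == "male"), function(i)
    track_for(pop$individuals[[i]], paste0("m", i), "male", 20))
  pool_track <- track_for(pop$pool, "poolx", "male", 30)
  first <- subtract_covered(common_regions(f_tracks, granularity = "interval"),
                            m_tracks, granularity = "interval")
  # trap insertion footprint on the female reference (female I carries it)
  trap_len <- nchar(spec$traps$seq[1])
  trap_gr <- GenomicRanges::GRanges(
    "autosome_1", IRanges::IRanges(spec$traps$position[1] + 1L,
                                   spec$traps$position[1] + trap_len))
  overlap_bp <- function(gr, target) suppressWarnings(sum(GenomicRanges::width(
    GenomicRanges::intersect(gr, target, ignore.strand = TRUE))))
  # the trap survives the individual-level screen by construction ...
  expect_gte(overlap_bp(first, trap_gr), 0.8 * trap_len)
  # ... and is wiped out by the male pool
  after_pool <- pool_filter(first, pool_track, target = "female",
                            granularity = "interval")
  expect_identical(overlap_bp(after_pool, trap_gr), 0L)
  # true W-unique candidates are untouched by the ZZ-male pool
  truth_gr <- GenomicRanges::GRanges(
    spec$truth$contig, IRanges::IRanges(spec$truth$start + 1L, spec$truth$end))
  expect_gt(overlap_bp(first, truth_gr), 0.9 * sum(GenomicRanges::width(truth_gr)))
  # pool reads may trim a few bases where a Z read overhangs the insertion
  # junction within the mismatch budget; the interval itself must stay
  expect_gte(overlap_bp(after_pool, truth_gr), overlap_bp(first, truth_gr) - 10L)
})

test_that("composition filters drop N-rich, repetitive and short regions", {
  base <- random_dna_chr(3000)
  dup <- substr(base, 501, 1500)                       # verbatim repeat
  nrich <- paste0(substr(random_dna_chr(1000), 1, 850), strrep("N", 150))
  ref <- Biostrings::DNAStringSet(c(
    c1 = paste0(base, dup, nrich, random_dna_chr(2000))))
  si <- GenomeInfoDb::Seqinfo("c1", length(ref[[1]]))
  regions <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    start = c(3001, 4001, 5151, 5251),
    end = c(4000, 5000, 5250, 7000)), seqinfo = si)
  # region 1: duplicate of base[501:1500] -> repeat
  # region 2: 15% N -> N-content
  # region 3: 100 bp clean -> min-length
  # region 4: clean unique -> retained
  res <- composition_filters(regions, ref)
  expect_identical(length(res), 1L)
  expect_identical(GenomicRanges::start(res), 5251L)
  dropped <- attr(res, "dropped")
  expect_identical(S4Vectors::mcols(dropped)$reason,
                   c("repeat", "N-content", "min-length"))
})

test_that("summaries are exact arithmetic and drive system inference", {
  mk <- function(count, len) {
    if (count == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges("s", IRanges::IRanges(rep(1, count), width = len))
  }
  s <- summarize_screen(mk(1883, 2131), mk(151, 1733))
  expect_identical(s$count, c(1883L, 151L))
  expect_identical(s$total_bp, c(1883 * 2131, 151 * 1733))
  expect_equal(s$mean_bp, c(2131, 1733))
  call <- infer_system(s)
  expect_identical(call$system, "ZW")
  # undetermined when both sides are empty
  s0 <- summarize_screen(GenomicRanges::GRanges(), GenomicRanges::GRanges())
  expect_identical(infer_system(s0)$system, "undetermined")
  expect_identical(infer_system(s0)$ratio, 1)
  # XY mirror
  sxy <- summarize_screen(mk(10, 100), mk(100, 2000))
  expect_identical(infer_system(sxy)$system, "XY")
})

test_that("candidate export round-trips BED and FASTA coordinates", {
  ref <- Biostrings::DNAStringSet(c(c1 = random_dna_chr(1000)))
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(101, 501, 801),
                                                      c(300, 700, 900)),
                               seqinfo = GenomeInfoDb::Seqinfo("c1", 1000L))
  prefix <- tempfile()
  paths <- export_candidates(gr, ref, prefix)
  bed <- read.table(paths[["bed"]], sep = "\t")
  expect_identical(nrow(bed), 3L)
  expect_identical(bed$V2, c(100L, 500L, 800L))      # 0-based starts
  expect_identical(bed$V3, c(300L, 700L, 900L))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_identical(names(fa), c("c1:100-300", "c1:500-700", "c1:800-900"))
  expect_identical(as.character(fa[[1]]),
                   as.character(Biostrings::subseq(ref[[1]], 101, 300)))
  # empty set writes empty valid files
  p0 <- export_candidates(GenomicRanges::GRanges(), ref, tempfile())
  expect_identical(length(Biostrings::readDNAStringSet(p0[["fasta"]])), 0L)
})

test_that("candidate bp never increases across screening stages", {
  run <- demo_run("ZW")
  a <- run$attrition
  for (tg in unique(a$target)) {
    tot <- a$total_bp[a$target == tg]
    expect_true(all(diff(tot) <= 0))
  }
})
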
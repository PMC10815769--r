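make_read_set <- function(seqs, quals) {
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- sprintf("r%d", seq_along(seqs))
  q <- Biostrings::BStringSet(quals)
  names(q) <- names(s)
  structure(list(id = "fix", seqs = s, quals = q,
                 read_length = if (length(seqs)) max(nchar(seqs)) else 0L,
                 depth = NA_real_,
                 error_rate = NA_real_, seed = NA_integer_),
            class = "read_set")
}

test_that("read filtering applies strict N and quality thresholds", {
  q30 <- strrep("?", 150)
  reads <- make_read_set(
    c(paste0(strrep("N", 20), strrep("A", 130)),   # 13.3% N -> polyN
      paste0(strrep("N", 15), strrep("A", 135)),   # exactly 10% N -> kept
      strrep("A", 150),                            # clean
      strrep("C", 150),                            # 75 bases at Q5 -> kept
      strrep("G", 150)),                           # 76 bases at Q5 -> removed
    c(q30, q30, q30,
      paste0(strrep("&", 75), strrep("?", 75)),    # '&' is Q5
      paste0(strrep("&", 76), strrep("?", 74))))
  res <- filter_reads(reads)
  expect_identical(res$report$input, 5L)
  expect_identical(res$report$removed_polyN, 1L)
  expect_identical(res$report$removed_lowq, 1L)
  expect_identical(res$report$retained, 3L)
  expect_identical(res$report$removed_polyN + res$report$removed_lowq +
                     res$report$retained, res$report$input)
  expect_identical(names(res$reads$seqs), c("r2", "r3", "r4"))
})

test_that("filtering an empty read set yields zero counts", {
  empty <- make_read_set(character(0), character(0))
  res <- filter_reads(empty)
  expect_identical(res$report$input, 0L)
  expect_identical(res$report$retained, 0L)
  expect_identical(length(res$reads$seqs), 0L)
})

test_that("QC conservation holds on random contaminated libraries", {
  ref <- Biostrings::DNAStringSet(c(chr = random_dna_chr(10000)))
  for (seed in 1:3) {
    rs <- simulate_reads(ref, depth = 3, read_length = 100, seed = seed,
                         contaminate = list(poly_n = 0.07, low_q = 0.05))
    rep <- filter_reads(rs)$report
    expect_identical(rep$removed_polyN + rep$removed_lowq + rep$retained,
                     rep$input)
    expect_gt(rep$removed_polyN, 0L)
    expect_gt(rep$removed_lowq, 0L)
  }
})

test_that("k-mer histogram counts canonical k-mers exactly on tiny fixtures", {
  # one read, k = read length: one k-mer at multiplicity 1
  h <- kmer_histogram(Biostrings::DNAStringSet("ACGTACGTACGTACGTACGTA"), k = 21)
  expect_identical(h$histogram$multiplicity, 1L)
  expect_identical(h$histogram$count, 1)
  expect_identical(h$total, 1)
  # a read and its reverse complement share all canonical k-mers
  s <- random_dna_chr(50)
  h2 <- kmer_histogram(c(a = s, b = revcomp_chr(s)), k = 21)
  expect_true(all(h2$histogram$multiplicity == 2L))
  expect_identical(h2$total, 2 * (50 - 21 + 1))
  # conservation: sum(multiplicity * count) = total occurrences
  rs <- simulate_reads(Biostrings::DNAStringSet(c(c1 = random_dna_chr(5000))),
                       depth = 8, read_length = 80, seed = 2)
  h3 <- kmer_histogram(rs)
  expect_equal(sum(h3$histogram$multiplicity * h3$histogram$count), h3$total)
  expect_error(kmer_histogram(rs, k = 20), "odd")
})

test_that("genome size is recovered within 2% on error-free simulations", {
  len <- 100000L
  ref <- Biostrings::DNAStringSet(c(chr = random_dna_chr(len)))
  rs <- simulate_reads(ref, depth = 20, read_length = 100, error_rate = 0,
                       seed = 5)
  est <- estimate_genome_size(kmer_histogram(rs))
  expect_true(est$determined)
  expect_lt(abs(est$genome_size - len) / len, 0.02)
  # doubling depth changes the estimate by < 2%
  rs2 <- simulate_reads(ref, depth = 40, read_length = 100, error_rate = 0,
                        seed = 6)
  est2 <- estimate_genome_size(kmer_histogram(rs2))
  expect_lt(abs(est2$genome_size - est$genome_size) / est$genome_size, 0.02)
})

test_that("flat histograms give an explicit undetermined result", {
  h <- kmer_histogram(Biostrings::DNAStringSet(random_dna_chr(60)), k = 21)
  est <- estimate_genome_size(h)
  expect_false(est$determined)
  expect_true(is.na(est$genome_size))
})

test_that("mapper handles planted reads, mismatch budgets and short reads", {
  ref_chr <- random_dna_chr(5000)
  ref <- Biostrings::DNAStringSet(c(c1 = ref_chr))
  idx <- build_index(ref)
  # exact substring at offset 1000 (0-based)
  r <- substr(ref_chr, 1001, 1100)
  aln <- map_reads(Biostrings::DNAStringSet(c(x = r)), idx)
  expect_identical(aln$start, 1000L)
  expect_identical(aln$mismatches, 0L)
  expect_identical(aln$strand, "+")
  # reverse-complement maps to the same position on the minus strand
  aln_rc <- map_reads(Biostrings::DNAStringSet(c(x = revcomp_chr(r))), idx)
  expect_identical(aln_rc$start, 1000L)
  expect_identical(aln_rc$strand, "-")
  # 3 substitutions spaced < 31 apart: no intact seed, max_mismatches = 2
  rr <- strsplit(substr(ref_chr, 2001, 2100), "")[[1]]
  for (pos in c(10, 35, 60, 85)) rr[pos] <- setdiff(c("A","C","G","T"), rr[pos])[1]
  aln2 <- map_reads(Biostrings::DNAStringSet(c(y = paste(rr, collapse = ""))),
                    idx, max_mismatches = 2)
  expect_identical(nrow(aln2), 0L)
  # reads shorter than the seed are skipped, not fatal
  aln3 <- map_reads(Biostrings::DNAStringSet(c(s = "ACGTACGT")), idx)
  expect_identical(nrow(aln3), 0L)
  expect_identical(attr(aln3, "n_skipped"), 1L)
})

test_that("mapper equals the exhaustive sliding-window oracle", {
  withr::with_seed(101, {
    for (rep in 1:3) {
      ref <- c(c1 = random_dna_chr(2500), c2 = random_dna_chr(1500))
      # duplicate a block to force multi-mapping
      ref[["c2"]] <- paste0(substr(ref[["c1"]], 101, 400),
                            substr(ref[["c2"]], 301, 1500))
      reads <- character(0)
      for (i in 1:25) {
        src <- sample(names(ref), 1)
        start <- sample(nchar(ref[[src]]) - 79, 1)
        r <- substr(ref[[src]], start, start + 79)
        chars <- strsplit(r, "")[[1]]
        nmut <- sample(0:5, 1)
        if (nmut > 0) {
          at <- sample(80, nmut)
          for (j in at) chars[j] <- sample(c("A", "C", "G", "T"), 1)
        }
        if (sample(c(TRUE, FALSE), 1)) chars <- strsplit(revcomp_chr(
          paste(chars, collapse = "")), "")[[1]]
        reads <- c(reads, paste(chars, collapse = ""))
      }
      reads <- c(reads, random_dna_chr(80))     # almost surely unmappable
      names(reads) <- sprintf("r%02d", seq_along(reads))
      got <- map_reads(reads, build_index(Biostrings::DNAStringSet(ref)),
                       max_mismatches = 5)
      want <- oracle_map(reads, ref, seed_k = 31, max_mm = 5)
      expect_identical(canonical_alignment_order(got),
                       canonical_alignment_order(want))
    }
  })
})

test_that("coverage tracks conserve aligned bases and do interval arithmetic", {
  ref <- Biostrings::DNAStringSet(c(c1 = random_dna_chr(300)))
  aln <- data.frame(read = c("a", "b"), contig = "c1", start = c(0L, 50L),
                    strand = "+", mismatches = 0L, length = c(100L, 100L))
  tr <- coverage_track(aln, ref)
  d <- as.integer(tr$depth[["c1"]])
  expect_identical(d[1:50], rep(1L, 50))
  expect_identical(d[51:100], rep(2L, 50))
  expect_identical(d[101:150], rep(1L, 50))
  expect_identical(d[151:300], rep(0L, 150))
  expect_identical(sum(d), 200L)
  # no alignments: all-zero track
  tr0 <- coverage_track(aln[0, ], ref)
  expect_identical(sum(as.integer(tr0$depth[["c1"]])), 0L)
  # conservation on a random mapped library
  ref2 <- Biostrings::DNAStringSet(c(chr = random_dna_chr(8000)))
  rs <- simulate_reads(ref2, depth = 4, read_length = 60, error_rate = 0,
                       seed = 8)
  a <- map_reads(rs, build_index(ref2), max_mismatches = 0)
  t2 <- coverage_track(a, ref2)
  expect_identical(sum(as.numeric(S4Vectors::runValue(t2$depth[["chr"]]) *
                                    S4Vectors::runLength(t2$depth[["chr"]]))),
                   sum(as.numeric(a$length)))
  # overhanging alignment violates the contract
  bad <- data.frame(read = "z", contig = "c1", start = 250L, strand = "+",
                    mismatches = 0L, length = 100L)
  expect_error(coverage_track(bad, ref), "overhangs")
})

test_that("SAM import maps primary records onto the alignment contract", {
  ref_chr <- random_dna_chr(500)
  ref <- Biostrings::DNAStringSet(c(t1 = ref_chr))
  sam <- tempfile(fileext = ".sam")
  r1 <- substr(ref_chr, 101, 180)
  r2 <- substr(ref_chr, 301, 380)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:t1\tLN:500",
    paste("p1", "0", "t1", "101", "60", "80M", "*", "0", "0", r1,
          strrep("I", 80), sep = "\t"),
    paste("p2", "16", "t1", "301", "60", "80M", "*", "0", "0", r2,
          strrep("I", 80), sep = "\t"),
    paste("p3", "256", "t1", "1", "0", "80M", "*", "0", "0",
          substr(ref_chr, 1, 80), strrep("I", 80), sep = "\t"),  # secondary
    paste("p4", "4", "*", "0", "0", "*", "*", "0", "0",
          random_dna_chr(80), strrep("I", 80), sep = "\t")),     # unmapped
    sam)
  aln <- import_alignments(sam, ref)
  expect_identical(sort(aln$read), c("p1", "p2"))
  expect_identical(aln$start[aln$read == "p1"], 100L)
  expect_identical(aln$strand[aln$read == "p2"], "-")
  aln_all <- import_alignments(sam, ref, include_secondary = TRUE)
  expect_identical(sort(aln_all$read), c("p1", "p2", "p3"))
  # imported alignments drive coverage like native ones
  tr <- coverage_track(aln, ref)
  expect_identical(sum(as.integer(tr$depth[["t1"]])), 160L)
})
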
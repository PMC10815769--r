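# Independent brute-force oracles and shared fixtures. The oracles are kept
# deliberately naive (exhaustive scans, explicit loops) and never call the
# code paths they check.

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Exhaustive sliding-window mapper with the same seed-visibility rule as the
# package mapper: report (contig, t, strand) iff some exact seed_k window
# (ACGT-only on both sides) anchors the diagonal and the full-length literal
# Hamming distance is <= max_mm.
oracle_map <- function(reads, ref, seed_k = 31L, max_mm = 5L) {
  out <- list()
  acgt <- c("A", "C", "G", "T")
  for (ctg in names(ref)) {
    refc <- strsplit(ref[[ctg]], "", fixed = TRUE)[[1L]]
    ref_ok <- refc %in% acgt
    for (rn in names(reads)) {
      for (strand in c("+", "-")) {
        rseq <- if (strand == "+") reads[[rn]] else revcomp_chr(reads[[rn]])
        L <- nchar(rseq)
        if (L < seed_k || L > length(refc)) next
        rchars <- strsplit(rseq, "", fixed = TRUE)[[1L]]
        read_ok <- rchars %in% acgt
        npos <- length(refc) - L + 1L
        for (t in seq_len(npos)) {
          win <- refc[t:(t + L - 1L)]
          eq <- win == rchars
          mm <- sum(!eq)
          if (mm > max_mm) next
          seed_ok <- eq & ref_ok[t:(t + L - 1L)] & read_ok
          runs <- rle(seed_ok)
          if (!any(runs$values & runs$lengths >= seed_k)) next
          out[[length(out) + 1L]] <- data.frame(
            read = rn, contig = ctg, start = t - 1L, strand = strand,
            mismatches = mm, length = L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(read = character(0), contig = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), length = integer(0)))
  do.call(rbind, out)
}

canonical_alignment_order <- function(df) {
  df <- as.data.frame(df)[, c("read", "contig", "start", "strand",
                              "mismatches", "length")]
  df <- df[order(df$read, df$contig, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# IUPAC base sets for the primer-scan oracle
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_compatible <- function(a, b) {
  length(intersect(.iupac_sets[[a]], .iupac_sets[[b]])) > 0
}

iupac_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# Exhaustive Hamming/IUPAC primer scan over both strands; mismatch = number
# of positions whose IUPAC base sets do not intersect.
oracle_primer_scan <- function(primer, ref, max_mm = 2L) {
  out <- list()
  scan_one <- function(pseq, ctg, refc, strand) {
    pc <- strsplit(pseq, "", fixed = TRUE)[[1L]]
    L <- length(pc)
    if (L > length(refc)) return()
    for (t in seq_len(length(refc) - L + 1L)) {
      mm <- 0L
      for (j in seq_len(L)) {
        if (!iupac_compatible(pc[j], refc[t + j - 1L])) mm <- mm + 1L
        if (mm > max_mm) break
      }
      if (mm <= max_mm)
        out[[length(out) + 1L]] <<- data.frame(
          contig = ctg, start = t - 1L, end = t - 1L + L, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  for (ctg in names(ref)) {
    refc <- strsplit(ref[[ctg]], "", fixed = TRUE)[[1L]]
    scan_one(primer, ctg, refc, "+")
    scan_one(iupac_revcomp(primer), ctg, refc, "-")
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$contig, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# small shared genome spec for fast cohort tests
small_spec <- function(seed = 1, system = "ZW", n_traps = 2L) {
  build_genome_spec(list(system = system, autosome_length = 30000L,
                         sex_shared_length = 8000L,
                         unique_lengths = c(800L, 1200L),
                         n_traps = n_traps), seed = seed)
}
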
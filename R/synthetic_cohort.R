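#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib sexscreen, .registration = TRUE
NULL

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (i in pos) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.het_sex <- function(system) if (system == "ZW") "female" else "male"
.hom_sex <- function(system) if (system == "ZW") "male" else "female"
.shared_chrom <- function(system) if (system == "ZW") "chrZ" else "chrX"
.het_chrom <- function(system) if (system == "ZW") "chrW" else "chrY"

#' Build a ground-truthed synthetic sex-genome specification
#'
#' Constructs the sequence layout of a small diploid genome with genotypic sex
#' determination: autosomes carrying biallelic presence/absence "trap" loci at
#' Hardy-Weinberg frequencies, a shared gametologous sex-chromosome pair
#' (Z/W or X/Y) whose heterogametic copy is a diverged duplicate of the
#' homogametic one, and heterogametic-chromosome-unique insertions whose
#' locations are the ground-truth sex-specific intervals the screening
#' pipeline should recover.
#'
#' Trap loci emulate the autosomal pseudo-marker problem: allele A is the
#' presence of a short insertion, allele a its absence, so a cohort in which
#' every heterogametic-sex individual is Aa and every homogametic-sex
#' individual is aa produces a false sex-specific signal.
#'
#' @param config Named list overriding any of the defaults:
#'   `system` ("ZW" or "XY"), `autosome_length` (200000), `n_autosomes` (1),
#'   `sex_shared_length` (20000, the gametolog), `unique_lengths`
#'   (c(2000, 3000, 5000), heterogametic-unique insertions),
#'   `gametolog_divergence` (0.02 substitutions/site, must be in [0, 0.2]),
#'   `n_traps` (10), `trap_length` (400), `trap_p_range` (c(0.2, 0.8)),
#'   `trap_positions` (optional explicit 0-based insertion points).
#' @param seed Integer seed; the spec is deterministic given `(config, seed)`.
#' @return An object of class `sex_genome_spec`: sequences for autosomes and
#'   both sex chromosomes (`Biostrings::DNAStringSet`), a `truth` data.frame
#'   of 0-based half-open heterogametic-unique intervals on the heterogametic
#'   chromosome, and a `traps` data.frame (`autosome`, `position`, `p`,
#'   `seq`).
#' @examples
#' spec <- build_genome_spec(list(autosome_length = 20000, n_traps = 2,
#'                                sex_shared_length = 5000,
#'                                unique_lengths = c(500, 800)), seed = 1)
#' spec$truth
#' @export
build_genome_spec <- function(config = list(), seed) {
  if (missing(seed)) stop("'seed' is required")
  defaults <- list(system = "ZW", autosome_length = 200000L, n_autosomes = 1L,
                   sex_shared_length = 20000L,
                   unique_lengths = c(2000L, 3000L, 5000L),
                   gametolog_divergence = 0.02,
                   n_traps = 10L, trap_length = 400L,
                   trap_p_range = c(0.2, 0.8), trap_positions = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  cfg$system <- match.arg(cfg$system, c("ZW", "XY"))
  stopifnot(cfg$autosome_length > 0, cfg$n_autosomes >= 1,
            cfg$sex_shared_length > 0, all(cfg$unique_lengths > 0))
  if (cfg$gametolog_divergence < 0 || cfg$gametolog_divergence > 0.2)
    stop("'gametolog_divergence' must be in [0, 0.2]")

  withr::with_seed(seed, {
    autosomes <- Biostrings::DNAStringSet(
      vapply(seq_len(cfg$n_autosomes), function(i) .random_dna(cfg$autosome_length),
             character(1)))
    names(autosomes) <- paste0("autosome_", seq_len(cfg$n_autosomes))

    shared <- .random_dna(cfg$sex_shared_length)
    gametolog <- .mutate_dna(shared, cfg$gametolog_divergence)

    # insert unique segments at evenly spaced points of the gametolog copy
    k <- length(cfg$unique_lengths)
    cut_points <- round(cfg$sex_shared_length * seq_len(k) / (k + 1))
    pieces <- character(0)
    truth <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0))
    prev <- 0L
    offset <- 0L
    for (i in seq_len(k)) {
      seg <- substr(gametolog, prev + 1L, cut_points[i])
      ins <- .random_dna(cfg$unique_lengths[i])
      pieces <- c(pieces, seg, ins)
      start <- as.integer(cut_points[i] + offset)
      truth <- rbind(truth, data.frame(contig = .het_chrom(cfg$system),
                                       start = start,
                                       end = as.integer(start + cfg$unique_lengths[i])))
      offset <- offset + cfg$unique_lengths[i]
      prev <- cut_points[i]
    }
    pieces <- c(pieces, substr(gametolog, prev + 1L, cfg$sex_shared_length))
    het_seq <- paste(pieces, collapse = "")

    # trap loci: insertion points on the autosomes, Hardy-Weinberg p each
    n_traps <- cfg$n_traps
    traps <- if (n_traps > 0) {
      if (is.null(cfg$trap_positions)) {
        per_auto <- ceiling(n_traps / cfg$n_autosomes)
        margin <- max(1000L, cfg$trap_length)
        span <- cfg$autosome_length - 2L * margin
        pos <- unlist(lapply(seq_len(cfg$n_autosomes), function(a) {
          m <- min(per_auto, n_traps - (a - 1L) * per_auto)
          if (m <= 0) return(integer(0))
          margin + round(span * seq_len(m) / (m + 1))
        }))
        auto <- rep(seq_len(cfg$n_autosomes),
                    times = vapply(seq_len(cfg$n_autosomes), function(a) {
                      max(0L, min(per_auto, n_traps - (a - 1L) * per_auto))
                    }, numeric(1)))
        data.frame(autosome = paste0("autosome_", auto), position = pos)
      } else {
        data.frame(autosome = paste0("autosome_", 1L), position = cfg$trap_positions)
      }
    } else {
      data.frame(autosome = character(0), position = integer(0))
    }
    if (nrow(traps) > 0) {
      traps$p <- stats::runif(nrow(traps), cfg$trap_p_range[1], cfg$trap_p_range[2])
      traps$seq <- vapply(seq_len(nrow(traps)), function(i)
        .random_dna(cfg$trap_length), character(1))
      # collision check: insertion points must not overlap once expanded
      bad <- unlist(lapply(split(seq_len(nrow(traps)), traps$autosome), function(ix) {
        pos <- sort(traps$position[ix])
        ix[which(diff(pos) < cfg$trap_length) + 1L]
      }))
      if (any(traps$position < 0) || any(traps$position > cfg$autosome_length))
        stop("trap positions outside autosome bounds")
      if (length(bad))
        stop("overlapping trap loci at positions: ",
             paste(traps$position[bad], collapse = ", "))
      traps$id <- paste0("trap_", seq_len(nrow(traps)))
    }

    structure(list(system = cfg$system, seed = as.integer(seed), config = cfg,
                   autosomes = autosomes,
                   shared_seq = shared, het_seq = het_seq,
                   truth = truth, traps = traps),
              class = "sex_genome_spec")
  })
}

#' @export
print.sex_genome_spec <- function(x, ...) {
  cat("Synthetic", x$system, "genome spec:",
      length(x$autosomes), "autosome(s) x", x$config$autosome_length, "bp;",
      .shared_chrom(x$system), nchar(x$shared_seq), "bp;",
      .het_chrom(x$system), nchar(x$het_seq), "bp with",
      nrow(x$truth), "unique insertion(s);",
      nrow(x$traps), "trap locus/loci\n")
  invisible(x)
}

# splice trap insertions carried on one haplotype into an autosome sequence
.splice_autosome <- function(base_seq, traps_here, carried) {
  if (!any(carried)) return(base_seq)
  sel <- traps_here[carried, , drop = FALSE]
  sel <- sel[order(sel$position), , drop = FALSE]
  pieces <- character(0)
  prev <- 0L
  for (i in seq_len(nrow(sel))) {
    pieces <- c(pieces, substr(base_seq, prev + 1L, sel$position[i]), sel$seq[i])
    prev <- sel$position[i]
  }
  paste(c(pieces, substr(base_seq, prev + 1L, nchar(base_seq))), collapse = "")
}

.make_individual <- function(spec, id, sex, hap_alleles, with_sequences = TRUE) {
  system <- spec$system
  karyotype <- if (system == "ZW") {
    if (sex == "female") "ZW" else "ZZ"
  } else {
    if (sex == "male") "XY" else "XX"
  }
  genotypes <- if (nrow(spec$traps) > 0) {
    g <- rowSums(hap_alleles)   # copies of allele A
    stats::setNames(c("aa", "Aa", "AA")[g + 1L], spec$traps$id)
  } else stats::setNames(character(0), character(0))

  haplotypes <- NULL
  if (with_sequences) {
    seqs <- character(0)
    nms <- character(0)
    for (a in seq_along(spec$autosomes)) {
      aname <- names(spec$autosomes)[a]
      here <- spec$traps$autosome == aname
      base_seq <- as.character(spec$autosomes[[a]])
      for (h in 1:2) {
        carried <- if (any(here)) hap_alleles[here, h] == 1L else logical(0)
        seqs <- c(seqs, .splice_autosome(base_seq,
                                         spec$traps[here, , drop = FALSE],
                                         carried))
        nms <- c(nms, paste0(aname, "|h", h))
      }
    }
    sex_haps <- if (karyotype %in% c("ZW", "XY")) {
      c(spec$shared_seq, spec$het_seq)
    } else {
      c(spec$shared_seq, spec$shared_seq)
    }
    sex_names <- if (karyotype %in% c("ZW", "XY")) {
      c(paste0(.shared_chrom(system), "|h1"), paste0(.het_chrom(system), "|h2"))
    } else {
      paste0(.shared_chrom(system), c("|h1", "|h2"))
    }
    haplotypes <- Biostrings::DNAStringSet(c(seqs, sex_haps))
    names(haplotypes) <- c(nms, sex_names)
  }

  structure(list(id = id, sex = sex, karyotype = karyotype,
                 genotypes = genotypes, haplotypes = haplotypes),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat("Individual", x$id, "-", x$sex, paste0("(", x$karyotype, ")"), "\n")
  if (length(x$genotypes))
    cat("  trap genotypes:", paste(x$genotypes, collapse = " "), "\n")
  invisible(x)
}

#' Simulate a genotyped population and single-sex pool from a genome spec
#'
#' Draws `n_females + n_males` group individuals plus a pool of `pool_size`
#' individuals of the homogametic sex (males for ZW, females for XY - any
#' pool coverage over a candidate region disproves its sex specificity).
#' Each individual receives two alleles per trap locus by independent
#' Bernoulli(`p`) draws, so genotypes follow canonical Hardy-Weinberg
#' `(p^2, 2pq, q^2)`; karyotypes follow phenotypic sex. Haplotype sequences
#' are assembled by splicing carried trap insertions into the autosomes.
#'
#' @param spec A [build_genome_spec()] result.
#' @param n_females,n_males Group sizes (each `>= 0`).
#' @param pool_size Number of homogametic-sex pool individuals.
#' @param seed Integer seed.
#' @param force_trap If `TRUE`, the first trap locus is forced to the
#'   worst-case pseudo-marker configuration: every heterogametic-sex group
#'   individual Aa, every homogametic-sex group individual aa (pool members
#'   are still drawn from Hardy-Weinberg, which is what lets the pool filter
#'   catch the trap).
#' @param with_sequences If `FALSE`, skip haplotype sequence assembly (cheap
#'   genotype-only populations, e.g. for Hardy-Weinberg checks).
#' @return An object of class `population`: list with `individuals` (group),
#'   `pool`, `spec`, and `truth` (list of `intervals` and a per-individual
#'   `genotypes` data.frame).
#' @examples
#' spec <- build_genome_spec(list(autosome_length = 20000, n_traps = 2,
#'                                sex_shared_length = 5000,
#'                                unique_lengths = c(500, 800)), seed = 1)
#' pop <- simulate_population(spec, 3, 3, pool_size = 5, seed = 2)
#' pop$individuals[[1]]
#' @export
simulate_population <- function(spec, n_females, n_males, pool_size = 0,
                                seed, force_trap = FALSE,
                                with_sequences = TRUE) {
  stopifnot(inherits(spec, "sex_genome_spec"))
  if (missing(seed)) stop("'seed' is required")
  if (n_females < 0 || n_males < 0 || pool_size < 0)
    stop("counts must be >= 0")
  system <- spec$system
  n_traps <- nrow(spec$traps)

  withr::with_seed(seed, {
    draw_alleles <- function() {
      if (n_traps == 0) return(matrix(integer(0), nrow = 0, ncol = 2))
      cbind(stats::rbinom(n_traps, 1L, spec$traps$p),
            stats::rbinom(n_traps, 1L, spec$traps$p))
    }
    make <- function(id, sex, forced = NULL) {
      al <- draw_alleles()
      if (!is.null(forced) && n_traps > 0) {
        al[1L, ] <- if (forced == "Aa") c(1L, 0L) else c(0L, 0L)
      }
      .make_individual(spec, id, sex, al, with_sequences = with_sequences)
    }
    het <- .het_sex(system); hom <- .hom_sex(system)
    forced_for <- function(sex) {
      if (!force_trap) return(NULL)
      if (sex == het) "Aa" else "aa"
    }
    females <- lapply(seq_len(n_females), function(i)
      make(sprintf("female_%d", i), "female", forced_for("female")))
    males <- lapply(seq_len(n_males), function(i)
      make(sprintf("male_%d", i), "male", forced_for("male")))
    pool <- lapply(seq_len(pool_size), function(i)
      make(sprintf("pool_%s_%d", hom, i), hom))

    individuals <- c(females, males)
    geno <- if (n_traps > 0) {
      all_ind <- c(individuals, pool)
      df <- as.data.frame(do.call(rbind, lapply(all_ind, function(x) x$genotypes)),
                          stringsAsFactors = FALSE)
      df$individual <- vapply(all_ind, function(x) x$id, character(1))
      df$sex <- vapply(all_ind, function(x) x$sex, character(1))
      df[, c("individual", "sex", spec$traps$id)]
    } else data.frame(individual = character(0), sex = character(0))

    structure(list(individuals = individuals, pool = pool, spec = spec,
                   system = system, seed = as.integer(seed),
                   truth = list(intervals = spec$truth, genotypes = geno)),
              class = "population")
  })
}

#' @export
print.population <- function(x, ...) {
  sexes <- vapply(x$individuals, function(i) i$sex, character(1))
  cat("Synthetic", x$system, "population:",
      sum(sexes == "female"), "female(s) +", sum(sexes == "male"),
      "male(s), pool of", length(x$pool), .hom_sex(x$system), "s\n", sep = " ")
  invisible(x)
}

#' Reference genome assembled from one individual of a population
#'
#' Emulates a collapsed de novo assembly of the first individual of the given
#' sex: one contig per autosome (a heterozygous trap insertion is assembled
#' into the contig), the shared sex chromosome, and - for the heterogametic
#' sex - the heterogametic chromosome. The spec's truth intervals are valid
#' coordinates on the heterogametic contig of this reference.
#'
#' @param population A [simulate_population()] result (with sequences).
#' @param sex `"female"` or `"male"`.
#' @return A named `Biostrings::DNAStringSet` of reference contigs.
#' @export
reference_genome <- function(population, sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(inherits(population, "population"))
  sexes <- vapply(population$individuals, function(i) i$sex, character(1))
  idx <- which(sexes == sex)
  if (length(idx) == 0) stop("no ", sex, " individual in the population")
  ind <- population$individuals[[idx[1L]]]
  if (is.null(ind$haplotypes))
    stop("population was simulated without sequences")
  spec <- population$spec

  contigs <- character(0); nms <- character(0)
  for (aname in names(spec$autosomes)) {
    here <- spec$traps$autosome == aname
    carried <- if (any(here)) ind$genotypes[spec$traps$id[here]] != "aa" else logical(0)
    contigs <- c(contigs, .splice_autosome(as.character(spec$autosomes[[aname]]),
                                           spec$traps[here, , drop = FALSE],
                                           carried))
    nms <- c(nms, aname)
  }
  contigs <- c(contigs, spec$shared_seq)
  nms <- c(nms, .shared_chrom(spec$system))
  if (ind$karyotype %in% c("ZW", "XY")) {
    contigs <- c(contigs, spec$het_seq)
    nms <- c(nms, .het_chrom(spec$system))
  }
  out <- Biostrings::DNAStringSet(contigs)
  names(out) <- nms
  out
}

.collect_haplotypes <- function(source) {
  if (inherits(source, "individual")) {
    if (is.null(source$haplotypes)) stop("individual carries no sequences")
    list(haps = source$haplotypes, ploidy = 2L)
  } else if (is.list(source) && all(vapply(source, inherits, logical(1), "individual"))) {
    haps <- do.call(c, lapply(source, function(ind) {
      h <- ind$haplotypes
      if (is.null(h)) stop("individual carries no sequences")
      names(h) <- paste0(ind$id, ":", names(h))
      h
    }))
    list(haps = haps, ploidy = 2L)
  } else if (methods::is(source, "DNAStringSet")) {
    list(haps = source, ploidy = 1L)
  } else stop("unsupported read source")
}

#' Simulate a short-read sequencing library
#'
#' Single-end reads of fixed length drawn uniformly over all source
#' haplotypes (both haplotypes of an individual, or of every pool member),
#' with independent substitution errors at `error_rate` and constant Q30
#' base qualities. `depth` is relative to the haploid genome length, so a
#' diploid position is covered `depth` times in expectation and a
#' single-copy (W/Y) region `depth/2` times. The expected read count is
#' `depth * haploid_length / read_length`.
#'
#' @param source An `individual`, a list of individuals (a pool library), or
#'   a bare `DNAStringSet` (haploid source).
#' @param depth Expected fold-coverage of the haploid genome (`> 0`).
#' @param read_length Read length in bp (`>= 31` so reads remain mappable
#'   with the default 31-bp seed).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed; the library regenerates byte-identically.
#' @param id Library identifier used in read names.
#' @param contaminate Optional list `list(poly_n = f1, low_q = f2)`: fractions
#'   of reads deliberately corrupted for QC testing (15% of bases set to N,
#'   or 60% of qualities dropped to Q2, respectively).
#' @return An object of class `read_set`: list with `seqs`
#'   (`DNAStringSet`, named), `quals` (`BStringSet`), and the simulation
#'   parameters.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 500), collapse = "")))
#' rs <- simulate_reads(ref, depth = 5, read_length = 50, seed = 1)
#' length(rs$seqs)
#' @export
simulate_reads <- function(source, depth = 20, read_length = 150,
                           error_rate = 0.001, seed, id = "lib",
                           contaminate = NULL) {
  if (missing(seed)) stop("'seed' is required")
  if (depth <= 0) stop("'depth' must be > 0")
  if (read_length < 31) stop("'read_length' must be >= 31")
  src <- .collect_haplotypes(source)
  haps <- as.character(src$haps)
  lens <- nchar(haps)
  if (read_length > min(lens))
    stop("'read_length' exceeds the shortest source contig")
  haploid_length <- sum(lens) / src$ploidy
  n_reads <- round(depth * haploid_length / read_length)

  withr::with_seed(seed, {
    # uniform over genome positions: weight haplotypes by eligible starts
    starts_per_hap <- lens - read_length + 1L
    hap_idx <- sample.int(length(haps), n_reads, replace = TRUE,
                          prob = starts_per_hap)
    start <- floor(stats::runif(n_reads) * starts_per_hap[hap_idx]) + 1L
    reads <- substring(haps[hap_idx], start, start + read_length - 1L)

    n_err <- stats::rbinom(n_reads, read_length, error_rate)
    for (i in which(n_err > 0L)) {
      chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      pos <- sample.int(read_length, n_err[i])
      for (j in pos)
        chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
      reads[i] <- paste(chars, collapse = "")
    }

    quals <- strrep("?", read_length)       # constant Q30 (Phred+33)
    quals <- rep(quals, n_reads)
    if (!is.null(contaminate)) {
      f_n <- contaminate$poly_n %||% 0
      f_q <- contaminate$low_q %||% 0
      n_polyn <- round(f_n * n_reads)
      n_lowq <- round(f_q * n_reads)
      corrupt <- sample.int(n_reads, min(n_reads, n_polyn + n_lowq))
      polyn_ix <- utils::head(corrupt, n_polyn)
      lowq_ix <- utils::tail(corrupt, length(corrupt) - length(polyn_ix))
      for (i in polyn_ix) {
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        chars[sample.int(read_length, ceiling(0.15 * read_length))] <- "N"
        reads[i] <- paste(chars, collapse = "")
      }
      for (i in lowq_ix) {
        chars <- strsplit(quals[i], "", fixed = TRUE)[[1L]]
        chars[sample.int(read_length, ceiling(0.6 * read_length))] <- "#"  # Q2
        quals[i] <- paste(chars, collapse = "")
      }
    }

    seqs <- Biostrings::DNAStringSet(reads)
    names(seqs) <- sprintf("%s_r%06d", id, seq_len(n_reads))
    qs <- Biostrings::BStringSet(quals)
    names(qs) <- names(seqs)
    structure(list(id = id, seqs = seqs, quals = qs,
                   read_length = as.integer(read_length), depth = depth,
                   error_rate = error_rate, seed = as.integer(seed)),
              class = "read_set")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.read_set <- function(x, ...) {
  cat("Read set", x$id, "-", length(x$seqs), "reads x", x$read_length,
      "bp (depth", x$depth, ", error rate", x$error_rate, ")\n")
  invisible(x)
}

#' Write/read a read set as FASTQ (Phred+33)
#'
#' @param reads A `read_set` (or any named `DNAStringSet` plus qualities).
#' @param path Output file; `.gz` suffix compresses.
#' @return `write_fastq` returns `path` invisibly; `read_fastq` returns a
#'   `read_set`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  Biostrings::writeXStringSet(reads$seqs, filepath = path, format = "fastq",
                              qualities = reads$quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @param id Library id to attach on import.
#' @export
read_fastq <- function(path, id = sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  quals <- S4Vectors::mcols(seqs)$qualities
  names(quals) <- names(seqs)
  structure(list(id = id, seqs = seqs, quals = quals,
                 read_length = if (length(seqs)) max(Biostrings::width(seqs)) else 0L,
                 depth = NA_real_, error_rate = NA_real_, seed = NA_integer_),
            class = "read_set")
}

#' Write reference contigs as 60-column wrapped FASTA
#' @param reference A named `DNAStringSet`.
#' @param path Output file.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, filepath = path, width = 60L)
  invisible(path)
}

#' Export the ground truth of a synthetic population
#'
#' Writes the heterogametic-unique truth intervals as a 0-based half-open BED
#' file and the per-individual trap genotypes as JSON.
#'
#' @param population A [simulate_population()] result.
#' @param bed_path,json_path Output paths.
#' @export
write_truth <- function(population, bed_path, json_path) {
  stopifnot(inherits(population, "population"))
  iv <- population$truth$intervals
  utils::write.table(iv, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(population$truth$genotypes, json_path,
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(c(bed = bed_path, json = json_path))
}
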
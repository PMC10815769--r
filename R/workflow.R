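#' Default run configuration
#'
#' Builds the full nested configuration for [run_workflow()], with every
#' tunable at its default. Thresholds mirror the screening protocol the
#' package implements: reads with more than 10% N or more than 50% of bases
#' at Q <= 5 are removed; k = 21 for the k-mer spectrum; a 31-bp exact seed
#' and 5-mismatch budget for mapping; strict zero-coverage subtraction; at
#' most 2 primer mismatches. Unknown keys are rejected.
#'
#' The global `seed` fans out to per-stage child seeds by the fixed rule
#' `child = seed * 1000 + stage_offset` (genome 1, population 2, group
#' library i uses 10 + i, pool library 50), so each stage is individually
#' reproducible.
#'
#' @param ... Named overrides; nested lists are merged (e.g.
#'   `cohort = list(pool_size = 20)` keeps the other cohort defaults).
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    system = "ZW",
    output_dir = NULL,
    genome = list(autosome_length = 200000L, n_autosomes = 1L,
                  sex_shared_length = 20000L,
                  unique_lengths = c(2000L, 3000L, 5000L),
                  gametolog_divergence = 0.02,
                  n_traps = 10L, trap_length = 400L,
                  trap_p_range = c(0.2, 0.8)),
    cohort = list(n_females = 3L, n_males = 3L, pool_size = 15L,
                  force_trap = FALSE),
    reads = list(depth = 20, pool_depth = 30, read_length = 150L,
                 error_rate = 0.001,
                 contaminate = list(poly_n = 0.01, low_q = 0.01)),
    qc = list(max_n_fraction = 0.10, lowq_fraction = 0.50, q_threshold = 5L),
    kmer = list(k = 21L),
    mapping = list(seed_k = 31L, max_mismatches = 5L),
    screen = list(granularity = "interval", min_depth = 1L,
                  covered_fraction = 0.5, min_reads = 1L,
                  max_n_fraction = 0.1, max_repeat_fraction = 0.5,
                  repeat_k = 21L, min_length = 200L,
                  ratio_threshold = 5, pseudocount = 1),
    markers = list(enabled = FALSE, gel_resolution = 20L,
                   max_mismatches = 2L))
  overrides <- list(...)
  merge_checked <- function(base, over, path = "") {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown))
      stop("unknown config entries: ",
           paste0(path, unknown, collapse = ", "))
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_checked(base[[nm]], over[[nm]],
                                    paste0(path, nm, "$"))
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_checked(defaults, overrides)
  cfg$system <- match.arg(cfg$system, c("ZW", "XY"))
  structure(cfg, class = c("run_config", "list"))
}

#' Read/write a run configuration as YAML
#'
#' The YAML round-trips: serialize -> parse -> serialize is byte-identical.
#'
#' @param path YAML file.
#' @return `read_run_config` returns a validated `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$output_dir <- NULL
  writeLines(yaml::as.yaml(x), path)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

.child_seed <- function(seed, offset) as.integer(seed) * 1000L + offset

#' Run the end-to-end screening workflow on a synthetic cohort
#'
#' Executes simulate -> QC -> k-mer genome-size estimate -> map -> screen ->
#' (optional) marker validation, in order, on a fully synthetic diploid
#' cohort with ground truth. First-round candidates (same-sex common regions
#' minus all opposite-sex coverage) are computed for both directions and
#' used for a preliminary system inference; the single-sex pool is then
#' subtracted from the candidates of the heterogametic-candidate direction
#' (the only direction its sex can legitimately filter), and composition
#' filters finish both sides.
#'
#' @param config A [run_config()] (or a list of overrides passed to it).
#' @return An object of class `run_result`: population, references, QC
#'   reports, genome-size estimate, first-round and final candidate
#'   `GRanges` per direction, attrition tables, `summary`
#'   ([summarize_screen()]), `system_call` ([infer_system()]), truth
#'   comparison (`jaccard`, traps retained), optional marker table, and a
#'   `manifest`. When `config$output_dir` is set, BED/FASTA/TSV exports,
#'   the truth files, a Markdown report and `manifest.json` are written
#'   there.
#' @examples
#' \donttest{
#' cfg <- run_config(genome = list(autosome_length = 30000L,
#'                                 sex_shared_length = 8000L,
#'                                 unique_lengths = c(800L, 1200L),
#'                                 n_traps = 2L),
#'                   cohort = list(pool_size = 5L))
#' res <- run_workflow(cfg)
#' res$system_call
#' }
#' @export
run_workflow <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  seed <- config$seed
  system <- config$system

  # --- simulate ---------------------------------------------------------
  spec <- build_genome_spec(c(config$genome, list(system = system)),
                            seed = .child_seed(seed, 1L))
  pop <- simulate_population(spec, config$cohort$n_females,
                             config$cohort$n_males,
                             pool_size = config$cohort$pool_size,
                             seed = .child_seed(seed, 2L),
                             force_trap = isTRUE(config$cohort$force_trap))
  female_ref <- reference_genome(pop, "female")
  male_ref <- reference_genome(pop, "male")
  libs <- lapply(seq_along(pop$individuals), function(i) {
    ind <- pop$individuals[[i]]
    simulate_reads(ind, depth = config$reads$depth,
                   read_length = config$reads$read_length,
                   error_rate = config$reads$error_rate,
                   seed = .child_seed(seed, 10L + i), id = ind$id,
                   contaminate = config$reads$contaminate)
  })
  names(libs) <- vapply(pop$individuals, function(x) x$id, character(1))
  pool_lib <- if (length(pop$pool)) {
    simulate_reads(pop$pool, depth = config$reads$pool_depth,
                   read_length = config$reads$read_length,
                   error_rate = config$reads$error_rate,
                   seed = .child_seed(seed, 50L),
                   id = paste0("pool_", .hom_sex(system)))
  } else NULL
  tick("simulate")

  # --- qc ---------------------------------------------------------------
  qc <- lapply(c(libs, if (!is.null(pool_lib)) list(pool = pool_lib)),
               function(l) filter_reads(l, config$qc$max_n_fraction,
                                        config$qc$lowq_fraction,
                                        config$qc$q_threshold))
  qc_reports <- do.call(rbind, lapply(names(qc), function(nm) {
    cbind(library = nm, qc[[nm]]$report)
  }))
  clean <- lapply(qc, function(x) x$reads)
  tick("qc")

  # --- k-mer genome size ------------------------------------------------
  gsize <- estimate_genome_size(kmer_histogram(clean[[1L]], config$kmer$k))
  tick("kmer")

  # --- map --------------------------------------------------------------
  sexes <- vapply(pop$individuals, function(x) x$sex, character(1))
  f_index <- build_index(female_ref, config$mapping$seed_k)
  m_index <- build_index(male_ref, config$mapping$seed_k)
  track_on <- function(read_set, index, ref, sex) {
    aln <- map_reads(read_set, index, config$mapping$max_mismatches)
    coverage_track(aln, ref, id = read_set$id, sex = sex)
  }
  group_ids <- names(libs)
  tracks_f_ref <- lapply(group_ids, function(nm)
    track_on(clean[[nm]], f_index, female_ref, sexes[[match(nm, group_ids)]]))
  tracks_m_ref <- lapply(group_ids, function(nm)
    track_on(clean[[nm]], m_index, male_ref, sexes[[match(nm, group_ids)]]))
  names(tracks_f_ref) <- names(tracks_m_ref) <- group_ids
  tick("map")

  # --- screen: first round (both directions) ----------------------------
  scr <- config$screen
  is_f <- sexes == "female"
  first_round <- list(
    female = subtract_covered(
      common_regions(tracks_f_ref[is_f], scr$min_depth, scr$covered_fraction,
                     scr$granularity),
      tracks_f_ref[!is_f], scr$min_reads, scr$granularity),
    male = subtract_covered(
      common_regions(tracks_m_ref[!is_f], scr$min_depth, scr$covered_fraction,
                     scr$granularity),
      tracks_m_ref[is_f], scr$min_reads, scr$granularity))
  prelim <- infer_system(summarize_screen(first_round$female, first_round$male),
                         scr$ratio_threshold, scr$pseudocount)

  # pool subtraction: only the direction whose homogametic sex matches the
  # pool can be filtered by it
  pool_sex <- if (length(pop$pool)) pop$pool[[1L]]$sex else NA_character_
  pool_target <- if (identical(pool_sex, "male")) "female"
                 else if (identical(pool_sex, "female")) "male" else NA
  post_pool <- first_round
  pool_track <- NULL
  if (!is.null(pool_lib) && !is.na(pool_target)) {
    target_ref <- if (pool_target == "female") female_ref else male_ref
    target_index <- if (pool_target == "female") f_index else m_index
    pool_track <- track_on(clean[["pool"]], target_index, target_ref, pool_sex)
    post_pool[[pool_target]] <- pool_filter(first_round[[pool_target]],
                                            pool_track, target = pool_target,
                                            min_reads = scr$min_reads,
                                            granularity = scr$granularity)
  }

  final <- list(
    female = composition_filters(post_pool$female, female_ref,
                                 scr$max_n_fraction, scr$max_repeat_fraction,
                                 scr$repeat_k, scr$min_length),
    male = composition_filters(post_pool$male, male_ref,
                               scr$max_n_fraction, scr$max_repeat_fraction,
                               scr$repeat_k, scr$min_length))

  attrition <- lapply(c("female", "male"), function(tg) {
    stages <- list(first_round = first_round[[tg]],
                   pool = post_pool[[tg]], final = final[[tg]])
    data.frame(target = paste0(tg, "-specific"), stage = names(stages),
               count = vapply(stages, length, integer(1)),
               total_bp = vapply(stages, function(g)
                 sum(as.numeric(GenomicRanges::width(g))), numeric(1)),
               row.names = NULL)
  })
  attrition <- do.call(rbind, attrition)

  summary <- summarize_screen(final$female, final$male, attrition = attrition)
  call <- infer_system(summary, scr$ratio_threshold, scr$pseudocount)
  tick("screen")

  # --- truth comparison -------------------------------------------------
  het_target <- .het_sex(system)
  truth_gr <- GenomicRanges::GRanges(
    pop$truth$intervals$contig,
    IRanges::IRanges(pop$truth$intervals$start + 1L, pop$truth$intervals$end))
  het_final <- final[[het_target]]
  jac <- interval_jaccard(het_final, truth_gr)
  # trap retention: any final candidate (either side) overlapping a trap
  # insertion footprint of the matching reference
  traps_retained <- 0L
  if (nrow(spec$traps) > 0) {
    for (side in c("female", "male")) {
      ref_ind <- pop$individuals[[which(sexes == side)[1L]]]
      gr <- final[[side]]
      if (length(gr) == 0) next
      tr <- spec$traps
      carried <- ref_ind$genotypes[tr$id] != "aa"
      if (!any(carried)) next
      tr <- tr[carried, , drop = FALSE]
      # reference coordinates shift by preceding carried insertions
      for (aname in unique(tr$autosome)) {
        sel <- tr[tr$autosome == aname, , drop = FALSE]
        sel <- sel[order(sel$position), , drop = FALSE]
        shift <- cumsum(c(0L, nchar(sel$seq)))[seq_len(nrow(sel))]
        tgr <- GenomicRanges::GRanges(
          aname, IRanges::IRanges(sel$position + shift + 1L,
                                  sel$position + shift + nchar(sel$seq)))
        traps_retained <- traps_retained +
          sum(IRanges::overlapsAny(tgr, gr))
      }
    }
  }
  truth_eval <- list(jaccard = jac, traps_retained = traps_retained,
                     truth = truth_gr)

  # --- optional marker validation ---------------------------------------
  marker_table <- NULL
  if (isTRUE(config$markers$enabled)) {
    mk <- design_synthetic_markers(pop)
    marker_table <- genotype_cohort(pop$individuals, mk$pairs, mk$classes,
                                    system = system,
                                    gel_resolution = config$markers$gel_resolution,
                                    max_mismatches = config$markers$max_mismatches)
  }
  tick("markers")

  manifest <- list(
    tool = "sexscreen", version = as.character(utils::packageVersion("sexscreen")),
    seed = as.integer(seed), system = system,
    config_hash = .config_hash(config),
    genome_size_estimate = gsize$genome_size,
    preliminary_system = prelim$system,
    final_system = call$system,
    stage_seconds = as.list(timings),
    attrition = attrition,
    checksums = list())

  result <- structure(list(
    config = config, population = pop,
    references = list(female = female_ref, male = male_ref),
    qc_reports = qc_reports, genome_size = gsize,
    first_round = first_round, final = final, attrition = attrition,
    summary = summary, preliminary_system = prelim, system_call = call,
    truth_eval = truth_eval, marker_table = marker_table,
    pool_track = pool_track, manifest = manifest),
    class = "run_result")

  if (!is.null(config$output_dir)) {
    result$manifest$checksums <- .write_run_outputs(result, config$output_dir)
  }
  result
}

.write_run_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (side in c("female", "male")) {
    prefix <- file.path(dir, paste0(side, "_specific"))
    ref <- result$references[[side]]
    p <- export_candidates(result$final[[side]], ref, prefix,
                           summary = result$summary)
    paths <- c(paths, p)
  }
  tp <- write_truth(result$population, file.path(dir, "truth.bed"),
                    file.path(dir, "truth.json"))
  paths <- c(paths, tp)
  rp <- file.path(dir, "report.md")
  writeLines(report(result), rp)
  paths <- c(paths, report = rp)
  cfgp <- file.path(dir, "config.yaml")
  write_run_config(result$config, cfgp)
  paths <- c(paths, config = cfgp)
  sums <- as.list(tools::md5sum(unname(paths)))
  mp <- file.path(dir, "manifest.json")
  manifest <- result$manifest
  manifest$checksums <- sums
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  sums
}

#' Human-readable report of a workflow run
#'
#' @param result A [run_workflow()] result.
#' @return Character vector of Markdown lines.
#' @export
report <- function(result) {
  stopifnot(inherits(result, "run_result"))
  s <- result$summary
  lines <- c(
    "# Sex-specific sequence screening report", "",
    sprintf("- system simulated: %s (seed %d)", result$config$system,
            result$config$seed),
    sprintf("- k-mer genome-size estimate: %s bp",
            if (result$genome_size$determined)
              format(round(result$genome_size$genome_size), big.mark = ",")
            else "undetermined"),
    sprintf("- preliminary system call (first round): %s",
            result$preliminary_system$system),
    sprintf("- final system call: %s (ratio %.2f)",
            result$system_call$system, result$system_call$ratio), "",
    "## Final candidates", "")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, if (s$count[i] > 0)
      sprintf("- %s: %d sequences, total %.0f bp, mean length %.0f bp",
              s$target[i], s$count[i], s$total_bp[i], s$mean_bp[i])
      else sprintf("- %s: no sequences were obtained", s$target[i]))
  }
  lines <- c(lines, "", "## Stage attrition", "",
             "| target | stage | count | total bp |",
             "|---|---|---|---|")
  a <- result$attrition
  for (i in seq_len(nrow(a)))
    lines <- c(lines, sprintf("| %s | %s | %d | %.0f |", a$target[i],
                              a$stage[i], a$count[i], a$total_bp[i]))
  lines <- c(lines, "", "## QC", "",
             "| library | input | removed polyN | removed lowQ | retained |",
             "|---|---|---|---|---|")
  q <- result$qc_reports
  for (i in seq_len(nrow(q)))
    lines <- c(lines, sprintf("| %s | %d | %d | %d | %d |", q$library[i],
                              q$input[i], q$removed_polyN[i],
                              q$removed_lowq[i], q$retained[i]))
  if (!is.null(result$marker_table)) {
    m <- result$marker_table
    lines <- c(lines, "", "## Marker validation", "",
               sprintf("- %d calls, %.1f%% correct", nrow(m),
                       100 * mean(m$correct)))
  }
  lines
}

#' @export
print.run_result <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}

#' Design demonstration markers from a synthetic population
#'
#' Constructs one dominant and one gametologous primer pair directly from
#' the known heterogametic-chromosome sequence: the dominant pair sits
#' entirely inside the largest heterogametic-unique insertion; the
#' gametologous pair uses flanking windows in the gametolog that are
#' identical between the two sex-chromosome copies and bracket the smallest
#' insertion, so the heterogametic sex yields a long (insertion-containing)
#' and a short product, the homogametic sex only the short one.
#'
#' @param population A [simulate_population()] result (with sequences).
#' @return List with `pairs` (two [primer_pair()]s) and `classes`
#'   (`c("dominant", "gametologous")`).
#' @export
design_synthetic_markers <- function(population) {
  stopifnot(inherits(population, "population"))
  spec <- population$spec
  truth <- spec$truth
  if (nrow(truth) == 0) stop("spec carries no heterogametic-unique insertions")
  het <- spec$het_seq
  shared <- spec$shared_seq
  lens <- truth$end - truth$start

  # dominant: 20-mer primers 100 bp and 400 bp into the largest insertion
  i <- which.max(lens)
  s <- truth$start[i]
  fwd <- substr(het, s + 101, s + 120)
  rev <- .revcomp_chr(substr(het, s + 381, s + 400))
  dominant <- primer_pair("SYN-DOM", fwd, rev)

  # gametologous: conserved 20-mers flanking the smallest insertion
  j <- which.min(lens)
  s <- truth$start[j]; e <- truth$end[j]
  w_to_shared <- function(x) x - sum(lens[truth$end <= x])
  find_window <- function(anchor, direction) {
    for (d in seq(30L, 600L, by = 1L)) {
      w0 <- if (direction == "left") anchor - d - 20L else anchor + d
      if (w0 < 0) break
      win <- substr(het, w0 + 1L, w0 + 20L)
      z0 <- w_to_shared(w0)
      zin <- substr(shared, z0 + 1L, z0 + 20L)
      if (nchar(win) == 20L && identical(win, zin)) return(list(start = w0, seq = win))
    }
    stop("no conserved flanking window found; increase the gametolog size or lower divergence")
  }
  left <- find_window(s, "left")
  right <- find_window(e, "right")
  gam <- primer_pair("SYN-GAM", left$seq, .revcomp_chr(right$seq),
                     product_min = 50L,
                     product_max = (e - s) + (s - left$start) +
                       (right$start + 20L - e) + 50L)
  list(pairs = list(dominant, gam), classes = c("dominant", "gametologous"))
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
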
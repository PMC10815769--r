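#' Define a PCR primer pair
#'
#' Primers are 5'->3' sequences of 15-35 nt over the IUPAC alphabet
#' (ambiguity codes such as W are allowed and match any compatible base at no
#' mismatch cost). The product-size window bounds which forward/reverse site
#' combinations count as amplicons.
#'
#' @param name Marker name.
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param product_min,product_max Product-size window in bp, inclusive of
#'   both primer footprints (default 50-2000).
#' @return An object of class `primer_pair`.
#' @examples
#' primer_pair("PB1", "GGATCTCATTTGTGAGCCTACATGT", "CCCACAGCTTGCTTTCCWTGTTTAG")
#' @export
primer_pair <- function(name, forward, reverse,
                        product_min = 50L, product_max = 2000L) {
  check <- function(s, what) {
    s <- toupper(s)
    if (nchar(s) < 15 || nchar(s) > 35)
      stop(what, " primer must be 15-35 nt")
    if (!grepl("^[ACGTRYSWKMBDHVN]+$", s))
      stop(what, " primer contains non-IUPAC letters")
    s
  }
  stopifnot(product_min > 0, product_max >= product_min)
  structure(list(name = name, forward = check(forward, "forward"),
                 reverse = check(reverse, "reverse"),
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Primer pair", x$name, "\n  F:", x$forward, "\n  R:", x$reverse,
      "\n  product window:", x$product_min, "-", x$product_max, "bp\n")
  invisible(x)
}

# IUPAC-aware mismatch-bounded matching of one oriented primer sequence
# against the plus strand of each template; returns 0-based starts and
# mismatch counts. Ambiguity codes on either side match when the base sets
# intersect (Biostrings fixed = FALSE semantics; the test oracle replicates
# this by hand).
.primer_sites <- function(primer_seq, templates, max_mismatches) {
  pat <- Biostrings::DNAString(primer_seq)
  hits <- lapply(seq_along(templates), function(i) {
    m <- Biostrings::matchPattern(pat, templates[[i]],
                                  max.mismatch = max_mismatches,
                                  with.indels = FALSE, fixed = FALSE)
    if (length(m) == 0)
      return(data.frame(template = character(0), start = integer(0),
                        end = integer(0), mismatches = integer(0)))
    mm <- Biostrings::neditAt(pat, templates[[i]],
                              at = Biostrings::start(m), fixed = FALSE)
    data.frame(template = names(templates)[i],
               start = Biostrings::start(m) - 1L,
               end = Biostrings::end(m),      # 0-based half-open
               mismatches = mm, stringsAsFactors = FALSE)
  })
  do.call(rbind, hits)
}

#' Find all binding sites of a primer on a reference
#'
#' Reports every position on either strand where the primer matches with at
#' most `max_mismatches` substitutions, IUPAC ambiguity codes matching any
#' compatible base without penalty - the in-silico specificity check run
#' before trusting a marker.
#'
#' @param primer A primer sequence (character) or a `primer_pair` (its
#'   forward primer is used).
#' @param reference Named `DNAStringSet`.
#' @param max_mismatches Mismatch budget (default 2).
#' @return A data.frame with columns `contig`, `start` (0-based), `end`
#'   (half-open), `strand`, `mismatches`.
#' @export
primer_specificity <- function(primer, reference, max_mismatches = 2L) {
  seq <- if (inherits(primer, "primer_pair")) primer$forward else toupper(primer)
  if (nchar(seq) < 15) stop("primer shorter than 15 nt")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", seq)) stop("primer contains non-IUPAC letters")
  if (is.null(names(reference))) stop("reference contigs must be named")
  templates <- Biostrings::DNAStringSet(reference)

  fwd <- .primer_sites(seq, templates, max_mismatches)
  rev <- .primer_sites(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))),
    templates, max_mismatches)
  out <- rbind(
    if (nrow(fwd)) cbind(fwd, strand = "+") else NULL,
    if (nrow(rev)) cbind(rev, strand = "-") else NULL)
  if (is.null(out))
    out <- data.frame(template = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      strand = character(0))
  names(out)[names(out) == "template"] <- "contig"
  out <- out[order(out$contig, out$start, out$strand), ]
  rownames(out) <- NULL
  out[, c("contig", "start", "end", "strand", "mismatches")]
}

#' Predict PCR amplicons on a set of templates
#'
#' An amplicon is emitted for every forward-primer site and downstream
#' reverse-complemented reverse-primer site on the same template whose span
#' - from the 5' end of the forward site to the 5' end of the reverse site,
#' inclusive of both primer footprints - lies within the pair's product
#' window. Both template orientations are considered (the reverse primer may
#' equally act as the left primer with the forward primer on the minus
#' strand), so amplicon lengths are invariant under reverse-complementing
#' the templates. Zero amplicons is a valid result.
#'
#' @param pair A [primer_pair()].
#' @param templates Named `DNAStringSet` (e.g. an individual's haplotypes).
#' @param max_mismatches Per-primer mismatch budget (default 2).
#' @return A data.frame of class `amplicons` with columns `template`,
#'   `start` (0-based), `end` (half-open), `length`, `forward_mismatches`,
#'   `reverse_mismatches`, `orientation` (`"FR"` or `"RF"`).
#' @export
in_silico_pcr <- function(pair, templates, max_mismatches = 2L) {
  stopifnot(inherits(pair, "primer_pair"))
  if (length(templates) == 0) stop("'templates' must be non-empty")
  templates <- Biostrings::DNAStringSet(templates)
  if (is.null(names(templates)))
    names(templates) <- sprintf("template_%d", seq_along(templates))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))

  span <- function(left_sites, right_sites) {
    if (is.null(left_sites) || is.null(right_sites) ||
        nrow(left_sites) == 0 || nrow(right_sites) == 0) return(NULL)
    rows <- list()
    for (i in seq_len(nrow(left_sites))) {
      rs <- right_sites[right_sites$template == left_sites$template[i] &
                          right_sites$start >= left_sites$start[i], , drop = FALSE]
      if (nrow(rs) == 0) next
      len <- rs$end - left_sites$start[i]
      ok <- len >= pair$product_min & len <= pair$product_max
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        template = left_sites$template[i], start = left_sites$start[i],
        end = rs$end[ok], length = len[ok],
        left_mm = left_sites$mismatches[i], right_mm = rs$mismatches[ok],
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) return(NULL)
    do.call(rbind, rows)
  }

  f_plus <- .primer_sites(pair$forward, templates, max_mismatches)
  r_rc <- .primer_sites(rc(pair$reverse), templates, max_mismatches)
  fr <- span(f_plus, r_rc)
  if (!is.null(fr)) {
    fr$forward_mismatches <- fr$left_mm
    fr$reverse_mismatches <- fr$right_mm
    fr$orientation <- "FR"
  }
  r_plus <- .primer_sites(pair$reverse, templates, max_mismatches)
  f_rc <- .primer_sites(rc(pair$forward), templates, max_mismatches)
  rf <- span(r_plus, f_rc)
  if (!is.null(rf)) {
    rf$forward_mismatches <- rf$right_mm
    rf$reverse_mismatches <- rf$left_mm
    rf$orientation <- "RF"
  }
  out <- rbind(fr, rf)
  if (is.null(out))
    out <- data.frame(template = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      left_mm = integer(0), right_mm = integer(0),
                      forward_mismatches = integer(0),
                      reverse_mismatches = integer(0),
                      orientation = character(0))
  out <- out[, c("template", "start", "end", "length",
                 "forward_mismatches", "reverse_mismatches", "orientation")]
  out <- unique(out[order(out$template, out$start, out$length), ])
  rownames(out) <- NULL
  class(out) <- c("amplicons", "data.frame")
  out
}

#' Predicted gel band pattern of an individual
#'
#' Pools the amplicon lengths from both haplotypes of a diploid genome and
#' merges lengths that a gel cannot resolve: single-linkage clusters of
#' lengths within `gel_resolution` bp of a neighbour collapse into one band
#' (reported at the cluster mean, rounded).
#'
#' @param amplicons An [in_silico_pcr()] result (amplicons from both
#'   haplotypes pooled), or a numeric vector of product lengths.
#' @param gel_resolution Minimum resolvable size difference in bp
#'   (default 20).
#' @param individual Identifier recorded on the pattern.
#' @return An object of class `band_pattern`: list with `individual`,
#'   `bands` (strictly increasing sizes differing pairwise by more than
#'   `gel_resolution`) and `n_bands`.
#' @examples
#' band_pattern(c(400, 410, 600))   # 2 bands
#' @export
band_pattern <- function(amplicons, gel_resolution = 20L, individual = NA_character_) {
  lens <- if (is.numeric(amplicons)) amplicons else amplicons$length
  lens <- sort(lens)
  bands <- numeric(0)
  if (length(lens) > 0) {
    grp <- cumsum(c(1L, as.integer(diff(lens) > gel_resolution)))
    bands <- round(tapply(lens, grp, mean))
    bands <- as.numeric(sort(bands))
  }
  structure(list(individual = individual, bands = bands,
                 n_bands = length(bands),
                 gel_resolution = as.integer(gel_resolution)),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  cat("Band pattern", if (!is.na(x$individual)) paste0("[", x$individual, "]"),
      ":", if (x$n_bands) paste(x$bands, collapse = ", ") else "no bands", "\n")
  invisible(x)
}

#' Classify a marker as dominant, gametologous or non-specific
#'
#' Runs the in-silico PCR on a heterogametic-sex and a homogametic-sex
#' diploid genome and compares band patterns: `dominant` markers amplify
#' only in the heterogametic sex (band presence = heterogametic); markers
#' spanning a gametolog pair with a heterogametic-specific insertion give
#' more bands in the heterogametic sex with the shared band as an internal
#' control (`gametologous`, the two-band/one-band pattern); identical
#' patterns in both sexes are `non_specific`.
#'
#' @param pair A [primer_pair()].
#' @param female_genome,male_genome Named `DNAStringSet`s of the two diploid
#'   genomes (both haplotypes).
#' @param system `"ZW"` (female heterogametic, default) or `"XY"`.
#' @param gel_resolution Passed to [band_pattern()].
#' @param max_mismatches Passed to [in_silico_pcr()].
#' @return A list of class `marker_class`: `class` (`"dominant"`,
#'   `"gametologous"` or `"non_specific"`), `het_bands`, `hom_bands`,
#'   `system`.
#' @export
classify_marker <- function(pair, female_genome, male_genome,
                            system = c("ZW", "XY"), gel_resolution = 20L,
                            max_mismatches = 2L) {
  system <- match.arg(system)
  het_genome <- if (system == "ZW") female_genome else male_genome
  hom_genome <- if (system == "ZW") male_genome else female_genome
  het <- band_pattern(in_silico_pcr(pair, het_genome, max_mismatches),
                      gel_resolution)
  hom <- band_pattern(in_silico_pcr(pair, hom_genome, max_mismatches),
                      gel_resolution)
  same <- het$n_bands == hom$n_bands &&
    (het$n_bands == 0 || all(abs(het$bands - hom$bands) <= gel_resolution))
  cls <- if (same) "non_specific"
         else if (hom$n_bands == 0 && het$n_bands >= 1) "dominant"
         else if (het$n_bands > hom$n_bands && hom$n_bands > 0) "gametologous"
         else "non_specific"
  structure(list(class = cls, het_bands = het, hom_bands = hom,
                 system = system, marker = pair$name),
            class = "marker_class")
}

#' @export
print.marker_class <- function(x, ...) {
  cat("Marker", x$marker, "-", x$class, "(", x$system, "system;",
      x$het_bands$n_bands, "heterogametic vs", x$hom_bands$n_bands,
      "homogametic bands )\n")
  invisible(x)
}

#' Call genetic sex from a band pattern
#'
#' Decision rules for the two marker classes in a ZW system (mirrored for
#' XY): a dominant marker calls female on any band and male on none; a
#' gametologous marker calls female on two bands, male on one, and
#' `invalid` on zero bands, since the shared band doubles as an internal
#' amplification control. Non-specific markers cannot sex the system.
#'
#' @param pattern A [band_pattern()].
#' @param marker_class `"dominant"` or `"gametologous"` (or a
#'   [classify_marker()] result).
#' @param system `"ZW"` (default) or `"XY"`.
#' @return An object of class `sex_call`: list with `individual`, `call`
#'   (`"female"`, `"male"` or `"invalid"`) and `rule`.
#' @export
call_sex <- function(pattern, marker_class, system = c("ZW", "XY")) {
  system <- match.arg(system)
  if (inherits(marker_class, "marker_class")) marker_class <- marker_class$class
  marker_class <- match.arg(marker_class, c("dominant", "gametologous",
                                            "non_specific"))
  if (marker_class == "non_specific")
    stop("marker cannot sex this system: non-specific band patterns")
  stopifnot(inherits(pattern, "band_pattern"))
  n <- pattern$n_bands
  het <- if (system == "ZW") "female" else "male"
  hom <- if (system == "ZW") "male" else "female"
  res <- if (marker_class == "dominant") {
    if (n >= 1) list(call = het, rule = "dominant: band present -> heterogametic")
    else list(call = hom, rule = "dominant: no band -> homogametic")
  } else {
    if (n >= 2) list(call = het, rule = "gametologous: two bands -> heterogametic")
    else if (n == 1) list(call = hom, rule = "gametologous: one band -> homogametic")
    else list(call = "invalid", rule = "gametologous: no bands -> amplification failure")
  }
  structure(list(individual = pattern$individual, call = res$call,
                 rule = res$rule, system = system),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat("Sex call", if (!is.na(x$individual)) paste0("[", x$individual, "]"),
      ":", x$call, "-", x$rule, "\n")
  invisible(x)
}

#' Genotype a cohort of individuals with a set of markers
#'
#' Applies [in_silico_pcr()], [band_pattern()] and [call_sex()] per
#' individual and marker.
#'
#' @param individuals List of `individual` objects (with haplotype
#'   sequences).
#' @param pairs List of [primer_pair()]s.
#' @param classes Character vector (or list of `marker_class`) parallel to
#'   `pairs`.
#' @param system `"ZW"` or `"XY"`.
#' @param gel_resolution,max_mismatches Passed through.
#' @return A data.frame with one row per individual x marker: `individual`,
#'   `true_sex`, `marker`, `n_bands`, `call`, `correct`.
#' @export
genotype_cohort <- function(individuals, pairs, classes,
                            system = c("ZW", "XY"), gel_resolution = 20L,
                            max_mismatches = 2L) {
  system <- match.arg(system)
  rows <- lapply(individuals, function(ind) {
    do.call(rbind, lapply(seq_along(pairs), function(j) {
      amp <- in_silico_pcr(pairs[[j]], ind$haplotypes, max_mismatches)
      bp <- band_pattern(amp, gel_resolution, individual = ind$id)
      call <- call_sex(bp, classes[[j]], system)
      data.frame(individual = ind$id, true_sex = ind$sex,
                 marker = pairs[[j]]$name, n_bands = bp$n_bands,
                 call = call$call, correct = call$call == ind$sex,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
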
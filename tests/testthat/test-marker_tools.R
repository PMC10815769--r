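test_that("primer pairs validate length and alphabet", {
  pp <- primer_pair("PB1", "GGATCTCATTTGTGAGCCTACATGT", "CCCACAGCTTGCTTTCCWTGTTTAG")
  expect_identical(pp$reverse, "CCCACAGCTTGCTTTCCWTGTTTAG")
  expect_error(primer_pair("x", "ACGTACGT", "ACGTACGTACGTACGTACGT"), "15-35")
  expect_error(primer_pair("x", "ACGTACGTACGTACG!", "ACGTACGTACGTACGT"),
               "IUPAC")
})

test_that("primer specificity finds planted sites within the mismatch budget", {
  withr::with_seed(31, {
    bg <- random_dna_chr(4000)
    primer <- substr(bg, 1001, 1020)
    # plant a 2-mismatch copy and a 3-mismatch copy
    mutate_at <- function(s, at) {
      ch <- strsplit(s, "")[[1]]
      for (j in at) ch[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[1]
      paste(ch, collapse = "")
    }
    copy2 <- mutate_at(primer, c(3, 11))
    copy3 <- mutate_at(primer, c(3, 11, 18))
    ref <- Biostrings::DNAStringSet(c(c1 = paste0(bg, copy2, copy3)))
    hits <- primer_specificity(primer, ref, max_mismatches = 2)
    plus <- hits[hits$strand == "+", ]
    expect_identical(plus$start, c(1000L, 4000L))
    expect_identical(plus$mismatches, c(0L, 2L))
    expect_false(4020L %in% hits$start)       # the 3-mismatch copy
    expect_error(primer_specificity("ACGTACGTAC", ref), "shorter than 15")
  })
})

test_that("primer specificity equals the exhaustive Hamming/IUPAC oracle", {
  withr::with_seed(32, {
    ref_chr <- c(c1 = random_dna_chr(1200), c2 = random_dna_chr(800))
    ref <- Biostrings::DNAStringSet(ref_chr)
    primers <- c(
      substr(ref_chr[["c1"]], 101, 120),
      substr(ref_chr[["c2"]], 301, 318),
      revcomp_chr(substr(ref_chr[["c1"]], 501, 520)),
      "CCCACAGCTTGCTTTCCWTGTTTAG",            # IUPAC W
      sub("^(...).", "\\1W", substr(ref_chr[["c1"]], 701, 720)))
    for (pr in primers) {
      got <- primer_specificity(pr, ref, max_mismatches = 2)
      want <- oracle_primer_scan(pr, ref_chr, max_mm = 2)
      rownames(got) <- NULL
      expect_identical(got, want)
    }
  })
})

test_that("in-silico PCR emits amplicons only for convergent primers in window", {
  withr::with_seed(33, {
    bg <- random_dna_chr(1000)
    f <- substr(bg, 101, 120)
    r_site <- substr(bg, 481, 500)
    pp <- primer_pair("t", f, revcomp_chr(r_site))
    tpl <- Biostrings::DNAStringSet(c(t1 = bg))
    amp <- in_silico_pcr(pp, tpl)
    expect_identical(nrow(amp), 1L)
    expect_identical(amp$start, 100L)
    expect_identical(amp$length, 400L)        # inclusive of both primers
    # reverse-complementing the template leaves the product length unchanged
    amp_rc <- in_silico_pcr(pp, Biostrings::reverseComplement(tpl))
    expect_identical(amp_rc$length, 400L)
    # same-orientation primers yield nothing
    pp_same <- primer_pair("s", f, r_site)
    expect_identical(nrow(in_silico_pcr(pp_same, tpl)), 0L)
    # span beyond the product window yields nothing
    pp_narrow <- primer_pair("n", f, revcomp_chr(r_site), product_max = 399)
    expect_identical(nrow(in_silico_pcr(pp_narrow, tpl)), 0L)
  })
})

test_that("band patterns merge within gel resolution", {
  expect_identical(band_pattern(c(400, 600))$n_bands, 2L)
  expect_identical(band_pattern(c(400, 410), gel_resolution = 20)$n_bands, 1L)
  expect_identical(band_pattern(numeric(0))$n_bands, 0L)
  bp <- band_pattern(c(100, 115, 130, 400))    # chain-merges 100..130
  expect_identical(bp$n_bands, 2L)
  expect_true(all(diff(bp$bands) > 20))
})

test_that("marker classification separates dominant, gametologous, non-specific", {
  spec <- small_spec(seed = 41)
  pop <- simulate_population(spec, 2, 2, seed = 42)
  mk <- design_synthetic_markers(pop)
  female <- pop$individuals[[which(vapply(pop$individuals, function(i) i$sex,
                                          character(1)) == "female")[1]]]
  male <- pop$individuals[[which(vapply(pop$individuals, function(i) i$sex,
                                        character(1)) == "male")[1]]]
  cls_dom <- classify_marker(mk$pairs[[1]], female$haplotypes, male$haplotypes)
  expect_identical(cls_dom$class, "dominant")
  cls_gam <- classify_marker(mk$pairs[[2]], female$haplotypes, male$haplotypes)
  expect_identical(cls_gam$class, "gametologous")
  expect_identical(cls_gam$het_bands$n_bands, 2L)
  expect_identical(cls_gam$hom_bands$n_bands, 1L)
  # an autosomal pair amplifies identically in both sexes
  auto <- as.character(spec$autosomes[[1]])
  pp_auto <- primer_pair("auto", substr(auto, 2001, 2020),
                         revcomp_chr(substr(auto, 2481, 2500)))
  cls_auto <- classify_marker(pp_auto, female$haplotypes, male$haplotypes)
  expect_identical(cls_auto$class, "non_specific")
})

test_that("sex calls follow the band-count rules including invalid", {
  b2 <- band_pattern(c(300, 900), individual = "i1")
  b1 <- band_pattern(500, individual = "i2")
  b0 <- band_pattern(numeric(0), individual = "i3")
  expect_identical(call_sex(b1, "dominant")$call, "female")
  expect_identical(call_sex(b0, "dominant")$call, "male")
  expect_identical(call_sex(b2, "gametologous")$call, "female")
  expect_identical(call_sex(b1, "gametologous")$call, "male")
  expect_identical(call_sex(b0, "gametologous")$call, "invalid")
  # XY mirror swaps the sexes
  expect_identical(call_sex(b1, "dominant", system = "XY")$call, "male")
  expect_identical(call_sex(b2, "gametologous", system = "XY")$call, "male")
  expect_error(call_sex(b1, "non_specific"), "cannot sex")
})

test_that("two synthetic markers genotype a 20+20 cohort with 100% accuracy", {
  spec <- small_spec(seed = 51)
  pop <- simulate_population(spec, 20, 20, seed = 52)
  mk <- design_synthetic_markers(pop)
  calls <- genotype_cohort(pop$individuals, mk$pairs, mk$classes)
  expect_identical(nrow(calls), 80L)
  expect_true(all(calls$correct))
  # dominant marker: no bands in males, at least one in females
  dom <- calls[calls$marker == "SYN-DOM", ]
  expect_true(all(dom$n_bands[dom$true_sex == "male"] == 0))
  expect_true(all(dom$n_bands[dom$true_sex == "female"] >= 1))
  gam <- calls[calls$marker == "SYN-GAM", ]
  expect_true(all(gam$n_bands[gam$true_sex == "male"] == 1))
  expect_true(all(gam$n_bands[gam$true_sex == "female"] == 2))
})
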
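test_that("enumeration yields the closed-form window count", {
  set.seed(5)
  r <- region_from_seq(random_dna(30))
  s <- uod_settings(length_min = 18, length_max = 25)
  oligos <- enumerate_oligos(r, s)
  expect_equal(nrow(oligos), 2 * sum(31 - 18:25)) # 152
  # one length exactly filling the region: one oligo per strand
  r18 <- region_from_seq(random_dna(18))
  o18 <- enumerate_oligos(r18, uod_settings(length_min = 18, length_max = 18))
  expect_equal(nrow(o18), 2)
  expect_setequal(o18$strand, c("F", "R"))
  # too-short region: empty with a warning, not an error
  expect_warning(
    o0 <- enumerate_oligos(
      region_from_seq(random_dna(10)),
      uod_settings(length_min = 18, length_max = 20)
    ),
    "shorter"
  )
  expect_equal(nrow(o0), 0)
})

test_that("enumerated oligos match the genome slice on both strands", {
  set.seed(6)
  seq <- random_dna(60)
  r <- region_from_seq(seq, chrom = "c1", start = 1)
  oligos <- enumerate_oligos(r, uod_settings(length_min = 20, length_max = 20))
  f <- oligos[oligos$strand == "F", ]
  expect_equal(f$seq, substring(seq, f$five_prime_pos, f$three_prime_pos))
  expect_true(all(f$three_prime_pos > f$five_prime_pos))
  rv <- oligos[oligos$strand == "R", ]
  expect_equal(
    rv$seq,
    reverse_complement(
      substring(seq, rv$three_prime_pos, rv$five_prime_pos)
    )
  )
  expect_true(all(rv$three_prime_pos < rv$five_prime_pos))
  # ids follow the naming convention
  expect_match(oligos$id, "^TA_c1_\\d+_20_[FR]$")
  # on-target Tm agrees with the scalar duplex computation
  idx <- sample(nrow(oligos), 5)
  expect_equal(oligos$tm_on_target[idx], tm_duplex(oligos$seq[idx]),
    tolerance = 1e-9
  )
})

test_that("flanking mode keeps 3' ends outside the locus", {
  set.seed(8)
  r <- region_from_seq(random_dna(200))
  s <- uod_settings(
    length_min = 18, length_max = 20,
    flanking_mode = TRUE, flank_size = 60
  )
  oligos <- enumerate_oligos(r, s, locus = c(90, 110))
  expect_gt(nrow(oligos), 0)
  f <- oligos[oligos$strand == "F", ]
  rv <- oligos[oligos$strand == "R", ]
  expect_true(all(f$three_prime_pos <= 90))
  expect_true(all(f$five_prime_pos >= 30))
  expect_true(all(rv$three_prime_pos >= 110))
  expect_true(all(rv$five_prime_pos <= 170))
})

test_that("sequence feature flags follow their published rules", {
  base <- tibble::tibble(
    id = letters[1:8],
    chrom = "c",
    seq = c(
      "ACGTACGTACGTACGTnCGT", # masked character
      "GCGCGGCCGCGCGGCCGCGC", # GC 100%
      "GCGCATATATGCGCATATAT", # ends in T
      "ATGCATGCATGCATACGCGA", # 3' pentamer CGCGA: 4 G/C -> clamp
      "ATGCATGCATGCATACGATA", # 3' pentamer CGATA: 2 G/C -> no clamp
      "GCGTACGATATATATGCGTC", # four AT units
      "GCGTACGCGATATATGCGTC", # three AT units only
      "CATGCAGAAAACTGCATGCG" # AAAA mononucleotide run
    ),
    strand = "F", five_prime_pos = 1L, three_prime_pos = 20L,
    length = 20L,
    gc_pct = c(45, 100, 50, 40, 40, 45, 55, 50),
    tm_on_target = 65
  )
  flags <- sequence_feature_filter(base, uod_settings())
  expect_true(flags$non_acgt[1])
  expect_true(flags$gc_range[2])
  expect_true(flags$at_end[3])
  expect_true(flags$gc_clamp[4])
  expect_false(flags$gc_clamp[5])
  expect_true(flags$repeats[6])
  expect_false(flags$repeats[7])
  expect_true(flags$repeats[8])
  # disabling a filter clears its flag without touching the others
  relaxed <- sequence_feature_filter(
    base, uod_settings(at_end_filter = FALSE)
  )
  expect_false(any(relaxed$at_end))
  expect_true(all(
    flags$pass_sequence_features | !relaxed$pass_sequence_features |
      flags$at_end
  ))
})

test_that("Tm range bounds are inclusive and structure margin applies", {
  oligos <- tibble::tibble(
    id = c("lo", "in_lo", "in_hi", "hi"),
    seq = rep("ACGTACGTACGTACGTACGT", 4),
    tm_on_target = c(63.9, 64, 74, 74.1)
  )
  flags <- hybridization_filter(oligos, uod_settings())
  expect_equal(flags$tm_range, c(TRUE, FALSE, FALSE, TRUE))
  # margin arithmetic: hairpin at 30 vs on-target 69 passes (30 < 49);
  # homodimer at 55 vs 69 fails (55 > 49)
  s <- uod_settings()
  expect_false(30 > 69 - s$self_structure_margin)
  expect_true(55 > 69 - s$self_structure_margin)
})

test_that("exact-match uniqueness flags planted duplicates", {
  set.seed(9)
  probe <- random_dna(20)
  probe_rc_site <- reverse_complement(random_dna(20))
  uniqueo <- random_dna(20)
  dup <- random_dna(20)
  genome <- make_genome(c(
    chr1 = paste0(
      random_dna(50), probe, random_dna(50), dup, random_dna(50)
    ),
    chr2 = paste0(
      random_dna(30), probe, random_dna(30), dup, random_dna(30),
      reverse_complement(probe_rc_site), random_dna(30)
    )
  ))
  # oligos "extracted" from chr1 coordinates
  oligos <- tibble::tibble(
    id = c("probe", "dup", "unique"),
    chrom = "chr1",
    seq = c(probe, dup, uniqueo),
    strand = "F",
    five_prime_pos = c(51L, 121L, 1L),
    three_prime_pos = c(70L, 140L, 20L),
    length = 20L
  )
  out <- exact_match_filter(oligos, genome)
  expect_true(out$off_target_exact[out$id == "probe"]) # second copy on chr2
  expect_true(out$off_target_exact[out$id == "dup"])
  expect_false(out$off_target_exact[out$id == "unique"])

  # an oligo whose reverse complement occurs elsewhere is flagged too
  oligos_rc <- tibble::tibble(
    id = "rcprobe", chrom = "chr1", seq = probe_rc_site,
    strand = "F", five_prime_pos = 200L, three_prime_pos = 219L,
    length = 20L
  )
  out_rc <- exact_match_filter(oligos_rc, genome)
  expect_true(out_rc$off_target_exact)
})

test_that("the pass set is invariant to filter evaluation order", {
  set.seed(10)
  seq <- random_dna(120)
  genome <- make_genome(c(z = seq))
  region <- extract_masked_region(genome, "z", 1, 120)
  s <- uod_settings(length_min = 18, length_max = 20)
  cascade <- design_oligos(region, genome, s)
  # independent evaluation: all three filters on every enumerated oligo
  all_oligos <- enumerate_oligos(region, s)
  f1 <- sequence_feature_filter(all_oligos, s)
  f2 <- hybridization_filter(all_oligos, s)
  f3 <- exact_match_filter(all_oligos, genome)
  pass_all <- f1$pass_sequence_features & f2$pass_hybridization &
    f3$pass_exact_match
  expect_setequal(cascade$id[cascade$pass], all_oligos$id[pass_all])
})

test_that("relaxing the A/T-end filter never shrinks the pass set", {
  set.seed(12)
  seq <- random_dna(150, gc = 0.55)
  genome <- make_genome(c(z = seq))
  region <- extract_masked_region(genome, "z", 1, 150)
  strict <- design_oligos(region, genome, uod_settings())
  relaxed <- design_oligos(
    region, genome, uod_settings(at_end_filter = FALSE)
  )
  expect_true(all(strict$id[strict$pass] %in% relaxed$id[relaxed$pass]))
})

test_that("polymorphism filtering removes masked oligos or restores them", {
  set.seed(13)
  seq <- random_dna(60)
  genome <- make_genome(c(z = seq))
  v <- tibble::tibble(chrom = "z", pos = 30L, class = "snp")
  region <- extract_masked_region(genome, "z", 1, 60, variants = v)
  s <- uod_settings(length_min = 20, length_max = 20)
  masked <- sequence_feature_filter(enumerate_oligos(region, s), s)
  covering <- masked$five_prime_pos <= 30 & masked$three_prime_pos >= 30 |
    masked$three_prime_pos <= 30 & masked$five_prime_pos >= 30
  expect_true(all(masked$non_acgt[covering]))
  # with the filter off, the reference base is restored before the test
  s_off <- uod_settings(
    length_min = 20, length_max = 20, polymorphism_filter = FALSE
  )
  unmasked <- sequence_feature_filter(enumerate_oligos(region, s_off), s_off)
  expect_false(any(unmasked$non_acgt))
})
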
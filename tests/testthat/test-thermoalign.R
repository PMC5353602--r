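test_that("a full-length ungapped hit maps onto itself", {
  set.seed(31)
  seq <- random_dna(2000)
  genome <- make_genome(c(chr1 = seq))
  primer_seq <- substr(seq, 501, 520)
  hit <- tibble::tibble(
    primer_id = "p", subject_name = "chr1", subject_strand = "+",
    subject_start = 801L, subject_stop = 820L,
    primer_aln_start = 1L, primer_aln_stop = 20L
  )
  ta <- build_thermoalignment(hit, primer_seq, genome)
  expect_equal(ta$template_window_start, 801L)
  expect_equal(ta$template_window_stop, 820L)
  expect_equal(ta$template_primer_frame, substr(seq, 801, 820))
})

test_that("truncated hits are end-filled toward the anchored 3' base", {
  # 12-mer primer whose hit covers only primer positions 3-12: the window
  # is extended by 2 nt on the primer-5' side
  set.seed(32)
  seq <- random_dna(500)
  genome <- make_genome(c(chr1 = seq))
  primer_seq <- paste0("GG", substr(seq, 103, 112))
  hit <- tibble::tibble(
    primer_id = "p", subject_name = "chr1", subject_strand = "+",
    subject_start = 103L, subject_stop = 112L,
    primer_aln_start = 3L, primer_aln_stop = 12L
  )
  ta <- build_thermoalignment(hit, primer_seq, genome)
  expect_equal(ta$template_window_start, 101L)
  expect_equal(ta$template_window_stop, 112L)
  # mismatches = filled columns that differ + hit mismatches (none here)
  filled <- substr(seq, 101, 102)
  expect_equal(
    ta$n_mismatches,
    sum(strsplit(filled, "")[[1]] != c("G", "G"))
  )
})

test_that("minus-strand windows preserve strandedness", {
  set.seed(33)
  seq <- random_dna(600)
  genome <- make_genome(c(chr1 = seq))
  primer_seq <- reverse_complement(substr(seq, 301, 320))
  # ungapped full-length minus-strand hit at 301..320
  hit <- tibble::tibble(
    primer_id = "p", subject_name = "chr1", subject_strand = "-",
    subject_start = 301L, subject_stop = 320L,
    primer_aln_start = 1L, primer_aln_stop = 20L
  )
  ta <- build_thermoalignment(hit, primer_seq, genome)
  expect_equal(ta$template_window_start, 301L)
  expect_equal(ta$template_window_stop, 320L)
  expect_equal(ta$template_primer_frame, primer_seq)
  expect_equal(ta$n_mismatches, 0)
})

test_that("gapped and truncated hits select the oracle's anchored window", {
  set.seed(34)
  seq <- random_dna(3000)
  genome <- make_genome(c(chr1 = seq))
  n_checked <- 0
  for (i in 1:150) {
    L <- sample(18:27, 1)
    p_start <- sample(1:5, 1)
    p_end <- L - sample(0:4, 1)
    if (p_end <= p_start + 7) next
    strand <- sample(c("+", "-"), 1)
    net_gap <- sample(-2:2, 1) # subject span minus primer span
    span_p <- p_end - p_start
    s_lo <- sample(100:2800, 1)
    s_hi <- s_lo + span_p + net_gap
    if (s_hi <= s_lo || s_hi > 2990) next
    hit <- tibble::tibble(
      primer_id = "p", subject_name = "chr1", subject_strand = strand,
      subject_start = as.integer(s_lo), subject_stop = as.integer(s_hi),
      primer_aln_start = as.integer(p_start),
      primer_aln_stop = as.integer(p_end)
    )
    primer_seq <- random_dna(L)
    ta <- build_thermoalignment(hit, primer_seq, genome)
    ws <- oracle_select_window(hit, L, nchar(seq))
    if (is.null(ta)) {
      expect_equal(length(ws), 0)
    } else {
      expect_equal(length(ws), 1)
      expect_equal(ta$template_window_start, ws)
      expect_equal(ta$template_window_stop, ws + L - 1)
      # coordinate audit: re-extraction reproduces the stored frame
      slice <- substr(seq, ta$template_window_start, ta$template_window_stop)
      frame <- if (strand == "+") slice else reverse_complement(slice)
      expect_equal(ta$template_primer_frame, frame)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 50)
})

test_that("hits running past the subject end are dropped with a message", {
  genome <- make_genome(c(chr1 = random_dna(100)))
  hit <- tibble::tibble(
    primer_id = "p", subject_name = "chr1", subject_strand = "+",
    subject_start = 95L, subject_stop = 99L,
    primer_aln_start = 1L, primer_aln_stop = 5L
  )
  expect_message(
    ta <- build_thermoalignment(hit, random_dna(20), genome),
    "boundary"
  )
  expect_null(ta)
})

test_that("misprime Tm ranks mismatch classes correctly", {
  set.seed(35)
  p <- "ACGTTGCAACGTAGCTAGCTAGGAA"
  # frame A at position 14 puts a template T under the primer base there:
  # primer G gives a G.T wobble (the least destabilizing class), primer C a
  # C.T mismatch, which melts lower
  expect_equal(substr(p, 14, 14), "G")
  f <- p
  substr(f, 14, 14) <- "A"
  p_ct <- p
  substr(p_ct, 14, 14) <- "C"
  tm_gt <- misprime_tm(p, f)
  tm_ct <- misprime_tm(p_ct, f)
  expect_gt(tm_gt, tm_ct)
  # oracle agreement for both variants
  expect_equal(tm_gt, oracle_tm(p, f), tolerance = 1e-9)
  expect_equal(tm_ct, oracle_tm(p_ct, f), tolerance = 1e-9)
  # degenerate zero-mismatch thermoalignment equals the duplex Tm
  expect_equal(misprime_tm(p, p), tm_duplex(p), tolerance = 1e-9)
})

test_that("misprime profiles exclude 3'-terminal-mismatch sites", {
  tas <- tibble::tibble(
    primer_id = "p",
    tm_offtarget = c(50, 55, 60),
    has_3prime_terminal_mismatch = c(FALSE, TRUE, FALSE),
    n_mismatches_last5 = c(0L, 1L, 2L)
  )
  cands <- tibble::tibble(id = "p", tm_on_target = 69)
  prof <- misprime_profile(tas, cands, threshold_celsius = 10)
  expect_equal(prof$n_hits_scored, 2)
  expect_equal(prof$tm_offtarget_max, 60)
  expect_equal(prof$frac_hits_with_last5_mismatch, 2 / 3)
  # 69 >= 60 + 10 fails by 1 degree
  expect_false(prof$pass_specificity)
  prof9 <- misprime_profile(tas, cands, threshold_celsius = 9)
  expect_true(prof9$pass_specificity)
})

test_that("zero-hit primers are trivially specific", {
  prof <- misprime_profile(
    empty_thermoalignment_tbl <- thermotile:::empty_thermoalignment_tbl(),
    tibble::tibble(id = "p", tm_on_target = 65)
  )
  expect_equal(prof$tm_offtarget_max, -Inf)
  expect_true(prof$pass_specificity)
})

test_that("the 90th percentile follows the nearest-rank definition", {
  set.seed(36)
  tms <- round(runif(10, 40, 70), 2)
  tas <- tibble::tibble(
    primer_id = "p", tm_offtarget = tms,
    has_3prime_terminal_mismatch = FALSE, n_mismatches_last5 = 0L
  )
  prof <- misprime_profile(
    tas, tibble::tibble(id = "p", tm_on_target = 80)
  )
  expect_equal(prof$tm_offtarget_p90, sort(tms)[ceiling(0.9 * 10)])
  expect_lte(prof$tm_offtarget_p90, prof$tm_offtarget_max)
})

test_that("the specificity filter is monotone in its threshold", {
  set.seed(37)
  on <- runif(50, 60, 75)
  off <- runif(50, 40, 70)
  strict <- specificity_filter(on, off, 10)
  relaxed <- specificity_filter(on, off, 6)
  expect_true(all(relaxed[strict])) # relaxing never shrinks the pass set
})

test_that("full-length Tm can fall on either side of the local hit's Tm", {
  # truncation hides terminal mismatches: end-filling can lower the Tm;
  # it can also raise it when the filled columns extend a perfect match
  set.seed(38)
  seq <- random_dna(2000)
  genome <- make_genome(c(chr1 = seq))
  directions <- c(FALSE, FALSE)
  for (i in 1:200) {
    L <- 22
    site <- sample(100:1900, 1)
    primer_seq <- substr(seq, site, site + L - 1)
    # corrupt two random internal bases so a local aligner would truncate
    mut <- primer_seq
    for (pos in sample(c(2:5, 18:21), 2)) {
      substr(mut, pos, pos) <- sample(
        setdiff(c("A", "C", "G", "T"), substr(mut, pos, pos)), 1
      )
    }
    trunc_start <- 6L
    trunc_stop <- 17L
    hit <- tibble::tibble(
      primer_id = "p", subject_name = "chr1", subject_strand = "+",
      subject_start = site + trunc_start - 1L,
      subject_stop = site + trunc_stop - 1L,
      primer_aln_start = trunc_start, primer_aln_stop = trunc_stop
    )
    ta <- build_thermoalignment(hit, mut, genome)
    tm_full <- misprime_tm(mut, ta$template_primer_frame)
    tm_local <- misprime_tm(
      substr(mut, trunc_start, trunc_stop),
      substr(seq, site + trunc_start - 1, site + trunc_stop - 1)
    )
    if (is.finite(tm_full) && is.finite(tm_local)) {
      directions[1] <- directions[1] || tm_full > tm_local
      directions[2] <- directions[2] || tm_full < tm_local
    }
    if (all(directions)) break
  }
  expect_true(all(directions))
})
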
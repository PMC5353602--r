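#' Convert a local hit into a full-length ungapped thermoalignment
#'
#' A local alignment is end-filled and de-gapped into the contiguous genomic
#' window of exactly primer length that anchors the primer's 3'-most aligned
#' base at its hit-assigned template coordinate, preserving strandedness (the
#' anchoring operationalizes maximizing complementarity toward the 3' end, the
#' site of primer extension). The template is returned in the primer frame: a
#' column is complementary exactly when the characters are equal. The primer
#' sequence itself is never altered. Hits whose filled window would run past
#' the subject's end are dropped (`NULL`) with a message.
#'
#' @param hit One-row hit tibble from [find_local_hits()].
#' @param primer_seq The primer sequence (5' to 3').
#' @param genome Genome from [load_genome()].
#' @return One-row tibble: `primer_id`, `subject_name`, `subject_strand`,
#'   `template_window_start`, `template_window_stop` (+ strand coordinates),
#'   `template_primer_frame`, `n_mismatches`, `mismatch_positions` (list
#'   column, 1-based from the primer 5' end), `has_3prime_terminal_mismatch`,
#'   `n_mismatches_last5`; or `NULL` when the window cannot be formed.
#' @export
build_thermoalignment <- function(hit, primer_seq, genome) {
  stopifnot(nrow(hit) == 1)
  L <- nchar(primer_seq)
  p_end <- hit$primer_aln_stop
  chrom_seq <- genome[[hit$subject_name]]
  len <- length(chrom_seq)

  if (hit$subject_strand == "+") {
    win_stop <- hit$subject_stop + (L - p_end)
    win_start <- win_stop - L + 1L
  } else {
    win_start <- hit$subject_start - (L - p_end)
    win_stop <- win_start + L - 1L
  }
  if (win_start < 1 || win_stop > len) {
    message(
      "build_thermoalignment: dropped boundary hit for ", hit$primer_id,
      " at ", hit$subject_name, ":", win_start, "-", win_stop,
      " (window extends past the subject end)"
    )
    return(NULL)
  }
  slice <- as.character(Biostrings::subseq(chrom_seq, win_start, win_stop))
  frame <- if (hit$subject_strand == "+") {
    slice
  } else {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(slice)
    ))
  }
  p <- strsplit(toupper(primer_seq), "", fixed = TRUE)[[1]]
  f <- strsplit(frame, "", fixed = TRUE)[[1]]
  mm <- which(p != f)
  tibble::tibble(
    primer_id = hit$primer_id,
    primer_seq = primer_seq,
    subject_name = hit$subject_name,
    subject_strand = hit$subject_strand,
    template_window_start = win_start,
    template_window_stop = win_stop,
    template_primer_frame = frame,
    n_mismatches = length(mm),
    mismatch_positions = list(mm),
    has_3prime_terminal_mismatch = L %in% mm,
    n_mismatches_last5 = sum(mm > L - 5)
  )
}

#' Build thermoalignments for a table of hits
#'
#' Vectorized driver over [build_thermoalignment()], joining hits with their
#' primer sequences and scoring each thermoalignment's misprime Tm.
#'
#' @param hits Hit tibble from [scan_offtargets()].
#' @param candidates Candidate tibble carrying `id` and `seq`.
#' @param genome Genome from [load_genome()].
#' @param conditions A [reaction_conditions()] object.
#' @param table An [nn_table()].
#' @return Thermoalignment tibble with a `tm_offtarget` column.
#' @export
build_thermoalignments <- function(hits, candidates, genome,
                                   conditions = reaction_conditions(),
                                   table = nn_table()) {
  if (nrow(hits) == 0) {
    return(empty_thermoalignment_tbl())
  }
  seqs <- stats::setNames(candidates$seq, candidates$id)
  rows <- purrr::map(seq_len(nrow(hits)), function(i) {
    h <- hits[i, , drop = FALSE]
    build_thermoalignment(h, unname(seqs[h$primer_id]), genome)
  })
  tas <- dplyr::bind_rows(rows)
  if (nrow(tas) == 0) {
    return(empty_thermoalignment_tbl())
  }
  tas$tm_offtarget <- vapply(seq_len(nrow(tas)), function(i) {
    misprime_tm(tas$primer_seq[i], tas$template_primer_frame[i],
      conditions = conditions, table = table
    )
  }, numeric(1))
  tas
}

empty_thermoalignment_tbl <- function() {
  tibble::tibble(
    primer_id = character(), primer_seq = character(),
    subject_name = character(), subject_strand = character(),
    template_window_start = integer(), template_window_stop = integer(),
    template_primer_frame = character(), n_mismatches = integer(),
    mismatch_positions = list(), has_3prime_terminal_mismatch = logical(),
    n_mismatches_last5 = integer(), tm_offtarget = numeric()
  )
}

#' Misprime melting temperature of a thermoalignment
#'
#' Tm of the full-length ungapped primer-template pairing, with mismatch
#' nearest-neighbor parameters applied at mismatch columns.
#'
#' @param primer_seq Primer sequence (5' to 3').
#' @param template_primer_frame Template window in the primer frame.
#' @param conditions A [reaction_conditions()] object.
#' @param table An [nn_table()].
#' @return Melting temperature in degrees Celsius.
#' @export
misprime_tm <- function(primer_seq, template_primer_frame,
                        conditions = reaction_conditions(),
                        table = nn_table()) {
  prof <- duplex_enthalpy_entropy(primer_seq, template_primer_frame, table)
  tryCatch(
    melting_temperature(prof, conditions),
    error = function(e) -Inf
  )
}

# nearest-rank percentile: the ceil(p * n)-th order statistic
nearest_rank <- function(x, p) {
  n <- length(x)
  if (n == 0) {
    return(-Inf)
  }
  sort(x)[max(1L, ceiling(p * n))]
}

#' Per-primer misprime profile
#'
#' Aggregates a primer's thermoalignments into specificity statistics.
#' Thermoalignments with a mismatch at the primer's 3'-terminal base are
#' excluded from Tm aggregation (such sites do not prime); the fraction of
#' hits with any mismatch among the last five 3' bases is recorded over all
#' hits but never used for filtering. The 90th-percentile Tm uses the
#' nearest-rank definition. A primer with zero scored hits gets a sentinel
#' maximum of `-Inf` (trivially specific).
#'
#' @param thermoalignments Tibble from [build_thermoalignments()].
#' @param candidates Candidate tibble with `id` and `tm_on_target`.
#' @param threshold_celsius Specificity margin in degrees Celsius
#'   (default 10): a primer passes when
#'   `tm_on_target >= tm_offtarget_max + threshold`.
#' @return One row per candidate: `primer_id`, `tm_on_target`,
#'   `n_hits_total`, `n_hits_scored`, `tm_offtarget_max`, `tm_offtarget_p90`,
#'   `frac_hits_with_last5_mismatch`, `pass_specificity`.
#' @export
misprime_profile <- function(thermoalignments, candidates,
                             threshold_celsius = 10) {
  base <- tibble::tibble(
    primer_id = candidates$id,
    tm_on_target = candidates$tm_on_target
  )
  if (nrow(thermoalignments) == 0) {
    agg <- tibble::tibble(
      primer_id = character(), n_hits_total = integer(),
      n_hits_scored = integer(), tm_offtarget_max = numeric(),
      tm_offtarget_p90 = numeric(), frac_hits_with_last5_mismatch = numeric()
    )
  } else {
    agg <- thermoalignments |>
      dplyr::group_by(.data$primer_id) |>
      dplyr::summarise(
        n_hits_total = dplyr::n(),
        n_hits_scored = sum(!.data$has_3prime_terminal_mismatch),
        tm_offtarget_max = if (any(!.data$has_3prime_terminal_mismatch)) {
          max(.data$tm_offtarget[!.data$has_3prime_terminal_mismatch])
        } else {
          -Inf
        },
        tm_offtarget_p90 = nearest_rank(
          .data$tm_offtarget[!.data$has_3prime_terminal_mismatch], 0.9
        ),
        frac_hits_with_last5_mismatch =
          mean(.data$n_mismatches_last5 > 0),
        .groups = "drop"
      )
  }
  base |>
    dplyr::left_join(agg, by = "primer_id") |>
    dplyr::mutate(
      n_hits_total = dplyr::coalesce(.data$n_hits_total, 0L),
      n_hits_scored = dplyr::coalesce(.data$n_hits_scored, 0L),
      tm_offtarget_max = dplyr::coalesce(.data$tm_offtarget_max, -Inf),
      tm_offtarget_p90 = dplyr::coalesce(.data$tm_offtarget_p90, -Inf),
      frac_hits_with_last5_mismatch =
        dplyr::coalesce(.data$frac_hits_with_last5_mismatch, 0),
      pass_specificity = specificity_filter(
        .data$tm_on_target, .data$tm_offtarget_max, threshold_celsius
      )
    )
}

#' Specificity filter on the on-target vs maximum misprime Tm margin
#'
#' @param tm_on_target,tm_offtarget_max Numeric vectors (degrees Celsius).
#' @param threshold_celsius Margin (default 10).
#' @return Logical vector: `tm_on_target >= tm_offtarget_max + threshold`.
#' @export
specificity_filter <- function(tm_on_target, tm_offtarget_max,
                               threshold_celsius = 10) {
  tm_on_target >= tm_offtarget_max + threshold_celsius
}
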
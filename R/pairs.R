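#' Settings for primer pair selection
#'
#' @param amplicon_min,amplicon_max Expected amplicon length range in bp
#'   (inclusive). Amplicon length is the distance between the 5' ends of the
#'   forward and reverse primer, inclusive of both.
#' @param tm_diff_max Maximum on-target Tm difference between the two primers
#'   of a pair (default 10).
#' @param misprime_margin The lower on-target Tm of the pair must exceed the
#'   maximum misprime Tm of both primers by at least this margin (default 10).
#' @param heterodimer_floor Minimum tolerated cross-dimer free energy in
#'   cal/mol (default -2000; pairs with a more negative dG are filtered).
#' @param gap_filter Exclude pairs whose amplicon spans an assembly gap
#'   (default `TRUE`). Indel content is annotated, never filtered.
#' @return A `pps_settings` list.
#' @export
pps_settings <- function(amplicon_min = 100, amplicon_max = 5000,
                         tm_diff_max = 10, misprime_margin = 10,
                         heterodimer_floor = -2000, gap_filter = TRUE) {
  stopifnot(amplicon_min >= 1, amplicon_max >= amplicon_min)
  structure(
    list(
      amplicon_min = amplicon_min, amplicon_max = amplicon_max,
      tm_diff_max = tm_diff_max, misprime_margin = misprime_margin,
      heterodimer_floor = heterodimer_floor, gap_filter = gap_filter
    ),
    class = "pps_settings"
  )
}

#' Enumerate compatible primer pairs with amplicon annotations
#'
#' Combines specificity-passing forward and reverse primers into convergent
#' pairs and applies the pair-level filters: amplicon length range, on-target
#' Tm difference, misprime margin (the pair's lower Tm against the maximum
#' misprime Tm of both primers), cross-dimer free energy, and (optionally)
#' assembly-gap content of the amplicon. Indels inside the amplicon are
#' annotated but never filtered.
#'
#' @param candidates Candidate tibble (pass-filter oligos joined with their
#'   misprime profiles: needs `id`, `seq`, `strand`, `five_prime_pos`,
#'   `three_prime_pos`, `tm_on_target`, `tm_offtarget_max`).
#' @param region The `target_region` (for gap runs, indels and amplicon GC).
#' @param settings A [pps_settings()] object.
#' @param conditions A [reaction_conditions()] object (cross-dimer dG).
#' @return An `AmpliconPair` tibble: `pair_id`, `fwd_id`, `rev_id`,
#'   `amplicon_start`, `amplicon_stop`, `amplicon_length`, `tm_min_of_pair`,
#'   `tm_diff`, `pair_max_misprime`, `heterodimer_dg`,
#'   `contains_assembly_gap`, `contains_indel`, `amplicon_gc_pct`.
#' @export
enumerate_pairs <- function(candidates, region,
                            settings = pps_settings(),
                            conditions = reaction_conditions()) {
  fwd <- dplyr::filter(candidates, .data$strand == "F")
  rev <- dplyr::filter(candidates, .data$strand == "R")
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(empty_pair_tbl())
  }

  # interval join: for each forward primer, the reverse primers whose 5' end
  # yields an amplicon length inside the configured range
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(
      fwd$five_prime_pos + settings$amplicon_min - 1L,
      fwd$five_prime_pos + settings$amplicon_max - 1L
    ),
    IRanges::IRanges(rev$five_prime_pos, rev$five_prime_pos)
  )
  pairs <- tibble::tibble(
    f = S4Vectors::queryHits(ov),
    r = S4Vectors::subjectHits(ov)
  ) |>
    dplyr::mutate(
      amplicon_start = fwd$five_prime_pos[.data$f],
      amplicon_stop = rev$five_prime_pos[.data$r],
      amplicon_length = .data$amplicon_stop - .data$amplicon_start + 1L,
      fwd_three = fwd$three_prime_pos[.data$f],
      rev_three = rev$three_prime_pos[.data$r]
    ) |>
    dplyr::filter(
      .data$amplicon_start < .data$amplicon_stop,
      .data$fwd_three < .data$rev_three
    ) |>
    dplyr::mutate(
      fwd_id = fwd$id[.data$f],
      rev_id = rev$id[.data$r],
      tm_f = fwd$tm_on_target[.data$f],
      tm_r = rev$tm_on_target[.data$r],
      tm_min_of_pair = pmin(.data$tm_f, .data$tm_r),
      tm_diff = abs(.data$tm_f - .data$tm_r),
      pair_max_misprime = pmax(
        fwd$tm_offtarget_max[.data$f],
        rev$tm_offtarget_max[.data$r]
      )
    ) |>
    dplyr::filter(
      .data$tm_diff <= settings$tm_diff_max,
      .data$tm_min_of_pair >= .data$pair_max_misprime +
        settings$misprime_margin
    )
  if (nrow(pairs) == 0) {
    return(empty_pair_tbl())
  }

  # amplicon annotations against the region
  gap_runs <- region$gap_runs
  has_gap <- vapply(seq_len(nrow(pairs)), function(i) {
    nrow(gap_runs) > 0 && any(
      gap_runs$start <= pairs$amplicon_stop[i] &
        gap_runs$stop >= pairs$amplicon_start[i]
    )
  }, logical(1))
  indel_pos <- region$variant_sites$pos[region$variant_sites$class == "indel"]
  has_indel <- vapply(seq_len(nrow(pairs)), function(i) {
    any(indel_pos >= pairs$amplicon_start[i] &
      indel_pos <= pairs$amplicon_stop[i])
  }, logical(1))

  chars <- strsplit(region$raw_seq, "", fixed = TRUE)[[1]]
  cum_gc <- c(0, cumsum(chars %in% c("G", "C")))
  cum_base <- c(0, cumsum(chars %in% BASES))
  lo <- pairs$amplicon_start - region$start + 1L
  hi <- pairs$amplicon_stop - region$start + 1L
  n_base <- cum_base[hi + 1] - cum_base[lo]
  gc_pct <- ifelse(n_base > 0,
    100 * (cum_gc[hi + 1] - cum_gc[lo]) / n_base, NA_real_
  )

  pairs <- pairs |>
    dplyr::mutate(
      contains_assembly_gap = has_gap,
      contains_indel = has_indel,
      amplicon_gc_pct = gc_pct
    )
  if (isTRUE(settings$gap_filter)) {
    pairs <- dplyr::filter(pairs, !.data$contains_assembly_gap)
  }
  if (nrow(pairs) == 0) {
    return(empty_pair_tbl())
  }

  # cross-dimer free energy only for the survivors (the expensive step)
  fwd_seq <- stats::setNames(fwd$seq, fwd$id)
  rev_seq <- stats::setNames(rev$seq, rev$id)
  pairs$heterodimer_dg <- vapply(seq_len(nrow(pairs)), function(i) {
    heterodimer_dg(
      unname(fwd_seq[pairs$fwd_id[i]]),
      unname(rev_seq[pairs$rev_id[i]]),
      conditions
    )
  }, numeric(1))
  pairs <- dplyr::filter(
    pairs, .data$heterodimer_dg >= settings$heterodimer_floor
  )

  pairs |>
    dplyr::transmute(
      pair_id = paste0(.data$fwd_id, "..", .data$rev_id),
      fwd_id = .data$fwd_id, rev_id = .data$rev_id,
      amplicon_start = .data$amplicon_start,
      amplicon_stop = .data$amplicon_stop,
      amplicon_length = .data$amplicon_length,
      tm_min_of_pair = .data$tm_min_of_pair,
      tm_diff = .data$tm_diff,
      pair_max_misprime = .data$pair_max_misprime,
      heterodimer_dg = .data$heterodimer_dg,
      contains_assembly_gap = .data$contains_assembly_gap,
      contains_indel = .data$contains_indel,
      amplicon_gc_pct = .data$amplicon_gc_pct
    ) |>
    dplyr::arrange(.data$amplicon_start, .data$amplicon_stop, .data$pair_id)
}

empty_pair_tbl <- function() {
  tibble::tibble(
    pair_id = character(), fwd_id = character(), rev_id = character(),
    amplicon_start = integer(), amplicon_stop = integer(),
    amplicon_length = integer(), tm_min_of_pair = numeric(),
    tm_diff = numeric(), pair_max_misprime = numeric(),
    heterodimer_dg = numeric(), contains_assembly_gap = logical(),
    contains_indel = logical(), amplicon_gc_pct = numeric()
  )
}
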
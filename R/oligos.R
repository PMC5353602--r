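#' Settings for unique oligonucleotide design
#'
#' Tunable parameters of the oligo enumeration and filter cascade.
#'
#' @param length_min,length_max Oligo length range in nt (defaults 18-27).
#' @param gc_min,gc_max GC content range in percent, inclusive (defaults
#'   40-60).
#' @param tm_min,tm_max On-target melting-temperature range in degrees
#'   Celsius, inclusive (defaults 64-74).
#' @param at_end_filter Filter oligos whose 3'-terminal base is A or T.
#' @param gc_clamp_filter Filter oligos with more than three G or C among the
#'   last five bases.
#' @param polymorphism_filter Enumerate from the variant-masked sequence so
#'   oligos over variant sites are removed by the base-composition test; when
#'   `FALSE`, masked characters are resolved back to the reference base.
#' @param repeat_units Minimum number of consecutive copies of a mono- or
#'   dinucleotide unit that counts as a disqualifying repeat (default 4).
#' @param self_structure_margin A hairpin or homodimer melting temperature
#'   within this many degrees Celsius of the on-target Tm disqualifies the
#'   oligo (default 20).
#' @param flanking_mode Design only primers flanking a locus (see
#'   [enumerate_oligos()]).
#' @param flank_size Maximum distance (nt) of a flanking primer's 5' end from
#'   the locus boundary.
#' @return A `uod_settings` list.
#' @export
uod_settings <- function(length_min = 18, length_max = 27,
                         gc_min = 40, gc_max = 60,
                         tm_min = 64, tm_max = 74,
                         at_end_filter = TRUE, gc_clamp_filter = TRUE,
                         polymorphism_filter = TRUE,
                         repeat_units = 4,
                         self_structure_margin = 20,
                         flanking_mode = FALSE, flank_size = NULL) {
  stopifnot(
    length_min >= 2, length_max >= length_min,
    gc_max >= gc_min, tm_max >= tm_min, repeat_units >= 2
  )
  structure(
    list(
      length_min = as.integer(length_min),
      length_max = as.integer(length_max),
      gc_min = gc_min, gc_max = gc_max,
      tm_min = tm_min, tm_max = tm_max,
      at_end_filter = at_end_filter,
      gc_clamp_filter = gc_clamp_filter,
      polymorphism_filter = polymorphism_filter,
      repeat_units = as.integer(repeat_units),
      self_structure_margin = self_structure_margin,
      flanking_mode = flanking_mode,
      flank_size = flank_size
    ),
    class = "uod_settings"
  )
}

# Working sequence for enumeration: variant-masked when the polymorphism
# filter is on, otherwise the raw reference slice (assembly Ns stay either way)
region_working_seq <- function(region, settings) {
  if (isTRUE(settings$polymorphism_filter)) region$masked_seq else region$raw_seq
}

#' Enumerate every candidate oligo in a target region
#'
#' Slides a 1-bp window for every length in the configured range across both
#' strands of the region, yielding `2 * sum(region_len - L + 1)` oligos. In
#' flanking mode only forward oligos whose 3' end is at or before the locus
#' start and reverse oligos whose 3' end is at or after the locus stop (within
#' `flank_size` of the boundary) are kept.
#'
#' @param region A `target_region` from [extract_masked_region()].
#' @param settings A [uod_settings()] object.
#' @param conditions A [reaction_conditions()] object (for the on-target Tm).
#' @param locus Optional `c(start, stop)` genomic coordinates of the locus to
#'   flank (required in flanking mode).
#' @return A tibble of oligos: `id` (`TA_<chrom>_<5' position>_<length>_<F|R>`),
#'   `seq` (5' to 3'), `strand`, `five_prime_pos`, `three_prime_pos`,
#'   `length`, `gc_pct`, `tm_on_target`.
#' @export
enumerate_oligos <- function(region, settings = uod_settings(),
                             conditions = reaction_conditions(),
                             locus = NULL) {
  working <- region_working_seq(region, settings)
  n <- nchar(working)
  lengths <- seq(settings$length_min, settings$length_max)
  lengths <- lengths[lengths <= n]
  if (length(lengths) == 0) {
    warning("enumerate_oligos: region shorter than length_min; no oligos")
    return(empty_oligo_tbl())
  }

  chars <- strsplit(working, "", fixed = TRUE)[[1]]
  rc_working <- paste(
    rev(unname(c(
      A = "T", C = "G", G = "C", T = "A",
      N = "N", n = "n"
    )[chars])),
    collapse = ""
  )
  is_gc <- chars %in% c("G", "C")
  is_base <- chars %in% BASES
  cum_gc <- c(0, cumsum(is_gc))
  cum_base <- c(0, cumsum(is_base))

  per_length <- lapply(lengths, function(L) {
    starts <- seq_len(n - L + 1)
    ends <- starts + L - 1
    fwd_seq <- substring(working, starts, ends)
    rev_seq <- substring(rc_working, n - ends + 1, n - starts + 1)
    n_base <- cum_base[ends + 1] - cum_base[starts]
    gc <- ifelse(n_base > 0,
      100 * (cum_gc[ends + 1] - cum_gc[starts]) / n_base, NA_real_
    )
    tm <- window_tm(chars, L, conditions)
    g_start <- region$start + starts - 1L
    g_end <- region$start + ends - 1L
    dplyr::bind_rows(
      tibble::tibble(
        seq = fwd_seq, strand = "F",
        five_prime_pos = g_start, three_prime_pos = g_end,
        length = L, gc_pct = gc, tm_on_target = tm
      ),
      tibble::tibble(
        seq = rev_seq, strand = "R",
        five_prime_pos = g_end, three_prime_pos = g_start,
        length = L, gc_pct = gc, tm_on_target = tm
      )
    )
  })
  oligos <- dplyr::bind_rows(per_length)

  if (isTRUE(settings$flanking_mode)) {
    if (is.null(locus) || length(locus) != 2) {
      stop("enumerate_oligos: flanking_mode requires locus = c(start, stop)",
        call. = FALSE
      )
    }
    flank <- settings$flank_size %||% Inf
    oligos <- oligos |>
      dplyr::filter(
        (.data$strand == "F" & .data$three_prime_pos <= locus[1] &
          .data$five_prime_pos >= locus[1] - flank) |
          (.data$strand == "R" & .data$three_prime_pos >= locus[2] &
            .data$five_prime_pos <= locus[2] + flank)
      )
  }

  # palindromic oligos: self-complementary duplex (symmetry term, x = 1)
  pal <- oligos$length %% 2 == 0 &
    !grepl("[^ACGT]", oligos$seq) &
    oligos$seq == as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(
        gsub("[^ACGT]", "A", oligos$seq)
      ))
    )
  if (any(pal)) {
    cond1 <- conditions
    cond1$symmetry_x <- 1
    oligos$tm_on_target[pal] <- tm_duplex(oligos$seq[pal], cond1)
  }

  oligos |>
    dplyr::mutate(
      id = paste0(
        "TA_", region$chrom, "_", .data$five_prime_pos, "_",
        .data$length, "_", .data$strand
      ),
      chrom = region$chrom,
      .before = 1
    ) |>
    dplyr::arrange(
      pmin(.data$five_prime_pos, .data$three_prime_pos),
      .data$length, .data$strand
    )
}

empty_oligo_tbl <- function() {
  tibble::tibble(
    id = character(), chrom = character(), seq = character(),
    strand = character(), five_prime_pos = integer(),
    three_prime_pos = integer(), length = integer(),
    gc_pct = numeric(), tm_on_target = numeric()
  )
}

#' Sequence-feature filter flags
#'
#' Pure per-oligo predicates on the primer sequence: base composition
#' (`non_acgt`; also removes variant-masked oligos), GC range (`gc_range`),
#' 3'-terminal A/T (`at_end`), GC clamp (`gc_clamp`: more than three G/C in
#' the last five bases) and mono-/dinucleotide repeats (`repeats`). Disabled
#' filters never set their flag.
#'
#' @param oligos Oligo tibble from [enumerate_oligos()].
#' @param settings A [uod_settings()] object.
#' @return `oligos` with added logical flag columns and
#'   `pass_sequence_features`.
#' @export
sequence_feature_filter <- function(oligos, settings = uod_settings()) {
  u <- settings$repeat_units
  mono_re <- sprintf("(.)\\1{%d,}", u - 1)
  di_re <- sprintf("(..)\\1{%d,}", u - 1)
  last5 <- substring(oligos$seq, pmax(1, oligos$length - 4), oligos$length)
  last1 <- substring(oligos$seq, oligos$length, oligos$length)

  oligos |>
    dplyr::mutate(
      non_acgt = grepl("[^ACGT]", .data$seq),
      gc_range = !is.na(.data$gc_pct) &
        (.data$gc_pct < settings$gc_min | .data$gc_pct > settings$gc_max) |
        is.na(.data$gc_pct),
      at_end = isTRUE(settings$at_end_filter) & last1 %in% c("A", "T"),
      gc_clamp = isTRUE(settings$gc_clamp_filter) &
        stringr::str_count(last5, "[GC]") > 3,
      repeats = grepl(mono_re, .data$seq) | grepl(di_re, .data$seq),
      pass_sequence_features = !(.data$non_acgt | .data$gc_range |
        .data$at_end | .data$gc_clamp | .data$repeats)
    )
}

#' Hybridization (thermodynamic) filter flags
#'
#' Flags oligos whose on-target Tm falls outside the configured inclusive
#' range (`tm_range`) and whose most stable hairpin or homodimer melts within
#' `self_structure_margin` degrees of the on-target Tm (`hairpin`,
#' `homodimer`).
#'
#' @param oligos Oligo tibble (sequence-feature survivors).
#' @param settings A [uod_settings()] object.
#' @param conditions A [reaction_conditions()] object.
#' @return `oligos` with `hairpin_tm`, `homodimer_tm`, flag columns and
#'   `pass_hybridization`.
#' @export
hybridization_filter <- function(oligos, settings = uod_settings(),
                                 conditions = reaction_conditions()) {
  tm_range <- is.na(oligos$tm_on_target) |
    oligos$tm_on_target < settings$tm_min |
    oligos$tm_on_target > settings$tm_max
  # structure Tm only needs computing where the Tm-range test did not already
  # disqualify the oligo (both are pure predicates; the pass set is unchanged)
  hairpin_tm <- rep(NA_real_, nrow(oligos))
  homodimer_tm <- rep(NA_real_, nrow(oligos))
  todo <- which(!tm_range)
  hairpin_tm[todo] <- vapply(
    oligos$seq[todo], self_structure_tm,
    numeric(1),
    kind = "hairpin", conditions = conditions,
    USE.NAMES = FALSE
  )
  homodimer_tm[todo] <- vapply(
    oligos$seq[todo], self_structure_tm,
    numeric(1),
    kind = "homodimer", conditions = conditions,
    USE.NAMES = FALSE
  )
  margin <- settings$self_structure_margin
  oligos |>
    dplyr::mutate(
      hairpin_tm = hairpin_tm,
      homodimer_tm = homodimer_tm,
      tm_range = tm_range,
      hairpin = !is.na(hairpin_tm) &
        hairpin_tm > .data$tm_on_target - margin,
      homodimer = !is.na(homodimer_tm) &
        homodimer_tm > .data$tm_on_target - margin,
      pass_hybridization = !(.data$tm_range | .data$hairpin | .data$homodimer)
    )
}

#' Genome-wide exact-match uniqueness filter
#'
#' Flags (`off_target_exact`) every oligo whose sequence, or its reverse
#' complement, occurs anywhere in the genome outside the oligo's own target
#' site. Implemented as an exhaustive exact string search over both strands,
#' which is guaranteed to find every extra occurrence.
#'
#' @param oligos Oligo tibble (with genomic coordinates).
#' @param genome Genome from [load_genome()].
#' @return `oligos` with `n_genome_matches`, `off_target_exact` and
#'   `pass_exact_match` columns.
#' @export
exact_match_filter <- function(oligos, genome) {
  if (nrow(oligos) == 0) {
    return(dplyr::mutate(oligos,
      n_genome_matches = integer(),
      off_target_exact = logical(), pass_exact_match = logical()
    ))
  }
  hits <- genome_exact_hits(unique(oligos$seq), genome)

  win_start <- pmin(oligos$five_prime_pos, oligos$three_prime_pos)
  win_end <- pmax(oligos$five_prime_pos, oligos$three_prime_pos)
  own <- tibble::tibble(
    seq = oligos$seq, chrom = oligos$chrom,
    start = win_start, end = win_end
  )
  counts <- hits |>
    dplyr::count(.data$seq, .data$chrom, .data$start, .data$end,
      name = "n_at_site"
    )
  per_oligo <- own |>
    dplyr::left_join(
      counts |>
        dplyr::group_by(.data$seq) |>
        dplyr::summarise(total = sum(.data$n_at_site), .groups = "drop"),
      by = "seq"
    ) |>
    dplyr::left_join(counts,
      by = c("seq", "chrom", "start", "end")
    ) |>
    dplyr::mutate(
      n_at_site = dplyr::coalesce(.data$n_at_site, 0L),
      total = dplyr::coalesce(.data$total, 0L),
      off_site = .data$total - .data$n_at_site
    )

  oligos |>
    dplyr::mutate(
      n_genome_matches = per_oligo$total,
      off_target_exact = per_oligo$off_site > 0,
      pass_exact_match = !.data$off_target_exact
    )
}

# All exact occurrences of each sequence (or its reverse complement) on the
# plus strand of every chromosome. Returns tibble(seq, chrom, start, end).
genome_exact_hits <- function(seqs, genome) {
  stopifnot(!any(grepl("[^ACGT]", seqs)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)
  ))
  out <- list()
  for (len in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == len)
    pats <- unique(c(seqs[idx], rc[idx]))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
    for (chrom in names(genome)) {
      m <- Biostrings::matchPDict(pd, genome[[chrom]])
      n_per <- S4Vectors::elementNROWS(m)
      if (sum(n_per) == 0) next
      flat <- unlist(m)
      out[[length(out) + 1]] <- tibble::tibble(
        pattern = rep(pats, n_per),
        chrom = chrom,
        start = IRanges::start(flat),
        end = IRanges::end(flat)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      seq = character(), chrom = character(),
      start = integer(), end = integer()
    ))
  }
  hits <- dplyr::bind_rows(out)
  # map matches of the reverse complement back to the original sequence
  map <- tibble::tibble(pattern = c(seqs, rc), seq = c(seqs, seqs)) |>
    dplyr::distinct()
  hits |>
    dplyr::inner_join(map, by = "pattern",
      relationship = "many-to-many"
    ) |>
    dplyr::distinct(.data$seq, .data$chrom, .data$start, .data$end)
}

#' Run the full unique-oligo design cascade
#'
#' Enumerates every oligo in the region and applies the ordered filter
#' cascade: sequence features, then thermodynamic self-interactions, then
#' genome-wide exact-match uniqueness. Flags for a stage are only computed for
#' survivors of the previous stage (each filter is a pure predicate, so the
#' final pass set does not depend on this order).
#'
#' @param region A `target_region`.
#' @param genome Genome from [load_genome()].
#' @param settings A [uod_settings()] object.
#' @param conditions A [reaction_conditions()] object.
#' @param locus Optional locus coordinates for flanking mode.
#' @return A tibble of all enumerated oligos with filter flags and a logical
#'   `pass` column; per-category removal counts are attached as
#'   `attr(, "uod_counts")`.
#' @export
design_oligos <- function(region, genome, settings = uod_settings(),
                          conditions = reaction_conditions(), locus = NULL) {
  oligos <- enumerate_oligos(region, settings, conditions, locus = locus)
  n_enumerated <- nrow(oligos)
  if (n_enumerated == 0) {
    return(structure(oligos, uod_counts = tibble::tibble(
      stage = character(), category = character(), n_flagged = integer()
    )))
  }

  feats <- sequence_feature_filter(oligos, settings)
  surv1 <- dplyr::filter(feats, .data$pass_sequence_features)

  hyb <- hybridization_filter(surv1, settings, conditions)
  surv2 <- dplyr::filter(hyb, .data$pass_hybridization)

  uniq <- exact_match_filter(surv2, genome)

  counts <- dplyr::bind_rows(
    tibble::tibble(
      stage = "enumerated", category = "total",
      n_flagged = n_enumerated
    ),
    tidyr::pivot_longer(
      dplyr::summarise(feats, dplyr::across(
        c("non_acgt", "gc_range", "at_end", "gc_clamp", "repeats"), sum
      )),
      dplyr::everything(),
      names_to = "category", values_to = "n_flagged"
    ) |>
      dplyr::mutate(stage = "sequence_features", .before = 1),
    tidyr::pivot_longer(
      dplyr::summarise(hyb, dplyr::across(
        c("tm_range", "hairpin", "homodimer"), sum
      )),
      dplyr::everything(),
      names_to = "category", values_to = "n_flagged"
    ) |>
      dplyr::mutate(stage = "interactions", .before = 1),
    tibble::tibble(
      stage = "interactions", category = "off_target_exact",
      n_flagged = sum(uniq$off_target_exact)
    )
  )

  result <- dplyr::bind_rows(
    dplyr::mutate(
      dplyr::anti_join(feats, surv1, by = "id"),
      pass = FALSE
    ),
    dplyr::mutate(
      dplyr::anti_join(hyb, surv2, by = "id"),
      pass = FALSE
    ),
    dplyr::mutate(uniq, pass = .data$pass_exact_match)
  ) |>
    dplyr::arrange(
      pmin(.data$five_prime_pos, .data$three_prime_pos),
      .data$length, .data$strand
    )
  attr(result, "uod_counts") <- counts
  result
}
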
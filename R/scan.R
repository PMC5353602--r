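#' Parameters for the off-target local-alignment scan
#'
#' The scanner mirrors a low-stringency seed-and-extend search: every exact
#' `word_size`-mer of the primer seeds a banded local alignment (match +1,
#' mismatch -1, gap open/extend 2) of the primer against a padded genomic
#' window around the seed, on both strands. Alignments scoring below
#' `score_min`, with percent identity below `min_identity`, or without an
#' exact `word_size` run of matches are discarded (`score_min` plays the role
#' of the permissive expectation-value cutoff of heuristic search tools: it
#' removes bare seed matches while keeping any alignment long and similar
#' enough to matter for mispriming). Caps default to off (the exhaustive
#' search); they can be set to emulate capped heuristic searches.
#'
#' @param word_size Exact-match seed length (default 7).
#' @param min_identity Minimum percent identity of a reported local alignment
#'   (default 70).
#' @param score_min Minimum local alignment score (default 10).
#' @param max_hits_per_subject,max_subjects Optional caps (default `Inf`).
#' @param pad Extra genomic bases on each side of the seeded window
#'   (default 10); also bounds the net alignment shift the banded extension
#'   can follow (half of `pad`).
#' @return A `scan_params` list.
#' @export
scan_params <- function(word_size = 7, min_identity = 70, score_min = 10,
                        max_hits_per_subject = Inf, max_subjects = Inf,
                        pad = 10) {
  structure(
    list(
      word_size = as.integer(word_size), min_identity = min_identity,
      score_min = score_min,
      max_hits_per_subject = max_hits_per_subject,
      max_subjects = max_subjects, pad = as.integer(pad)
    ),
    class = "scan_params"
  )
}

empty_hit_tbl <- function() {
  tibble::tibble(
    primer_id = character(), subject_name = character(),
    subject_strand = character(), subject_start = integer(),
    subject_stop = integer(), primer_aln_start = integer(),
    primer_aln_stop = integer(), aligned_primer = character(),
    aligned_subject = character(), percent_identity = numeric(),
    score = numeric()
  )
}

# longest run of identical aligned (non-gap) columns
longest_match_run <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  eq <- a == b & a != "-"
  if (!any(eq)) {
    return(0L)
  }
  r <- rle(eq)
  max(r$lengths[r$values])
}

# rowMaxs without an extra dependency
matrixStats_rowMaxs <- function(m) {
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# integer codes for a DNA character string (N never equals a base code)
dna_codes <- function(x) {
  utf8ToInt(x)
}

#' Find off-target binding sites for a table of candidate primers
#'
#' Seeds with every exact `word_size`-mer of each primer on both genome
#' strands, prescreens each seeded anchor with a banded local alignment, and
#' aligns the surviving windows with [Biostrings::pairwiseAlignment()]
#' (match +1, mismatch -1, gap open/extend 2, local). Each primer's own
#' target site is excluded (any hit overlapping it by at least 1 bp on the
#' binding strand). Hits are deterministic and ordered by primer, subject,
#' then position. The aligned subject is reported in the primer frame (same
#' sense as the primer; a column matches when the characters are equal).
#'
#' @param candidates Tibble with `id`, `seq`, `chrom`, `strand`,
#'   `five_prime_pos`, `three_prime_pos` (as produced by [design_oligos()]).
#' @param genome Genome from [load_genome()].
#' @param params A [scan_params()] object.
#' @return A tibble of local hits (possibly empty): `primer_id`,
#'   `subject_name`, `subject_strand` (+/-), `subject_start`, `subject_stop`
#'   (1-based on the + strand), `primer_aln_start`, `primer_aln_stop` (within
#'   the primer, 5' to 3'), `aligned_primer`, `aligned_subject` (gapped),
#'   `percent_identity`, `score`.
#' @export
scan_offtargets <- function(candidates, genome, params = scan_params()) {
  if (nrow(candidates) == 0) {
    return(empty_hit_tbl())
  }
  stopifnot(!any(grepl("[^ACGT]", candidates$seq)))
  w <- params$word_size
  band <- max(1L, params$pad %/% 2L)
  n_primer <- nrow(candidates)
  lens <- nchar(candidates$seq)

  # global seed table: every word of every primer
  seed_rows <- purrr::map(seq_len(n_primer), function(p) {
    L <- lens[p]
    if (L < w) {
      return(NULL)
    }
    starts <- seq_len(L - w + 1)
    tibble::tibble(
      primer = p, offset = starts,
      seed = substring(candidates$seq[p], starts, starts + w - 1)
    )
  })
  seed_tbl <- dplyr::bind_rows(seed_rows)
  if (nrow(seed_tbl) == 0) {
    return(empty_hit_tbl())
  }
  useeds <- unique(seed_tbl$seed)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(useeds))

  primer_codes <- lapply(candidates$seq, dna_codes)

  own_start <- pmin(candidates$five_prime_pos, candidates$three_prime_pos)
  own_end <- pmax(candidates$five_prime_pos, candidates$three_prime_pos)
  own_orient <- ifelse(candidates$strand == "R", "-", "+")

  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE
  )

  # phase 1: seed matching + banded prescreen, collecting surviving windows
  win_list <- list()
  for (chrom in names(genome)) {
    chrom_seq <- genome[[chrom]]
    len <- length(chrom_seq)
    for (orient in c("+", "-")) {
      subj <- if (orient == "+") {
        chrom_seq
      } else {
        Biostrings::reverseComplement(chrom_seq)
      }
      subj_codes <- dna_codes(as.character(subj))
      m <- Biostrings::matchPDict(pd, subj)
      n_per <- S4Vectors::elementNROWS(m)
      if (sum(n_per) == 0) next
      flat <- unlist(m)
      anchor_tbl <- tibble::tibble(
        seed = rep(useeds, n_per),
        match_start = IRanges::start(flat)
      ) |>
        dplyr::inner_join(seed_tbl, by = "seed",
          relationship = "many-to-many"
        ) |>
        dplyr::mutate(anchor = .data$match_start - .data$offset + 1L) |>
        dplyr::distinct(.data$primer, .data$anchor)

      # banded prescreen, grouped by primer length so the recurrence is
      # vectorized over all anchors of all primers of that length at once
      anchor_tbl$len <- lens[anchor_tbl$primer]
      keep_rows <- list()
      for (L in unique(anchor_tbl$len)) {
        rows <- anchor_tbl[anchor_tbl$len == L, , drop = FALSE]
        pc <- matrix(
          unlist(primer_codes[rows$primer]),
          nrow = nrow(rows), byrow = TRUE
        )
        scores <- banded_screen_scores_rows(
          pc, subj_codes, rows$anchor, band
        )
        keep_rows[[length(keep_rows) + 1]] <-
          rows[scores >= params$score_min, , drop = FALSE]
      }
      survivors <- dplyr::bind_rows(keep_rows)
      if (nrow(survivors) == 0) next

      win_start <- pmax(1L, survivors$anchor - params$pad)
      win_end <- pmin(len, survivors$anchor + survivors$len - 1L + params$pad)
      keep <- win_end - win_start + 1L >= w
      wins <- tibble::tibble(
        primer = survivors$primer[keep],
        chrom = chrom, orient = orient, subj_len = len,
        start = win_start[keep], end = win_end[keep]
      ) |>
        dplyr::distinct()
      if (nrow(wins) == 0) next
      wins$win_seq <- as.character(Biostrings::DNAStringSet(
        Biostrings::Views(subj, wins$start, wins$end)
      ))
      win_list[[length(win_list) + 1]] <- wins
    }
  }
  if (length(win_list) == 0) {
    return(empty_hit_tbl())
  }
  windows <- dplyr::bind_rows(win_list)

  # phase 2: one local alignment call per primer over all its windows
  out <- list()
  for (p in unique(windows$primer)) {
    wp <- windows[windows$primer == p, , drop = FALSE]
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(wp$win_seq),
      subject = Biostrings::DNAString(candidates$seq[p]),
      type = "local", substitutionMatrix = sub_mat,
      gapOpening = 2, gapExtension = 2
    )
    score <- Biostrings::score(aln)
    nmatches <- Biostrings::nmatch(aln)
    p_rng <- Biostrings::pattern(aln)
    q_rng <- Biostrings::subject(aln)
    ap <- as.character(p_rng)
    as_ <- as.character(q_rng)
    p_start <- IRanges::start(p_rng)
    p_end <- IRanges::end(p_rng)
    q_start <- IRanges::start(q_rng)
    q_end <- IRanges::end(q_rng)

    ok <- which(score >= params$score_min)
    if (length(ok) == 0) next
    o_start <- wp$start[ok] + p_start[ok] - 1L
    o_end <- wp$start[ok] + p_end[ok] - 1L
    minus <- wp$orient[ok] == "-"
    s_start <- ifelse(minus, wp$subj_len[ok] - o_end + 1L, o_start)
    s_stop <- ifelse(minus, wp$subj_len[ok] - o_start + 1L, o_end)
    out[[length(out) + 1]] <- tibble::tibble(
      primer = p,
      primer_id = candidates$id[p],
      subject_name = wp$chrom[ok],
      subject_strand = wp$orient[ok],
      subject_start = as.integer(s_start),
      subject_stop = as.integer(s_stop),
      primer_aln_start = q_start[ok],
      primer_aln_stop = q_end[ok],
      aligned_primer = unname(as_[ok]),
      aligned_subject = unname(ap[ok]),
      percent_identity = 100 * nmatches[ok] / nchar(ap[ok]),
      score = score[ok]
    )
  }
  if (length(out) == 0) {
    return(empty_hit_tbl())
  }
  hits <- dplyr::bind_rows(out) |>
    dplyr::distinct(
      .data$primer, .data$subject_name, .data$subject_strand,
      .data$subject_start, .data$subject_stop,
      .data$primer_aln_start, .data$primer_aln_stop,
      .keep_all = TRUE
    ) |>
    dplyr::filter(.data$percent_identity >= params$min_identity)
  if (nrow(hits) > 0) {
    runs <- mapply(
      longest_match_run,
      hits$aligned_primer, hits$aligned_subject
    )
    hits <- hits[runs >= w, , drop = FALSE]
  }
  # drop each primer's own target site (overlap on the binding strand)
  hits <- hits |>
    dplyr::filter(!(
      !is.na(own_start[.data$primer]) &
        .data$subject_name == candidates$chrom[.data$primer] &
        .data$subject_strand == own_orient[.data$primer] &
        .data$subject_start <= own_end[.data$primer] &
        .data$subject_stop >= own_start[.data$primer]
    ))
  # optional caps, applied on score then resolved deterministically
  if (is.finite(params$max_hits_per_subject)) {
    hits <- hits |>
      dplyr::group_by(.data$primer, .data$subject_name) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$subject_start,
        .by_group = TRUE
      ) |>
      dplyr::slice_head(n = params$max_hits_per_subject) |>
      dplyr::ungroup()
  }
  if (is.finite(params$max_subjects)) {
    keep_subj <- hits |>
      dplyr::group_by(.data$primer, .data$subject_name) |>
      dplyr::summarise(best = max(.data$score), .groups = "drop_last") |>
      dplyr::arrange(dplyr::desc(.data$best), .data$subject_name,
        .by_group = TRUE
      ) |>
      dplyr::slice_head(n = params$max_subjects) |>
      dplyr::ungroup() |>
      dplyr::mutate(key = paste(.data$primer, .data$subject_name))
    hits <- dplyr::filter(
      hits,
      paste(.data$primer, .data$subject_name) %in% keep_subj$key
    )
  }
  hits |>
    dplyr::arrange(
      .data$primer, .data$subject_name, .data$subject_start,
      .data$subject_strand
    ) |>
    dplyr::select(-"primer")
}

# banded screen where each anchor row carries its own primer codes (matrix
# `pc`, one row per anchor; all primers share the same length)
banded_screen_scores_rows <- function(pc, subj_codes, anchors,
                                      band = 5, gap = 2) {
  n <- length(anchors)
  L <- ncol(pc)
  slen <- length(subj_codes)
  ks <- -band:band
  h_prev <- matrix(0, n, length(ks))
  best <- numeric(n)
  for (i in seq_len(L)) {
    h_cur <- matrix(0, n, length(ks))
    pci <- pc[, i]
    for (kidx in seq_along(ks)) {
      j <- anchors + (i - 1L) + ks[kidx]
      valid <- j >= 1L & j <= slen
      s <- ifelse(valid & subj_codes[pmax(j, 1L)] == pci, 1, -1)
      s[!valid] <- -99
      cand <- pmax(0, h_prev[, kidx] + s)
      if (kidx < length(ks)) {
        cand <- pmax(cand, h_prev[, kidx + 1] - gap)
      }
      if (kidx > 1) {
        cand <- pmax(cand, h_cur[, kidx - 1] - gap)
      }
      h_cur[, kidx] <- cand
    }
    best <- pmax(best, matrixStats_rowMaxs(h_cur))
    h_prev <- h_cur
  }
  best
}

#' Find candidate off-target binding sites for one primer
#'
#' Single-primer interface over the batch scanner [scan_offtargets()].
#'
#' @param primer One-row tibble with `id`, `seq`, `chrom`, `strand`,
#'   `five_prime_pos`, `three_prime_pos`, or a bare sequence string (then no
#'   on-target exclusion applies).
#' @param genome Genome from [load_genome()].
#' @param params A [scan_params()] object.
#' @return A hit tibble; see [scan_offtargets()].
#' @export
find_local_hits <- function(primer, genome, params = scan_params()) {
  if (is.character(primer)) {
    primer <- tibble::tibble(
      id = "query", seq = primer, chrom = NA_character_,
      strand = "F", five_prime_pos = NA_integer_,
      three_prime_pos = NA_integer_
    )
  }
  stopifnot(nrow(primer) == 1)
  scan_offtargets(primer, genome, params)
}

#' Export / import local hits as a BLAST-like tabular file
#'
#' The tabular format has columns `qseqid`, `sseqid`, `sstrand` (`plus` /
#' `minus`), `sstart`, `send`, `qstart`, `qend`, `qseq_aln`, `sseq_aln`,
#' `pident`. On import, rows whose subject coordinates are reversed (minus
#' strand convention) are normalized to plus-strand coordinates with the
#' strand flag set; rows referencing unknown primer ids and malformed rows are
#' rejected with a reported count.
#'
#' @param hits Hit tibble from [find_local_hits()] / [scan_offtargets()].
#' @param path Tabular file path.
#' @return `export_hits()` returns `path` invisibly; `import_external_hits()`
#'   returns a hit tibble identical in shape to [scan_offtargets()] output.
#' @export
export_hits <- function(hits, path) {
  readr::write_tsv(
    tibble::tibble(
      qseqid = hits$primer_id,
      sseqid = hits$subject_name,
      sstrand = ifelse(hits$subject_strand == "+", "plus", "minus"),
      sstart = hits$subject_start,
      send = hits$subject_stop,
      qstart = hits$primer_aln_start,
      qend = hits$primer_aln_stop,
      qseq_aln = hits$aligned_primer,
      sseq_aln = hits$aligned_subject,
      pident = hits$percent_identity
    ),
    path
  )
  invisible(path)
}

#' @param primer_catalog Tibble of known primers (column `id`), used to reject
#'   rows referencing unknown primer ids.
#' @rdname export_hits
#' @export
import_external_hits <- function(path, primer_catalog) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    qseqid = readr::col_character(),
    sseqid = readr::col_character(),
    sstrand = readr::col_character(),
    sstart = readr::col_integer(),
    send = readr::col_integer(),
    qstart = readr::col_integer(),
    qend = readr::col_integer(),
    qseq_aln = readr::col_character(),
    sseq_aln = readr::col_character(),
    pident = readr::col_double()
  ))
  malformed <- is.na(raw$sstart) | is.na(raw$send) | is.na(raw$qstart) |
    is.na(raw$qend) | is.na(raw$qseq_aln) | is.na(raw$sseq_aln) |
    is.na(raw$pident) | nchar(raw$qseq_aln) != nchar(raw$sseq_aln)
  if (any(malformed)) {
    message(
      "import_external_hits: rejected ", sum(malformed),
      " malformed row(s)"
    )
    raw <- raw[!malformed, , drop = FALSE]
  }
  unknown <- !raw$qseqid %in% primer_catalog$id
  if (any(unknown)) {
    message(
      "import_external_hits: rejected ", sum(unknown),
      " row(s) with unknown primer id(s): ",
      paste(utils::head(unique(raw$qseqid[unknown]), 5), collapse = ", ")
    )
    raw <- raw[!unknown, , drop = FALSE]
  }
  # minus-strand rows may carry reversed subject coordinates
  rev_coords <- raw$sstart > raw$send
  strand <- dplyr::case_when(
    rev_coords | raw$sstrand %in% c("minus", "-") ~ "-",
    TRUE ~ "+"
  )
  tibble::tibble(
    primer_id = raw$qseqid,
    subject_name = raw$sseqid,
    subject_strand = strand,
    subject_start = pmin(raw$sstart, raw$send),
    subject_stop = pmax(raw$sstart, raw$send),
    primer_aln_start = raw$qstart,
    primer_aln_stop = raw$qend,
    aligned_primer = raw$qseq_aln,
    aligned_subject = raw$sseq_aln,
    percent_identity = raw$pident,
    score = NA_real_
  ) |>
    dplyr::arrange(
      .data$primer_id, .data$subject_name,
      .data$subject_start, .data$subject_strand
    )
}
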
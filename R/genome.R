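#' Load a reference genome from FASTA files
#'
#' Reads one or more (multi-record) FASTA files into a single indexed genome.
#' Record names must be unique across files; empty records and characters
#' outside A/C/G/T/N are rejected. Lower-case soft masking is uppercased on
#' load (repeat masking plays no role in the algorithms here); a message
#' reports how many records contained lower-case characters.
#'
#' @param fasta_paths Character vector of FASTA file paths.
#' @return A [Biostrings::DNAStringSet] with unique names, usable for random
#'   access by `(name, start, stop)` via [Biostrings::subseq()].
#' @export
load_genome <- function(fasta_paths) {
  sets <- lapply(fasta_paths, Biostrings::readDNAStringSet)
  genome <- do.call(c, sets)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    dups <- unique(names(genome)[duplicated(names(genome))])
    stop("load_genome: duplicate sequence names: ",
      paste(dups, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(Biostrings::width(genome) == 0)) {
    empties <- names(genome)[Biostrings::width(genome) == 0]
    stop("load_genome: empty records: ", paste(empties, collapse = ", "),
      call. = FALSE
    )
  }
  freq <- Biostrings::alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, !colnames(freq) %in% allowed, drop = FALSE])
  if (any(bad > 0)) {
    stop("load_genome: records with characters outside A/C/G/T/N: ",
      paste(names(genome)[bad > 0], collapse = ", "),
      call. = FALSE
    )
  }
  genome
}

#' Convert a VCF into a compact variant-position table
#'
#' Reads a VCF (v4.0/4.1) sharing the genome's coordinate system and reduces
#' it to one row per site with a class label: `snp` when REF and every ALT
#' allele are single bases, otherwise `indel`, recorded at its single POS
#' (indels spanning several bases are encoded at one position). Malformed
#' records are skipped with a reported count. When a SNP and an indel collide
#' at one position, the indel wins.
#'
#' @param vcf_path Path to a VCF file.
#' @return A tibble with columns `chrom`, `pos` (1-based), `class`
#'   (`"snp"` or `"indel"`), sorted by chromosome and position.
#' @export
convert_variants <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
    stringsAsFactors = FALSE
  ))
  n_in <- nrow(fix)
  fix$pos_num <- suppressWarnings(as.integer(fix$POS))
  ok <- !is.na(fix$pos_num) & !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF != "" & fix$ALT != ""
  n_skipped <- n_in - sum(ok)
  if (n_skipped > 0) {
    message("convert_variants: skipped ", n_skipped, " malformed record(s)")
  }
  fix <- fix[ok, , drop = FALSE]
  alt_lens <- vapply(
    strsplit(fix$ALT, ",", fixed = TRUE),
    function(a) max(nchar(a)), integer(1)
  )
  out <- tibble::tibble(
    chrom = fix$CHROM,
    pos = fix$pos_num,
    class = ifelse(nchar(fix$REF) == 1 & alt_lens == 1, "snp", "indel")
  )
  out |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      class = if (any(.data$class == "indel")) "indel" else "snp",
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Write / read the persisted 3-column variant table
#'
#' @param variants Tibble from [convert_variants()].
#' @param path File path for the tab-separated table (chrom, pos, class).
#' @return `path` (write) or the variant tibble (read), invisibly for write.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    class = readr::col_character()
  ))
}

#' Extract a (variant-masked) target region
#'
#' Slices `[start, stop]` (1-based, inclusive) from a chromosome and, when
#' masking is enabled, rewrites known variant positions to indicator
#' characters: `n` for SNPs, `N` for indels. Assembly gaps (runs of `N` of at
#' least `gap_min` in the reference itself) are preserved and reported as
#' intervals. The summary GC% is computed over A/C/G/T characters only.
#'
#' @param genome A genome from [load_genome()].
#' @param chrom Chromosome name.
#' @param start,stop 1-based inclusive coordinates.
#' @param variants Optional variant table from [convert_variants()].
#' @param mask_enabled Apply variant masking (default `TRUE` when `variants`
#'   is supplied).
#' @param gap_min Minimum N-run length that counts as an assembly gap
#'   (default 100).
#' @return A `target_region` list: `chrom`, `start`, `stop`, `raw_seq`,
#'   `masked_seq`, and `summary` (tibble: gc_pct, n_snps, n_indels) with
#'   `gap_runs` (tibble of genomic intervals).
#' @export
extract_masked_region <- function(genome, chrom, start, stop,
                                  variants = NULL,
                                  mask_enabled = !is.null(variants),
                                  gap_min = 100) {
  if (!chrom %in% names(genome)) {
    stop("extract_masked_region: unknown chromosome '", chrom, "'",
      call. = FALSE
    )
  }
  chrom_len <- Biostrings::width(genome[chrom])
  if (start < 1 || stop > chrom_len || start > stop) {
    stop("extract_masked_region: coordinates out of range (1..", chrom_len,
      ")",
      call. = FALSE
    )
  }
  raw_seq <- as.character(Biostrings::subseq(genome[[chrom]], start, stop))
  chars <- strsplit(raw_seq, "", fixed = TRUE)[[1]]

  n_snps <- 0L
  n_indels <- 0L
  v <- tibble::tibble(chrom = character(), pos = integer(), class = character())
  if (!is.null(variants)) {
    v <- variants[variants$chrom == chrom &
      variants$pos >= start & variants$pos <= stop, , drop = FALSE]
  }
  if (nrow(v) > 0) {
    n_snps <- sum(v$class == "snp")
    n_indels <- sum(v$class == "indel")
    if (isTRUE(mask_enabled)) {
      local_pos <- v$pos - start + 1L
      chars[local_pos[v$class == "snp"]] <- "n"
      chars[local_pos[v$class == "indel"]] <- "N"
    }
  }
  masked_seq <- paste(chars, collapse = "")

  offset <- start - 1L
  gap_runs <- find_gap_runs(raw_seq, gap_min) |>
    dplyr::mutate(
      start = .data$start + .env$offset,
      stop = .data$stop + .env$offset
    )

  acgt <- strsplit(raw_seq, "", fixed = TRUE)[[1]]
  is_base <- acgt %in% BASES & !(seq_along(acgt) %in%
    which(chars %in% c("n", "N")))
  gc_pct <- if (any(is_base)) {
    100 * sum(acgt[is_base] %in% c("G", "C")) / sum(is_base)
  } else {
    NA_real_
  }

  structure(
    list(
      chrom = chrom,
      start = start,
      stop = stop,
      raw_seq = raw_seq,
      masked_seq = masked_seq,
      variant_sites = v,
      summary = tibble::tibble(
        chrom = chrom, start = start, stop = stop,
        length = stop - start + 1L,
        gc_pct = gc_pct, n_snps = n_snps, n_indels = n_indels,
        n_gap_runs = nrow(gap_runs)
      ),
      gap_runs = gap_runs
    ),
    class = "target_region"
  )
}

# Maximal runs of N (>= gap_min) in a sequence; coordinates local (1-based).
find_gap_runs <- function(seq, gap_min = 100) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(chars == "N")
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  keep <- r$values & r$lengths >= gap_min
  tibble::tibble(start = starts[keep], stop = stops[keep])
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf(
    "<target_region> %s:%d-%d (%d bp, GC %.1f%%, %d SNPs, %d indels, %d gap runs)\n",
    x$chrom, x$start, x$stop, x$stop - x$start + 1,
    x$summary$gc_pct, x$summary$n_snps, x$summary$n_indels,
    nrow(x$gap_runs)
  ))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a target region
#'
#' @param x A `target_region`.
#' @param ... Unused.
#' @return The region's summary tibble (one row).
#' @method glance target_region
#' @export
glance.target_region <- function(x, ...) {
  x$summary
}
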
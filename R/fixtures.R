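#' Specification for a deterministic synthetic test genome
#'
#' Describes a multi-chromosome genome with tunable GC content, planted
#' divergent repeat families (which create off-target priming sites),
#' assembly-gap N runs, and a set of SNP/indel variant positions inside a
#' target interval. Generation is fully deterministic for a fixed seed.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param gc_fraction Target GC fraction of the background sequence
#'   (realized GC is asserted to within 2 percentage points at test time).
#' @param repeat_families Tibble with one row per family: `copies` (total),
#'   `in_target` (how many of them are laid out inside the target interval,
#'   evenly spaced with random jitter, emulating a repeat-dense target the
#'   way highly repetitive plant genomes present one), `length` (bp of the
#'   repeat unit), `divergence` (per-base substitution rate between copies;
#'   0 gives exact copies that off-target exact matching must catch),
#'   `indel_rate` (per-copy probability of one 1-nt deletion).
#' @param gap_runs Tibble of planted assembly gaps: `chrom`, `start`,
#'   `length` (conventionally 100 or 1000).
#' @param n_snps,n_indels Variant counts planted inside the target interval.
#' @param target Named list or vector `chrom`, `start`, `stop`: the target
#'   interval used for variant planting and for pipeline runs.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1,
                         n_chroms = 2,
                         chrom_length = 25000,
                         gc_fraction = 0.46,
                         repeat_families = tibble::tibble(
                           copies = c(14, 4), in_target = c(6, 2),
                           length = c(400, 300),
                           divergence = c(0, 0.05),
                           indel_rate = c(0, 0.25)
                         ),
                         gap_runs = tibble::tibble(
                           chrom = character(), start = integer(),
                           length = integer()
                         ),
                         n_snps = 180, n_indels = 16,
                         target = list(
                           chrom = "chr1", start = 8001, stop = 12000
                         )) {
  stopifnot(
    n_chroms >= 1, chrom_length >= 1000,
    gc_fraction > 0, gc_fraction < 1
  )
  structure(
    list(
      seed = as.integer(seed), n_chroms = as.integer(n_chroms),
      chrom_length = as.integer(chrom_length), gc_fraction = gc_fraction,
      repeat_families = repeat_families, gap_runs = gap_runs,
      n_snps = as.integer(n_snps), n_indels = as.integer(n_indels),
      target = target
    ),
    class = "fixture_spec"
  )
}

sample_bases <- function(n, gc) {
  sample(BASES, n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  )
}

#' Generate a synthetic genome with planted features
#'
#' Builds the background sequence, plants the divergent repeat-family copies
#' at non-overlapping random positions (substitutions at the stated
#' per-base rate; optionally one single-nucleotide deletion per copy),
#' overwrites assembly-gap N runs, and records every planted feature in a
#' truth table for scanner-completeness checks.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `genome` ([Biostrings::DNAStringSet]) and `truth` (tibble:
#'   `chrom`, `start`, `stop`, `family`, `copy`, `n_subs`, `n_indels`,
#'   `identity_pct` of the copy against the family master).
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  chrom_names <- paste0("chr", seq_len(spec$n_chroms))
  chroms <- lapply(chrom_names, function(nm) {
    sample_bases(spec$chrom_length, spec$gc_fraction)
  })
  names(chroms) <- chrom_names

  occupied <- stats::setNames(
    replicate(spec$n_chroms, IRanges::IRanges(), simplify = FALSE),
    chrom_names
  )
  for (g in seq_len(nrow(spec$gap_runs))) {
    gchrom <- spec$gap_runs$chrom[g]
    gstart <- spec$gap_runs$start[g]
    glen <- spec$gap_runs$length[g]
    if (gstart + glen - 1 > spec$chrom_length) {
      stop("generate_genome: gap run exceeds chromosome length",
        call. = FALSE
      )
    }
    chroms[[gchrom]][gstart:(gstart + glen - 1)] <- "N"
    occupied[[gchrom]] <- c(
      occupied[[gchrom]],
      IRanges::IRanges(gstart, gstart + glen - 1)
    )
  }

  truth <- list()
  fams <- spec$repeat_families
  if (!"in_target" %in% names(fams)) fams$in_target <- 0L
  masters <- lapply(
    fams$length, function(len) sample_bases(len, spec$gc_fraction)
  )

  mutate_copy <- function(master, divergence, indel_rate) {
    seq_copy <- master
    unit_len <- length(master)
    n_sub <- stats::rbinom(1, unit_len, divergence)
    if (n_sub > 0) {
      sub_pos <- sample.int(unit_len, n_sub)
      for (p in sub_pos) {
        seq_copy[p] <- sample(setdiff(BASES, seq_copy[p]), 1)
      }
    }
    n_del <- 0L
    if (stats::runif(1) < indel_rate) {
      del_pos <- sample.int(unit_len - 2, 1) + 1
      seq_copy <- seq_copy[-del_pos]
      n_del <- 1L
    }
    list(seq = seq_copy, n_sub = n_sub, n_del = n_del)
  }

  plant <- function(fam, copy, cpos_chrom, cpos) {
    unit_len <- fams$length[fam]
    mut <- mutate_copy(
      masters[[fam]], fams$divergence[fam], fams$indel_rate[fam]
    )
    written_len <- length(mut$seq)
    chroms[[cpos_chrom]][cpos:(cpos + written_len - 1)] <<- mut$seq
    occupied[[cpos_chrom]] <<- c(
      occupied[[cpos_chrom]],
      IRanges::IRanges(cpos, cpos + unit_len - 1)
    )
    truth[[length(truth) + 1]] <<- tibble::tibble(
      chrom = cpos_chrom, start = cpos,
      stop = cpos + written_len - 1,
      family = fam, copy = copy,
      n_subs = mut$n_sub, n_indels = mut$n_del,
      identity_pct = 100 * (unit_len - mut$n_sub - mut$n_del) / unit_len
    )
  }

  # in-target copies: evenly spaced slots with random jitter, emulating a
  # repeat-dense target region
  fam_of_slot <- rep(seq_len(nrow(fams)), fams$in_target)
  if (length(fam_of_slot) > 0) {
    if (is.null(spec$target)) {
      stop("generate_genome: in_target repeat copies require a target",
        call. = FALSE
      )
    }
    tlen <- spec$target$stop - spec$target$start + 1L
    slack <- tlen - sum(fams$length[fam_of_slot])
    gap <- slack %/% (length(fam_of_slot) + 1L)
    if (gap < 4) {
      stop("generate_genome: infeasible packing of planted features",
        call. = FALSE
      )
    }
    pos <- spec$target$start
    copy_counter <- integer(nrow(fams))
    for (k in seq_along(fam_of_slot)) {
      fam <- fam_of_slot[k]
      copy_counter[fam] <- copy_counter[fam] + 1L
      jitter <- sample.int(gap %/% 2, 1) - gap %/% 4
      pos <- pos + max(1L, gap + jitter)
      plant(fam, copy_counter[fam], spec$target$chrom, pos)
      pos <- pos + fams$length[fam]
    }
  }

  # remaining copies: random non-overlapping placement across the genome
  for (fam in seq_len(nrow(fams))) {
    unit_len <- fams$length[fam]
    n_extra <- fams$copies[fam] - fams$in_target[fam]
    for (copy in seq_len(max(0L, n_extra))) {
      placed <- FALSE
      for (try in 1:200) {
        cpos_chrom <- sample(chrom_names, 1)
        cpos <- sample.int(spec$chrom_length - unit_len - 1, 1)
        cand <- IRanges::IRanges(cpos, cpos + unit_len - 1)
        if (length(IRanges::findOverlaps(
          cand, occupied[[cpos_chrom]]
        )) == 0) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("generate_genome: infeasible packing of planted features",
          call. = FALSE
        )
      }
      plant(fam, fams$in_target[fam] + copy, cpos_chrom, cpos)
    }
  }

  genome <- Biostrings::DNAStringSet(
    vapply(chroms, paste, character(1), collapse = "")
  )
  names(genome) <- chrom_names
  list(
    genome = genome,
    truth = if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble(
      chrom = character(), start = integer(), stop = integer(),
      family = integer(), copy = integer(), n_subs = integer(),
      n_indels = integer(), identity_pct = numeric()
    )
  )
}

#' Plant SNP and indel variants and emit them as VCF records
#'
#' Draws `n_snps` single-base substitutions and `n_indels` short deletions at
#' distinct non-N positions inside the target interval; indels use a
#' multi-base REF anchored at a single POS. Position collisions are resolved
#' by re-drawing.
#'
#' @param spec A [fixture_spec()].
#' @param genome The genome from [generate_genome()].
#' @return A list: `variants` truth tibble (`chrom`, `pos`, `class`, `ref`,
#'   `alt`) and `vcf_lines` (character vector of VCF v4.1 text).
#' @export
generate_variants <- function(spec, genome) {
  set.seed(spec$seed + 1L)
  tchrom <- spec$target$chrom
  tstart <- spec$target$start
  tstop <- spec$target$stop
  chars <- strsplit(
    as.character(Biostrings::subseq(
      genome[[tchrom]], tstart, tstop
    )), "",
    fixed = TRUE
  )[[1]]
  usable <- which(chars %in% BASES)
  usable <- usable[usable < length(chars)] # room for a 2-base indel REF
  n_total <- spec$n_snps + spec$n_indels
  stopifnot(length(usable) >= n_total)
  pick <- sort(sample(usable, n_total))
  # avoid adjacent picks so a deletion REF never spans another variant
  while (any(diff(pick) == 1)) {
    bad <- which(diff(pick) == 1)[1] + 1
    replacement <- sample(setdiff(usable, c(pick, pick + 1, pick - 1)), 1)
    pick[bad] <- replacement
    pick <- sort(pick)
  }
  classes <- rep(c("snp", "indel"), c(spec$n_snps, spec$n_indels))
  classes <- classes[sample.int(n_total)]

  pos <- tstart + pick - 1L
  ref <- character(n_total)
  alt <- character(n_total)
  for (i in seq_len(n_total)) {
    if (classes[i] == "snp") {
      ref[i] <- chars[pick[i]]
      alt[i] <- sample(setdiff(BASES, ref[i]), 1)
    } else {
      ref[i] <- paste0(chars[pick[i]], chars[pick[i] + 1])
      alt[i] <- chars[pick[i]]
    }
  }
  variants <- tibble::tibble(
    chrom = tchrom, pos = pos, class = classes, ref = ref, alt = alt
  )
  header <- c(
    "##fileformat=VCFv4.1",
    paste0(
      "##contig=<ID=", names(genome), ",length=",
      Biostrings::width(genome), ">"
    ),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  records <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
    variants$chrom, variants$pos, variants$ref, variants$alt
  )
  list(variants = variants, vcf_lines = c(header, records))
}

#' Write fixture files to a directory
#'
#' Writes the genome FASTA, the VCF and the truth tables of a fixture spec,
#' producing byte-identical files for a fixed seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written paths plus the in-memory
#'   `genome`, `truth` and `variants` objects.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(spec)
  var <- generate_variants(spec, gen$genome)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(gen$genome, fasta)
  vcf <- file.path(dir, "variants.vcf")
  writeLines(var$vcf_lines, vcf)
  truth_path <- file.path(dir, "repeat_truth.tsv")
  readr::write_tsv(gen$truth, truth_path)
  var_truth_path <- file.path(dir, "variant_truth.tsv")
  readr::write_tsv(var$variants, var_truth_path)
  invisible(list(
    fasta = fasta, vcf = vcf, truth_path = truth_path,
    variant_truth_path = var_truth_path,
    genome = gen$genome, truth = gen$truth, variants = var$variants
  ))
}
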
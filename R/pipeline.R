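#' Assemble a validated run configuration
#'
#' One declarative document drives a full run: inputs, target coordinates and
#' the settings of every stage. A run is fully reproducible from its inputs
#' plus this configuration.
#'
#' @param genome_fasta Character vector of reference FASTA paths.
#' @param vcf Optional VCF path with known variants.
#' @param chrom,start,stop Target region coordinates (1-based inclusive).
#' @param mask_variants Mask variant positions in the target region.
#' @param gap_min Minimum N-run length treated as an assembly gap.
#' @param uod A [uod_settings()] object.
#' @param scan A [scan_params()] object.
#' @param pse_threshold Specificity margin in degrees Celsius (default 10).
#' @param pps A [pps_settings()] object.
#' @param conditions A [reaction_conditions()] object.
#' @param outdir Optional default output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(genome_fasta, vcf = NULL, chrom, start, stop,
                       mask_variants = !is.null(vcf), gap_min = 100,
                       uod = uod_settings(), scan = scan_params(),
                       pse_threshold = 10, pps = pps_settings(),
                       conditions = reaction_conditions(), outdir = NULL) {
  stopifnot(
    is.character(genome_fasta), length(genome_fasta) >= 1,
    is.character(chrom), length(chrom) == 1,
    start >= 1, stop >= start
  )
  structure(
    list(
      genome_fasta = genome_fasta, vcf = vcf,
      chrom = chrom, start = as.integer(start), stop = as.integer(stop),
      mask_variants = mask_variants, gap_min = gap_min,
      uod = uod, scan = scan, pse_threshold = pse_threshold,
      pps = pps, conditions = conditions, outdir = outdir
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()], with nested blocks `uod`,
#' `scan`, `pps` and `conditions` passed to the corresponding constructors.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  run_config(
    genome_fasta = y$genome_fasta,
    vcf = y$vcf,
    chrom = y$chrom, start = y$start, stop = y$stop,
    mask_variants = y$mask_variants %||% !is.null(y$vcf),
    gap_min = y$gap_min %||% 100,
    uod = build(uod_settings, y$uod),
    scan = build(scan_params, y$scan),
    pse_threshold = y$pse_threshold %||% 10,
    pps = build(pps_settings, y$pps),
    conditions = build(reaction_conditions, y$conditions),
    outdir = y$outdir
  )
}

#' Run the full primer-design pipeline
#'
#' Executes the four stages in order: target region selection (genome and
#' variant I/O, masking), unique oligo design (enumeration plus the filter
#' cascade), priming specificity evaluation (off-target scan,
#' thermoalignments, misprime profiles) and primer pair selection (pair
#' filters, tiling graph, minimum path, multiplex groups). Identical inputs
#' and configuration produce identical results.
#'
#' @param config A [run_config()].
#' @param genome Optional pre-loaded genome (skips FASTA reading).
#' @return A `pipeline_run` list: `config`, `region`, `oligos` (all
#'   enumerated, with flags), `candidates` (pass-filter oligos with misprime
#'   profiles), `hits`, `thermoalignments`, `profiles`, `pairs`, `tiling`
#'   (a `tiling_result` or `NULL`), `summary` (stage accounting tibble) and
#'   `timings`.
#' @export
run_pipeline <- function(config, genome = NULL) {
  stopifnot(inherits(config, "run_config"))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    message(sprintf("[%s] done in %.1fs", stage, timings[[stage]]))
    value
  }

  # TRS
  region <- clock("TRS", {
    if (is.null(genome)) genome <- load_genome(config$genome_fasta)
    variants <- if (!is.null(config$vcf)) convert_variants(config$vcf)
    extract_masked_region(
      genome, config$chrom, config$start, config$stop,
      variants = variants, mask_enabled = config$mask_variants,
      gap_min = config$gap_min
    )
  })

  # UOD
  oligos <- clock("UOD", {
    design_oligos(region, genome, config$uod, config$conditions)
  })
  uod_pass <- dplyr::filter(oligos, .data$pass)

  # PSE
  hits <- clock("PSE-scan", scan_offtargets(uod_pass, genome, config$scan))
  tas <- clock(
    "PSE-thermoalign",
    build_thermoalignments(hits, uod_pass, genome, config$conditions)
  )
  profiles <- misprime_profile(tas, uod_pass, config$pse_threshold)
  candidates <- uod_pass |>
    dplyr::inner_join(
      dplyr::select(profiles, -"tm_on_target"),
      by = c(id = "primer_id")
    ) |>
    dplyr::filter(.data$pass_specificity)

  # PPS
  pairs <- clock(
    "PPS",
    enumerate_pairs(candidates, region, config$pps, config$conditions)
  )
  tiling <- NULL
  if (nrow(pairs) > 0) {
    graph <- build_tiling_graph(pairs)
    tiling <- minimum_tiling_path(
      graph,
      target = c(config$start, config$stop)
    ) |>
      split_multiplex_groups()
  }

  summary <- dplyr::bind_rows(
    attr(oligos, "uod_counts"),
    tibble::tibble(
      stage = "UOD", category = "candidates",
      n_flagged = nrow(uod_pass)
    ),
    tibble::tibble(
      stage = "PSE", category = c(
        "local_hits", "thermoalignments", "pass_specificity"
      ),
      n_flagged = c(nrow(hits), nrow(tas), nrow(candidates))
    ),
    tibble::tibble(
      stage = "PPS", category = c("pairs", "minimum_set"),
      n_flagged = c(
        nrow(pairs),
        if (is.null(tiling)) 0L else nrow(tiling$path)
      )
    )
  )

  structure(
    list(
      config = config, region = region, oligos = oligos,
      candidates = candidates, hits = hits, thermoalignments = tas,
      profiles = profiles, pairs = pairs, tiling = tiling,
      summary = summary,
      timings = tibble::tibble(
        stage = names(timings),
        seconds = unlist(timings)
      )
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<pipeline_run> %s:%d-%d\n  %d oligos enumerated, %d candidates, ",
      "%d pairs%s\n"
    ),
    x$config$chrom, x$config$start, x$config$stop,
    nrow(x$oligos), nrow(x$candidates), nrow(x$pairs),
    if (!is.null(x$tiling)) {
      sprintf(
        ", minimum set of %d (%.1f%% coverage)",
        nrow(x$tiling$path), 100 * x$tiling$coverage_fraction
      )
    } else {
      ""
    }
  ))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @return Tibble of the headline counts and tiling coverage.
#' @method glance pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) {
  tibble::tibble(
    n_enumerated = nrow(x$oligos),
    n_candidates = nrow(x$candidates),
    n_pairs = nrow(x$pairs),
    n_minimum_set = if (is.null(x$tiling)) 0L else nrow(x$tiling$path),
    coverage_fraction = if (is.null(x$tiling)) {
      0
    } else {
      x$tiling$coverage_fraction
    }
  )
}

# BED conversion: 1-based inclusive -> 0-based half-open.
primer_bed <- function(candidates) {
  start1 <- pmin(candidates$five_prime_pos, candidates$three_prime_pos)
  stop1 <- pmax(candidates$five_prime_pos, candidates$three_prime_pos)
  tibble::tibble(
    chrom = candidates$chrom,
    start = start1 - 1L,
    end = stop1,
    name = candidates$id,
    score = 0L,
    strand = ifelse(candidates$strand == "F", "+", "-")
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$name)
}

#' Write the run's primary output files
#'
#' Produces the five primary outputs in `outdir`: (i) `summary.txt` (settings
#' and per-filter accounting), (ii) `primer_order.tsv` (id, sequence),
#' (iii) `pairs.tsv` (pair/amplicon feature table), (iv) `minimum_set.tsv`
#' (tiling path with multiplex groups), (v) `primers.bed` and `amplicons.bed`
#' (0-based half-open, strand column), plus a MultiPLX-format input export
#' `multiplx_input.txt`. Files are deterministic for fixed inputs and
#' configuration (no timestamps); empty results still produce headers.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @param outdir Output directory (created if needed; must be writable).
#' @return Invisibly, the vector of written paths.
#' @export
write_outputs <- function(run, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_outputs: cannot create '", outdir, "'", call. = FALSE)
  }
  if (file.access(outdir, 2) != 0) {
    stop("write_outputs: directory '", outdir, "' is not writable",
      call. = FALSE
    )
  }
  paths <- character(0)
  p <- function(name) {
    paths <<- c(paths, file.path(outdir, name))
    file.path(outdir, name)
  }

  cfg <- run$config
  summary_lines <- c(
    "# thermotile run summary",
    sprintf("target\t%s:%d-%d", cfg$chrom, cfg$start, cfg$stop),
    sprintf(
      "region\tGC %.2f%%, %d SNPs, %d indels, %d gap runs",
      run$region$summary$gc_pct, run$region$summary$n_snps,
      run$region$summary$n_indels, run$region$summary$n_gap_runs
    ),
    sprintf(
      "settings\tlengths %d-%d, GC %g-%g%%, Tm %g-%g C, margin +%g C",
      cfg$uod$length_min, cfg$uod$length_max, cfg$uod$gc_min, cfg$uod$gc_max,
      cfg$uod$tm_min, cfg$uod$tm_max, cfg$pse_threshold
    ),
    "",
    "stage\tcategory\tn"
  )
  summary_lines <- c(
    summary_lines,
    sprintf(
      "%s\t%s\t%d",
      run$summary$stage, run$summary$category, run$summary$n_flagged
    )
  )
  writeLines(summary_lines, p("summary.txt"))

  in_set <- if (!is.null(run$tiling)) {
    unique(c(run$tiling$path$fwd_id, run$tiling$path$rev_id))
  } else {
    run$candidates$id
  }
  order_tbl <- run$candidates |>
    dplyr::filter(.data$id %in% in_set) |>
    dplyr::transmute(id = .data$id, sequence = .data$seq) |>
    dplyr::arrange(.data$id)
  readr::write_tsv(order_tbl, p("primer_order.tsv"))

  readr::write_tsv(run$pairs, p("pairs.tsv"))

  min_set <- if (!is.null(run$tiling)) {
    run$tiling$path
  } else {
    tibble::tibble(
      component = integer(), position = integer(), pair_id = character(),
      fwd_id = character(), rev_id = character(),
      amplicon_start = integer(), amplicon_stop = integer(),
      group = character()
    )
  }
  readr::write_tsv(min_set, p("minimum_set.tsv"))

  readr::write_tsv(primer_bed(run$candidates), p("primers.bed"),
    col_names = FALSE
  )
  amp_bed <- min_set |>
    dplyr::transmute(
      chrom = cfg$chrom,
      start = .data$amplicon_start - 1L,
      end = .data$amplicon_stop,
      name = .data$pair_id,
      score = 0L,
      strand = "+"
    )
  readr::write_tsv(amp_bed, p("amplicons.bed"), col_names = FALSE)

  seqs <- stats::setNames(run$candidates$seq, run$candidates$id)
  mplx <- min_set |>
    dplyr::transmute(
      name = .data$pair_id,
      fwd_seq = unname(seqs[.data$fwd_id]),
      rev_seq = unname(seqs[.data$rev_id]),
      product_size = .data$amplicon_stop - .data$amplicon_start + 1L
    )
  readr::write_tsv(mplx, p("multiplx_input.txt"), col_names = FALSE)

  invisible(paths)
}
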
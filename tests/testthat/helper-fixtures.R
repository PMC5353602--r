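# Small in-code fixtures shared across test files.

random_dna <- function(n, gc = 0.5) {
  paste(
    sample(c("A", "C", "G", "T"), n,
      replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ),
    collapse = ""
  )
}

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

write_temp_fasta <- function(genome, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(genome, path)
  path
}

write_temp_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(contigs) {
  c(
    "##fileformat=VCFv4.1",
    paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
}

# a target_region built directly from a sequence string (no genome file)
region_from_seq <- function(seq, chrom = "chrZ", start = 1) {
  genome <- make_genome(stats::setNames(seq, chrom))
  extract_masked_region(genome, chrom, start, start + nchar(seq) - 1)
}

# random amplicon-pair table for tiling tests
random_pair_set <- function(n, span = 400, len_min = 60, len_max = 180) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(seq(len_min, len_max), n, replace = TRUE)
  tibble::tibble(
    pair_id = paste0("P", seq_len(n)),
    fwd_id = paste0("F", seq_len(n)),
    rev_id = paste0("R", seq_len(n)),
    amplicon_start = as.integer(start),
    amplicon_stop = as.integer(start + len - 1),
    amplicon_length = as.integer(len)
  )
}
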
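# Secondary-structure evaluation: a simplified exhaustive fold. Hairpins are
# enumerated over all perfect Watson-Crick stems of >= 3 bp closing loops of
# 3-30 nt, scored with the same NN table as duplexes plus an entropic loop
# penalty. Dimers are the best-scoring ungapped antiparallel offset of the two
# strands, scored with the duplex machinery (mismatch columns included,
# terminal mismatch columns trimmed).

# Hairpin loop free-energy increments at 37 C (kcal/mol), interpolated between
# published anchor sizes; treated as purely entropic.
hairpin_loop_dg37 <- function(size) {
  anchors_n <- c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30)
  anchors_g <- c(
    3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.6, 5.0, 5.1, 5.3,
    5.5, 5.7, 6.1, 6.3
  )
  stats::approx(anchors_n, anchors_g, xout = size, rule = 2)$y
}

# All scorable ungapped antiparallel pairings of a and b: for each offset the
# outermost-paired core is extracted and scored with the duplex machinery.
# Enumerating offsets of `a` against the reverse complement of `b` covers
# every antiparallel pairing of the two strands, and the scoring is strand
# symmetric, so the result does not depend on the argument order. Returns
# vectors dh (kcal/mol), ds (cal/(K.mol)) and n_phosphates per scorable
# offset (zero-length when no pairing can be scored).
dimer_cores <- function(seq_a, seq_b, table) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  rc_b <- strsplit(reverse_complement(toupper(seq_b)), "", fixed = TRUE)[[1]]
  na_len <- length(a)
  nb_len <- length(rc_b)

  a_code <- match(a, BASES) - 1L
  f_code_full <- match(rc_b, BASES) - 1L
  empty <- list(dh = numeric(0), ds = numeric(0), n_phosphates = integer(0))
  ds_off <- seq(-(na_len - 2), nb_len - 2)
  nd <- length(ds_off)
  if (nd < 1) {
    return(empty)
  }

  # column i of row d pairs a[i] with rc_b[i + d]; everything below is
  # vectorized over all offsets at once
  col_idx <- outer(ds_off, seq_len(na_len), "+")
  valid <- col_idx >= 1 & col_idx <= nb_len
  fmat <- matrix(NA_integer_, nd, na_len)
  fmat[valid] <- f_code_full[col_idx[valid]]
  amat <- matrix(a_code, nd, na_len, byrow = TRUE)
  eq <- !is.na(fmat) & amat == fmat
  n_match <- rowSums(eq)

  # outermost paired core per offset
  lo <- max.col(eq, ties.method = "first")
  hi <- na_len + 1L - max.col(eq[, na_len:1, drop = FALSE],
    ties.method = "first"
  )
  usable <- which(n_match >= 1 & hi - lo >= 1)
  if (length(usable) == 0) {
    return(empty)
  }

  dh256 <- attr(table, "dh256")
  ds256 <- attr(table, "ds256")
  step_idx <- (amat[, -na_len, drop = FALSE] * 4L +
    amat[, -1, drop = FALSE]) * 16L +
    fmat[, -na_len, drop = FALSE] * 4L + fmat[, -1, drop = FALSE] + 1L
  in_core <- outer(lo, seq_len(na_len - 1), "<=") &
    outer(hi, seq_len(na_len - 1) + 1L, ">=")
  dh_step <- matrix(dh256[step_idx], nd, na_len - 1)
  ds_step <- matrix(ds256[step_idx], nd, na_len - 1)
  dh_step[is.na(dh_step)] <- 0 # untabulated double-mismatch steps
  ds_step[is.na(ds_step)] <- 0
  dh_sum <- rowSums(dh_step * in_core)
  ds_sum <- rowSums(ds_step * in_core)

  gc_init <- nn_lookup("init_GC", table)
  at_init <- nn_lookup("init_AT", table)
  term_lo <- a_code[lo]
  term_hi <- a_code[hi]
  is_gc <- function(code) code == 1L | code == 2L
  dh_sum <- dh_sum +
    ifelse(is_gc(term_lo), gc_init$dh, at_init$dh) +
    ifelse(is_gc(term_hi), gc_init$dh, at_init$dh)
  ds_sum <- ds_sum +
    ifelse(is_gc(term_lo), gc_init$ds, at_init$ds) +
    ifelse(is_gc(term_hi), gc_init$ds, at_init$ds)

  m <- hi[usable] - lo[usable] + 1L
  dh <- dh_sum[usable]
  ds <- ds_sum[usable]
  # fully paired self-complementary cores carry the symmetry term
  perfect <- which(n_match[usable] == m)
  for (k in perfect) {
    d <- usable[k]
    core <- paste(a[lo[d]:hi[d]], collapse = "")
    if (core == reverse_complement(core)) {
      sym <- nn_lookup("sym", table)
      dh[k] <- dh[k] + sym$dh
      ds[k] <- ds[k] + sym$ds
    }
  }
  keep <- dh < 0
  list(
    dh = dh[keep], ds = ds[keep],
    n_phosphates = 2L * (m[keep] - 1L)
  )
}

#' Melting temperature of the most stable self-structure
#'
#' Predicts the melting temperature of the most stable hairpin or homodimer an
#' oligonucleotide can form, using an exhaustive simplified fold (perfect
#' Watson-Crick stems of at least 3 bp with loops of 3-30 nt for hairpins; the
#' best ungapped antiparallel self-pairing for homodimers). When no stable
#' structure exists, `-Inf` is returned as a sentinel far below any filter
#' threshold.
#'
#' @param seq Oligonucleotide sequence (A/C/G/T).
#' @param kind `"hairpin"` or `"homodimer"`.
#' @param conditions A [reaction_conditions()] object. Homodimer Tm uses
#'   symmetry factor 1 (identical-strand duplex); hairpin Tm is unimolecular.
#' @param table An [nn_table()].
#' @return Predicted structure melting temperature in degrees Celsius
#'   (`-Inf` when no structure can form).
#' @export
#' @examples
#' self_structure_tm("ATATATATATATATATATAT", "hairpin")
#' self_structure_tm("GGGCCCATATATGGGCCCAT", "homodimer")
self_structure_tm <- function(seq, kind = c("hairpin", "homodimer"),
                              conditions = reaction_conditions(),
                              table = nn_table()) {
  kind <- match.arg(kind)
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% BASES)) {
    stop("self_structure_tm: alphabet must be A/C/G/T", call. = FALSE)
  }
  n <- length(chars)

  if (kind == "homodimer") {
    cond1 <- conditions
    cond1$symmetry_x <- 1
    cores <- dimer_cores(seq, seq, table)
    if (length(cores$dh) == 0) {
      return(-Inf)
    }
    na_eq_M <- sodium_equivalent(cond1) / 1000
    ds_adj <- cores$ds + 0.368 * (cores$n_phosphates / 2) * log(na_eq_M)
    ct <- cond1$total_oligo_uM * 1e-6
    denom <- ds_adj + cond1$gas_constant_R * log(ct / cond1$symmetry_x)
    tms <- ifelse(denom < 0, cores$dh * 1000 / denom - 273.15, -Inf)
    return(max(tms, -Inf))
  }

  # hairpin: stem seq[i..i+k-1] pairs seq[j-k+1..j] antiparallel
  comp <- unname(COMPLEMENT[chars])
  na_eq_M <- sodium_equivalent(conditions) / 1000
  best_tm <- -Inf
  for (k in 3:max(3, floor((n - 3) / 2))) {
    if (2 * k + 3 > n) break
    for (i in 1:(n - 2 * k - 3 + 1)) {
      for (j in (i + 2 * k + 3 - 1):n) {
        loop <- j - i + 1 - 2 * k
        if (loop < 3 || loop > 30) next
        top <- chars[i:(i + k - 1)]
        bot <- comp[j:(j - k + 1)] # frame representation of the 3' arm
        if (!all(top == bot)) next
        prof <- duplex_enthalpy_entropy(
          paste(top, collapse = ""), paste(top, collapse = ""), table
        )
        ds_loop <- -hairpin_loop_dg37(loop) * 1000 / 310.15
        ds_adj <- prof$ds_total + ds_loop +
          0.368 * (k - 1) * log(na_eq_M)
        if (ds_adj >= 0 || prof$dh_total >= 0) next
        tm <- prof$dh_total * 1000 / ds_adj - 273.15
        best_tm <- max(best_tm, tm)
      }
    }
  }
  best_tm
}

#' Free energy of the most stable cross-dimer of two oligonucleotides
#'
#' Evaluates every ungapped antiparallel offset of the two sequences, scores
#' the paired core with the nearest-neighbor machinery and returns the most
#' negative free energy at 37 C (salt-adjusted entropy). Symmetric in its two
#' arguments. When no stable pairing exists, 0 is returned (no duplex forms).
#'
#' @param seq_a,seq_b Oligonucleotide sequences (A/C/G/T).
#' @param conditions A [reaction_conditions()] object.
#' @param table An [nn_table()].
#' @return Free energy in cal/mol (negative = stable; 0 = no stable duplex).
#' @export
#' @examples
#' heterodimer_dg("ACGTACGTACGTACGTACGT", reverse_complement("ACGTACGTACGTACGTACGT"))
heterodimer_dg <- function(seq_a, seq_b, conditions = reaction_conditions(),
                           table = nn_table()) {
  a <- toupper(seq_a)
  b <- toupper(seq_b)
  # scoring is strand symmetric up to floating-point summation order;
  # canonicalize the argument order so the symmetry is bit-exact
  if (b < a) {
    tmp <- a
    a <- b
    b <- tmp
  }
  na_eq_M <- sodium_equivalent(conditions) / 1000
  cores <- dimer_cores(a, b, table)
  if (length(cores$dh) == 0) {
    return(0)
  }
  ds_adj <- cores$ds + 0.368 * (cores$n_phosphates / 2) * log(na_eq_M)
  dg <- cores$dh * 1000 - 310.15 * ds_adj
  best <- min(dg)
  if (best > 0) {
    return(0)
  }
  best
}
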
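#' Reaction conditions for melting-temperature calculations
#'
#' Bundles the PCR reaction chemistry used by the two-state nearest-neighbor
#' melting-temperature model: monovalent and divalent cation concentrations,
#' dNTP concentration (which chelates divalent ions), the total oligonucleotide
#' strand concentration and the symmetry factor.
#'
#' @param monovalent_mM Monovalent cation concentration (mM). Default 50.
#' @param divalent_mg_mM Free Mg2+ concentration (mM). Default 1.5.
#' @param dntp_mM Total dNTP concentration (mM). Default 0.8.
#' @param total_oligo_uM Total strand concentration C_T (micromolar).
#'   Default 0.25.
#' @param symmetry_x Symmetry factor x in the Tm denominator: 4 for
#'   non-self-complementary duplexes, 1 for self-complementary.
#' @return A `reaction_conditions` list.
#' @export
#' @examples
#' reaction_conditions()
reaction_conditions <- function(monovalent_mM = 50, divalent_mg_mM = 1.5,
                                dntp_mM = 0.8, total_oligo_uM = 0.25,
                                symmetry_x = 4) {
  if (any(c(monovalent_mM, divalent_mg_mM, dntp_mM, total_oligo_uM) < 0)) {
    stop("reaction_conditions: all concentrations must be >= 0", call. = FALSE)
  }
  if (!symmetry_x %in% c(1, 4)) {
    stop("reaction_conditions: symmetry_x must be 1 or 4", call. = FALSE)
  }
  structure(
    list(
      monovalent_mM = monovalent_mM,
      divalent_mg_mM = divalent_mg_mM,
      dntp_mM = dntp_mM,
      total_oligo_uM = total_oligo_uM,
      symmetry_x = symmetry_x,
      gas_constant_R = 1.9872
    ),
    class = "reaction_conditions"
  )
}

#' Sodium-equivalent concentration of a reaction
#'
#' Converts divalent Mg2+ (net of dNTP chelation) into a monovalent-equivalent
#' concentration: `na_eq = monovalent + 120 * sqrt(mg - dntp)` (all in mM) when
#' Mg2+ exceeds the dNTP concentration; when dNTPs are at or above the Mg2+
#' concentration the divalent contribution is zero.
#'
#' @param conditions A [reaction_conditions()] object.
#' @return Sodium-equivalent concentration in mM.
#' @export
#' @examples
#' sodium_equivalent(reaction_conditions(monovalent_mM = 50,
#'   divalent_mg_mM = 1.5, dntp_mM = 0.8))
sodium_equivalent <- function(conditions) {
  stopifnot(inherits(conditions, "reaction_conditions"))
  div <- conditions$divalent_mg_mM - conditions$dntp_mM
  conditions$monovalent_mM + if (div > 0) 120 * sqrt(div) else 0
}

#' Sum nearest-neighbor enthalpy and entropy for an aligned duplex
#'
#' Computes total duplex enthalpy and entropy (pre salt adjustment) under the
#' two-state nearest-neighbor model, summing doublet-step parameters plus the
#' two initiation terms. The template is given in the primer frame: the same
#' sense as the primer, so a column is a Watson-Crick pair exactly when the two
#' characters are equal. Steps with a single mismatched column use the
#' published mismatch parameter sets; steps with two mismatched columns use the
#' tabulated tandem G.T parameters when available, otherwise a neutral
#' (0, 0) pseudo-step that is flagged on the profile (such duplexes are always
#' far below priming temperatures).
#'
#' @param primer_seq Primer sequence, 5' to 3' (A/C/G/T).
#' @param template_in_primer_frame Genomic window rewritten in the primer
#'   frame, same length as the primer.
#' @param table An [nn_table()].
#' @param on_unparameterized `"pseudo"` (default) scores untabulated
#'   double-mismatch steps as (0, 0) and records them; `"error"` aborts,
#'   naming the step and position.
#' @return A `duplex_profile` list: `dh_total` (kcal/mol), `ds_total`
#'   (cal/(K.mol)), `length`, `n_phosphates` (= 2 * (length - 1)),
#'   `n_mismatches`, `mismatch_positions`, `unparameterized_steps`.
#' @export
#' @examples
#' duplex_enthalpy_entropy("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
duplex_enthalpy_entropy <- function(primer_seq, template_in_primer_frame,
                                    table = nn_table(),
                                    on_unparameterized = c("pseudo", "error")) {
  on_unparameterized <- match.arg(on_unparameterized)
  p <- strsplit(toupper(primer_seq), "", fixed = TRUE)[[1]]
  t_frame <- strsplit(toupper(template_in_primer_frame), "", fixed = TRUE)[[1]]
  n <- length(p)
  if (n < 2 || length(t_frame) != n) {
    stop("duplex_enthalpy_entropy: sequences must be the same length >= 2",
      call. = FALSE
    )
  }
  if (!all(p %in% BASES) || !all(t_frame %in% BASES)) {
    stop("duplex_enthalpy_entropy: alphabet must be A/C/G/T", call. = FALSE)
  }

  bottom <- unname(COMPLEMENT[t_frame])
  keys <- paste0(p[-n], p[-1], "/", bottom[-n], bottom[-1])
  vals <- nn_lookup(keys, table)
  unparam <- which(is.na(vals$dh))
  if (length(unparam) > 0 && on_unparameterized == "error") {
    stop(sprintf(
      "unparameterized step '%s' at position %d",
      keys[unparam[1]], unparam[1]
    ), call. = FALSE)
  }
  vals$dh[unparam] <- 0
  vals$ds[unparam] <- 0

  init_key <- function(primer_base) {
    if (primer_base %in% c("G", "C")) "init_GC" else "init_AT"
  }
  init <- nn_lookup(c(init_key(p[1]), init_key(p[n])), table)

  dh <- sum(vals$dh) + sum(init$dh)
  ds <- sum(vals$ds) + sum(init$ds)

  mismatches <- which(p != t_frame)
  perfect <- length(mismatches) == 0
  if (perfect && primer_seq == reverse_complement(primer_seq)) {
    sym <- nn_lookup("sym", table)
    dh <- dh + sym$dh
    ds <- ds + sym$ds
  }

  structure(
    list(
      dh_total = dh,
      ds_total = ds,
      length = n,
      n_phosphates = 2 * (n - 1),
      n_mismatches = length(mismatches),
      mismatch_positions = mismatches,
      unparameterized_steps = unparam,
      primer_seq = primer_seq,
      template_in_primer_frame = template_in_primer_frame
    ),
    class = "duplex_profile"
  )
}

#' Two-state melting temperature of a duplex profile
#'
#' Salt-adjusts the duplex entropy,
#' `dS[Na+] = dS[1 M] + 0.368 * (n_phosphates / 2) * ln([Na+])` with the
#' sodium-equivalent concentration in mol/L, then evaluates
#' `Tm(K) = dH * 1000 / (dS_adjusted + R * ln(C_T / x))` and returns degrees
#' Celsius.
#'
#' @param profile A `duplex_profile` from [duplex_enthalpy_entropy()], or any
#'   list with `dh_total`, `ds_total` and `n_phosphates`.
#' @param conditions A [reaction_conditions()] object.
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' prof <- duplex_enthalpy_entropy(
#'   "ACGTACGTACGTACGTACGT",
#'   "ACGTACGTACGTACGTACGT"
#' )
#' melting_temperature(prof, reaction_conditions())
melting_temperature <- function(profile, conditions = reaction_conditions()) {
  na_eq_M <- sodium_equivalent(conditions) / 1000
  if (na_eq_M <= 0) {
    stop("melting_temperature: sodium equivalent must be > 0", call. = FALSE)
  }
  ds_adj <- profile$ds_total +
    0.368 * (profile$n_phosphates / 2) * log(na_eq_M)
  ct <- conditions$total_oligo_uM * 1e-6
  denom <- ds_adj + conditions$gas_constant_R * log(ct / conditions$symmetry_x)
  if (denom >= 0) {
    stop("melting_temperature: non-physical duplex (denominator >= 0)",
      call. = FALSE
    )
  }
  profile$dh_total * 1000 / denom - 273.15
}

#' Melting temperature of a perfectly complementary duplex
#'
#' Convenience wrapper: Tm of `seq` bound to its exact complement.
#'
#' @param seq Character vector of A/C/G/T sequences.
#' @param conditions A [reaction_conditions()] object.
#' @param table An [nn_table()].
#' @return Numeric vector of melting temperatures (degrees Celsius).
#' @export
#' @examples
#' tm_duplex("ACGTACGTACGTACGTACGT")
tm_duplex <- function(seq, conditions = reaction_conditions(),
                      table = nn_table()) {
  vapply(seq, function(s) {
    melting_temperature(duplex_enthalpy_entropy(s, s, table), conditions)
  }, numeric(1), USE.NAMES = FALSE)
}

# Vectorized on-target Tm for every window of length L in a region sequence,
# via cumulative sums of the Watson-Crick step parameters. Windows containing
# non-ACGT characters get NA. Returns Tm for windows starting at 1..(n - L + 1)
# (the duplex Tm is strand-symmetric, so the same values serve both strands).
window_tm <- function(chars, L, conditions = reaction_conditions(),
                      table = nn_table()) {
  n <- length(chars)
  if (n < L) {
    return(numeric(0))
  }
  ok <- chars %in% BASES
  safe <- ifelse(ok, chars, "A")
  bottom <- unname(COMPLEMENT[safe])
  keys <- paste0(
    safe[-n], safe[-1], "/",
    bottom[-n], bottom[-1]
  )
  vals <- nn_lookup(keys, table)
  cum_dh <- c(0, cumsum(vals$dh))
  cum_ds <- c(0, cumsum(vals$ds))
  cum_bad <- c(0, cumsum(!ok))

  starts <- seq_len(n - L + 1)
  ends <- starts + L - 1
  dh_step <- cum_dh[ends] - cum_dh[starts]
  ds_step <- cum_ds[ends] - cum_ds[starts]
  has_bad <- (cum_bad[ends + 1] - cum_bad[starts]) > 0

  init <- function(b) ifelse(b %in% c("G", "C"), 1, 0) # 1 -> GC init
  gc_init <- nn_lookup("init_GC", table)
  at_init <- nn_lookup("init_AT", table)
  gc1 <- init(chars[starts])
  gc2 <- init(chars[ends])
  dh <- dh_step + gc1 * gc_init$dh + (1 - gc1) * at_init$dh +
    gc2 * gc_init$dh + (1 - gc2) * at_init$dh
  ds <- ds_step + gc1 * gc_init$ds + (1 - gc1) * at_init$ds +
    gc2 * gc_init$ds + (1 - gc2) * at_init$ds

  na_eq_M <- sodium_equivalent(conditions) / 1000
  ds_adj <- ds + 0.368 * (L - 1) * log(na_eq_M)
  ct <- conditions$total_oligo_uM * 1e-6
  denom <- ds_adj + conditions$gas_constant_R * log(ct / conditions$symmetry_x)
  tm <- dh * 1000 / denom - 273.15
  tm[has_bad | denom >= 0] <- NA_real_
  tm
}
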
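#' Nearest-neighbor thermodynamic parameter table
#'
#' Loads the packaged nearest-neighbor (NN) parameter set used for all duplex
#' enthalpy/entropy summation: the unified Watson-Crick doublet parameters with
#' their initiation and symmetry terms, plus the single-internal-mismatch sets
#' for G.T, G.A, A.C, C.T and identical-base (A.A, C.C, G.G, T.T) pairings and
#' the tandem G.T doublets. Values are in kcal/mol (enthalpy) and cal/(K.mol)
#' (entropy); each entry carries a source tag.
#'
#' A doublet step is written `"XY/WZ"`: top strand 5'-XY-3' (the primer), bottom
#' strand 3'-WZ-5' (the template), so column one pairs X with W. Lookup is
#' symmetric under reading a step from the opposite strand
#' (`"XY/WZ"` is equivalent to `"ZW/YX"`).
#'
#' @param path Optional path to an alternative tab-separated parameter file
#'   with columns `step`, `dh_kcal_mol`, `ds_cal_k_mol`, `source`.
#' @return A tibble with columns `step`, `dh_kcal_mol`, `ds_cal_k_mol`,
#'   `source`, carrying lookup maps as attributes (used internally).
#' @export
#' @examples
#' nn <- nn_table()
#' dplyr::count(nn, source)
nn_table <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("nn_table_default", envir = .thermotile_cache)
    if (!is.null(cached)) {
      return(cached)
    }
    path <- system.file("extdata", "nn_parameters_v1.tsv", package = "thermotile")
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    step = readr::col_character(),
    dh_kcal_mol = readr::col_double(),
    ds_cal_k_mol = readr::col_double(),
    source = readr::col_character()
  ))
  stopifnot(!anyDuplicated(tbl$step))
  dh <- stats::setNames(tbl$dh_kcal_mol, tbl$step)
  ds <- stats::setNames(tbl$ds_cal_k_mol, tbl$step)
  attr(tbl, "dh_map") <- dh
  attr(tbl, "ds_map") <- ds
  # dense doublet lookup: index = ((p1*4 + p2)*4 + f1)*4 + f2 + 1 over base
  # codes A=0, C=1, G=2, T=3 for the primer doublet (p1, p2) and the
  # template doublet in the primer frame (f1, f2); NA = untabulated step
  codes <- expand.grid(f2 = 0:3, f1 = 0:3, p2 = 0:3, p1 = 0:3)
  comp_code <- c(3L, 2L, 1L, 0L)
  keys <- paste0(
    BASES[codes$p1 + 1], BASES[codes$p2 + 1], "/",
    BASES[comp_code[codes$f1 + 1] + 1], BASES[comp_code[codes$f2 + 1] + 1]
  )
  dh256 <- unname(dh[keys])
  ds256 <- unname(ds[keys])
  miss <- is.na(dh256)
  flipped <- flip_step(keys[miss])
  dh256[miss] <- unname(dh[flipped])
  ds256[miss] <- unname(ds[flipped])
  ord <- order(
    codes$p1 * 64 + codes$p2 * 16 + codes$f1 * 4 + codes$f2
  )
  attr(tbl, "dh256") <- dh256[ord]
  attr(tbl, "ds256") <- ds256[ord]
  class(tbl) <- c("nn_table", class(tbl))
  if (identical(path, system.file("extdata", "nn_parameters_v1.tsv", package = "thermotile"))) {
    assign("nn_table_default", tbl, envir = .thermotile_cache)
  }
  tbl
}

.thermotile_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", n = "n")

#' Reverse complement of a DNA string
#'
#' @param x Character vector of A/C/G/T/N sequences (5' to 3').
#' @return Character vector of reverse complements (5' to 3').
#' @export
#' @examples
#' reverse_complement("ACGTT")
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Flip a step key to its opposite-strand reading: "XY/WZ" -> "ZW/YX".
flip_step <- function(keys) {
  top <- substr(keys, 1, 2)
  bot <- substr(keys, 4, 5)
  paste0(
    substr(bot, 2, 2), substr(bot, 1, 1), "/",
    substr(top, 2, 2), substr(top, 1, 1)
  )
}

# Vectorized doublet lookup. Returns a list of dh, ds (NA when the step has no
# tabulated entry in either strand orientation).
nn_lookup <- function(keys, table) {
  dh_map <- attr(table, "dh_map")
  ds_map <- attr(table, "ds_map")
  dh <- unname(dh_map[keys])
  ds <- unname(ds_map[keys])
  miss <- is.na(dh)
  if (any(miss)) {
    flipped <- flip_step(keys[miss])
    dh[miss] <- unname(dh_map[flipped])
    ds[miss] <- unname(ds_map[flipped])
  }
  list(dh = dh, ds = ds)
}
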
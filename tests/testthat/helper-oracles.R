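# Independent oracles, coded separately from the package internals.

# Independent nearest-neighbor summation: reads the parameter file itself,
# walks the duplex one doublet at a time with explicit complementation and
# strand-flip handling, and applies the two-state Tm formula directly.
oracle_nn_env <- local({
  env <- NULL
  function() {
    if (!is.null(env)) {
      return(env)
    }
    tbl <- utils::read.delim(
      system.file("extdata", "nn_parameters_v1.tsv", package = "thermotile"),
      stringsAsFactors = FALSE
    )
    e <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(tbl))) {
      assign(tbl$step[i], c(tbl$dh_kcal_mol[i], tbl$ds_cal_k_mol[i]),
        envir = e
      )
    }
    env <<- e
    env
  }
})

oracle_comp <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

oracle_duplex_sum <- function(primer, frame) {
  e <- oracle_nn_env()
  p <- strsplit(primer, "")[[1]]
  f <- strsplit(frame, "")[[1]]
  stopifnot(length(p) == length(f), length(p) >= 2)
  dh <- 0
  ds <- 0
  n <- length(p)
  for (i in 1:(n - 1)) {
    top <- paste0(p[i], p[i + 1])
    bot <- paste0(oracle_comp(f[i]), oracle_comp(f[i + 1]))
    key <- paste0(top, "/", bot)
    flip <- paste0(
      substr(bot, 2, 2), substr(bot, 1, 1), "/",
      substr(top, 2, 2), substr(top, 1, 1)
    )
    v <- if (exists(key, envir = e)) {
      get(key, envir = e)
    } else if (exists(flip, envir = e)) {
      get(flip, envir = e)
    } else {
      c(0, 0) # untabulated double-mismatch step
    }
    dh <- dh + v[1]
    ds <- ds + v[2]
  }
  for (term in c(p[1], p[n])) {
    v <- if (term %in% c("G", "C")) {
      get("init_GC", envir = e)
    } else {
      get("init_AT", envir = e)
    }
    dh <- dh + v[1]
    ds <- ds + v[2]
  }
  if (identical(p, f)) {
    rc <- paste(rev(oracle_comp(p)), collapse = "")
    if (rc == primer) {
      v <- get("sym", envir = e)
      dh <- dh + v[1]
      ds <- ds + v[2]
    }
  }
  c(dh = dh, ds = ds)
}

oracle_tm <- function(primer, frame, mono = 50, mg = 1.5, dntp = 0.8,
                      ct_uM = 0.25, x = 4) {
  hs <- oracle_duplex_sum(primer, frame)
  na_mM <- mono + if (mg > dntp) 120 * sqrt(mg - dntp) else 0
  L <- nchar(primer)
  ds_adj <- hs["ds"] + 0.368 * (L - 1) * log(na_mM / 1000)
  unname(hs["dh"] * 1000 /
    (ds_adj + 1.9872 * log(ct_uM * 1e-6 / x)) - 273.15)
}

# Window-selection oracle for thermoalignment construction: enumerate every
# primer-length window overlapping the hit's subject interval and keep the
# one whose pairing puts the primer's 3'-most aligned base at its
# hit-assigned template coordinate (subject_stop on +, subject_start on -).
oracle_select_window <- function(hit, primer_len, subj_len) {
  starts <- seq(
    max(1, hit$subject_start - primer_len + 1),
    min(hit$subject_stop, subj_len - primer_len + 1)
  )
  sel <- vapply(starts, function(ws) {
    we <- ws + primer_len - 1
    if (hit$subject_strand == "+") {
      # primer position i pairs coordinate ws + i - 1
      anchor <- ws + hit$primer_aln_stop - 1
      anchor == hit$subject_stop
    } else {
      # primer position i pairs coordinate we - i + 1
      anchor <- we - hit$primer_aln_stop + 1
      anchor == hit$subject_start
    }
  }, logical(1))
  starts[sel]
}

# Brute-force enumeration of every directed path in a tiling graph component.
# Returns a list of integer node-index vectors.
oracle_all_paths <- function(nodes, edges, comp_nodes) {
  adj <- lapply(seq_len(nrow(nodes)), function(v) {
    edges$to[edges$from == v]
  })
  wmap <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edges))) {
    assign(paste(edges$from[i], edges$to[i]), edges$W[i], envir = wmap)
  }
  paths <- list()
  dfs <- function(v, path) {
    paths[[length(paths) + 1]] <<- path
    for (u in adj[[v]]) dfs(u, c(path, u))
  }
  for (s in comp_nodes) dfs(s, s)
  paths
}

oracle_path_w <- function(path, edges) {
  if (length(path) < 2) {
    return(0)
  }
  sum(vapply(seq_len(length(path) - 1), function(i) {
    edges$W[edges$from == path[i] & edges$to == path[i + 1]]
  }, numeric(1)))
}
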
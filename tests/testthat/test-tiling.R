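test_that("edge construction follows the overlap and ordering rules", {
  pairs <- tibble::tibble(
    pair_id = c("A", "B", "C", "Bp"),
    fwd_id = paste0("f", 1:4), rev_id = paste0("r", 1:4),
    amplicon_start = c(1L, 400L, 700L, 350L),
    amplicon_stop = c(600L, 1000L, 1200L, 1000L),
    amplicon_length = c(600L, 601L, 501L, 651L)
  )
  g <- build_tiling_graph(pairs)
  key <- function(i) g$nodes$pair_id[i]
  edges <- tibble::tibble(
    from = key(g$edges$from), to = key(g$edges$to),
    overlap = g$edges$overlap, E = g$edges$E
  )
  # A=[1,600], B=[400,1000]: overlap 201, E = 600 + 601 - 201 = union length
  ab <- edges[edges$from == "A" & edges$to == "B", ]
  expect_equal(ab$overlap, 201L)
  expect_equal(ab$E, 1000L)
  # A and C do not overlap: no edge
  expect_false(any(edges$from == "A" & edges$to == "C"))
  # B=[400,1000] vs Bp=[350,1000]: ordering violated in both directions
  expect_false(any(edges$from == "B" & edges$to == "Bp"))
  expect_false(any(edges$from == "Bp" & edges$to == "B"))
  # weights are the rescaled scores, non-negative, zero at the maximum
  expect_true(all(g$edges$W >= 0))
  expect_equal(g$m_g, max(g$edges$E))
  expect_true(any(g$edges$W == 0))
})

test_that("a unique chain is returned as the path", {
  pairs <- tibble::tibble(
    pair_id = c("A", "B", "C"),
    fwd_id = paste0("f", 1:3), rev_id = paste0("r", 1:3),
    amplicon_start = c(1L, 500L, 1100L),
    amplicon_stop = c(600L, 1200L, 1700L),
    amplicon_length = c(600L, 701L, 601L)
  )
  res <- minimum_tiling_path(build_tiling_graph(pairs))
  expect_equal(res$path$pair_id, c("A", "B", "C"))
  expect_equal(res$coverage_fraction, 1)
  # an isolated node is its own path
  single <- minimum_tiling_path(build_tiling_graph(pairs[1, ]))
  expect_equal(single$path$pair_id, "A")
})

test_that("ties on total weight break toward fewer nodes", {
  # diamond: two 3-node routes and one 2-node route arranged so that total
  # weights tie; the shorter path must win
  pairs <- tibble::tibble(
    pair_id = c("S", "M1", "M2", "T"),
    fwd_id = paste0("f", 1:4), rev_id = paste0("r", 1:4),
    amplicon_start = c(1L, 200L, 250L, 500L),
    amplicon_stop = c(300L, 700L, 750L, 1000L),
    amplicon_length = c(300L, 501L, 501L, 501L)
  )
  g <- build_tiling_graph(pairs)
  res <- minimum_tiling_path(g)
  paths <- oracle_all_paths(g$nodes, g$edges, seq_len(nrow(g$nodes)))
  ws <- vapply(paths, oracle_path_w, numeric(1), edges = g$edges)
  # restrict to source-sink paths
  src <- which(g$nodes$start == min(g$nodes$start))
  snk <- which(g$nodes$stop == max(g$nodes$stop))
  ok <- vapply(paths, function(p) {
    p[1] %in% src && p[length(p)] %in% snk
  }, logical(1))
  best_w <- min(ws[ok])
  best_n <- min(lengths(paths)[ok & ws == best_w])
  got <- match(res$path$pair_id, g$nodes$pair_id)
  expect_equal(oracle_path_w(got, g$edges), best_w)
  expect_equal(length(got), best_n)
})

test_that("random graphs match brute force and Dijkstra", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    pairs <- random_pair_set(n)
    pairs <- pairs[!duplicated(pairs[, c("amplicon_start", "amplicon_stop")]), ]
    g <- build_tiling_graph(pairs)
    res <- minimum_tiling_path(g)

    for (comp in unique(g$nodes$component)) {
      comp_nodes <- which(g$nodes$component == comp)
      paths <- oracle_all_paths(g$nodes, g$edges, comp_nodes)
      cov <- vapply(paths, function(p) {
        sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
          g$nodes$start[p], g$nodes$stop[p]
        ))))
      }, numeric(1))
      best_cov <- max(cov)
      best_n <- min(lengths(paths)[cov == best_cov])

      chosen <- res$path[res$path$component == comp, ]
      got <- match(chosen$pair_id, g$nodes$pair_id)
      got_cov <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
        g$nodes$start[got], g$nodes$stop[got]
      ))))
      expect_equal(got_cov, best_cov)
      expect_equal(length(got), best_n)

      # Dijkstra cross-check: virtual source/sink with zero-weight arcs
      src <- comp_nodes[g$nodes$start[comp_nodes] ==
        min(g$nodes$start[comp_nodes])]
      snk <- comp_nodes[g$nodes$stop[comp_nodes] ==
        max(g$nodes$stop[comp_nodes])]
      nn <- nrow(g$nodes)
      ig_edges <- rbind(
        as.matrix(g$edges[, c("from", "to")]),
        cbind(nn + 1L, src),
        cbind(snk, nn + 2L)
      )
      ig <- igraph::graph_from_edgelist(ig_edges, directed = TRUE)
      wts <- c(g$edges$W, rep(0, length(src) + length(snk)))
      d <- igraph::distances(
        ig,
        v = nn + 1L, to = nn + 2L, mode = "out", weights = wts,
        algorithm = "dijkstra"
      )
      expect_equal(oracle_path_w(got, g$edges), as.numeric(d))
    }
  }
})

test_that("the shared-primer exception drops nested amplicons", {
  # two amplicons share a forward primer; the shorter is nested in the
  # longer and touches nothing else -> only the long one is retained
  pairs <- tibble::tibble(
    pair_id = c("short", "long", "far"),
    fwd_id = c("f1", "f1", "f9"), rev_id = c("r1", "r2", "r9"),
    amplicon_start = c(100L, 100L, 5000L),
    amplicon_stop = c(400L, 900L, 5600L),
    amplicon_length = c(301L, 801L, 601L)
  )
  res <- minimum_tiling_path(build_tiling_graph(pairs))
  expect_false("short" %in% res$path$pair_id)
  expect_true(all(c("long", "far") %in% res$path$pair_id))

  # with an external overlap present, the nested amplicon is kept in the
  # graph (no drop), though the path may not use it
  pairs2 <- dplyr::bind_rows(
    pairs,
    tibble::tibble(
      pair_id = "bridge", fwd_id = "f5", rev_id = "r5",
      amplicon_start = 300L, amplicon_stop = 1200L,
      amplicon_length = 901L
    )
  )
  drops <- thermotile:::shared_primer_nested_drops(
    build_tiling_graph(pairs2)$nodes
  )
  expect_equal(length(drops), 0)
})

test_that("coverage accounting partitions the target exactly", {
  pairs <- tibble::tibble(
    pair_id = c("A", "B"),
    fwd_id = c("f1", "f2"), rev_id = c("r1", "r2"),
    amplicon_start = c(100L, 800L),
    amplicon_stop = c(500L, 1300L),
    amplicon_length = c(401L, 501L)
  )
  res <- minimum_tiling_path(build_tiling_graph(pairs), target = c(1, 1500))
  covered <- sum(res$covered$stop - res$covered$start + 1)
  gaps <- sum(res$gaps$stop - res$gaps$start + 1)
  expect_equal(covered + gaps, 1500)
  expect_equal(res$coverage_fraction, covered / 1500)
  # every covered base lies inside a path amplicon
  for (i in seq_len(nrow(res$covered))) {
    expect_true(any(
      res$path$amplicon_start <= res$covered$start[i] &
        res$path$amplicon_stop >= res$covered$stop[i]
    ))
  }
})

test_that("widening the amplicon size range never reduces coverage", {
  set.seed(43)
  for (rep in 1:10) {
    pairs <- random_pair_set(15, span = 600, len_min = 50, len_max = 250)
    pairs <- pairs[!duplicated(pairs[, c("amplicon_start", "amplicon_stop")]), ]
    narrow <- pairs[pairs$amplicon_length >= 80 & pairs$amplicon_length <= 180, ]
    if (nrow(narrow) == 0) next
    res_wide <- minimum_tiling_path(
      build_tiling_graph(pairs),
      target = c(1, 850)
    )
    res_narrow <- minimum_tiling_path(
      build_tiling_graph(narrow),
      target = c(1, 850)
    )
    expect_gte(res_wide$coverage_fraction, res_narrow$coverage_fraction)
  }
})

test_that("multiplex groups alternate and never overlap internally", {
  pairs <- tibble::tibble(
    pair_id = paste0("P", 1:5),
    fwd_id = paste0("f", 1:5), rev_id = paste0("r", 1:5),
    amplicon_start = c(1L, 400L, 900L, 1400L, 1900L),
    amplicon_stop = c(500L, 1000L, 1500L, 2000L, 2500L),
    amplicon_length = c(500L, 601L, 601L, 601L, 601L)
  )
  res <- split_multiplex_groups(
    minimum_tiling_path(build_tiling_graph(pairs))
  )
  expect_setequal(unique(res$path$group), c("A", "B"))
  expect_equal(sort(table(res$path$group), decreasing = TRUE)[[1]], 3)
  for (grp in unique(res$path$group)) {
    members <- res$path[res$path$group == grp, ]
    if (nrow(members) < 2) next
    for (i in 1:(nrow(members) - 1)) {
      for (j in (i + 1):nrow(members)) {
        expect_false(
          members$amplicon_start[i] <= members$amplicon_stop[j] &&
            members$amplicon_stop[i] >= members$amplicon_start[j]
        )
      }
    }
  }
  # single amplicon: group A only
  one <- split_multiplex_groups(
    minimum_tiling_path(build_tiling_graph(pairs[1, ]))
  )
  expect_equal(one$path$group, "A")

  # disjoint subgraphs restart alternation; the audit resolves conflicts
  two_comp <- tibble::tibble(
    pair_id = paste0("Q", 1:4),
    fwd_id = paste0("f", 1:4), rev_id = paste0("r", 1:4),
    amplicon_start = c(1L, 200L, 2000L, 2200L),
    amplicon_stop = c(300L, 500L, 2300L, 2500L),
    amplicon_length = c(300L, 301L, 301L, 301L)
  )
  res2 <- split_multiplex_groups(
    minimum_tiling_path(build_tiling_graph(two_comp))
  )
  for (grp in unique(res2$path$group)) {
    members <- res2$path[res2$path$group == grp, ]
    if (nrow(members) < 2) next
    combs <- utils::combn(nrow(members), 2)
    for (k in seq_len(ncol(combs))) {
      i <- combs[1, k]
      j <- combs[2, k]
      expect_false(
        members$amplicon_start[i] <= members$amplicon_stop[j] &&
          members$amplicon_stop[i] >= members$amplicon_start[j]
      )
    }
  }
})

test_that("tidy and glance summarize a tiling result", {
  pairs <- tibble::tibble(
    pair_id = c("A", "B"),
    fwd_id = c("f1", "f2"), rev_id = c("r1", "r2"),
    amplicon_start = c(1L, 400L), amplicon_stop = c(600L, 1000L),
    amplicon_length = c(600L, 601L)
  )
  res <- split_multiplex_groups(
    minimum_tiling_path(build_tiling_graph(pairs))
  )
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(res)
  expect_equal(gl$n_amplicons, 2)
  expect_equal(gl$coverage_fraction, 1)
})
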
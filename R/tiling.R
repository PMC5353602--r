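#' Build the directed amplicon-overlap graph
#'
#' Each primer pair (expected amplicon) is a node. A directed edge `i -> j`
#' exists when the two amplicons overlap by at least 1 bp, amplicon `j` starts
#' after `i` and ends after `i` (strict inequalities), so edges strictly
#' increase both endpoints and the graph is acyclic. The raw edge score is the
#' cumulative length of the two amplicons penalized by their overlap,
#' `E = (len_i + len_j) - O_ij` (the union length); scores are rescaled
#' against the graph's maximum, `W = M_g - E >= 0`, so that Dijkstra's
#' shortest path prefers long, lightly-overlapping amplicons. Weakly connected
#' components partition the graph into subgraphs.
#'
#' @param pairs An `AmpliconPair` tibble from [enumerate_pairs()].
#' @return A `tiling_graph`: list with `nodes` (tibble: `node`, `pair_id`,
#'   `fwd_id`, `rev_id`, `start`, `stop`, `length`, `component`), `edges`
#'   (tibble: `from`, `to`, `overlap`, `E`, `W`), `m_g`, and the `igraph`
#'   object.
#' @export
build_tiling_graph <- function(pairs) {
  stopifnot(nrow(pairs) > 0)
  nodes <- pairs |>
    dplyr::arrange(.data$amplicon_start, .data$amplicon_stop, .data$pair_id) |>
    dplyr::transmute(
      node = dplyr::row_number(),
      pair_id = .data$pair_id, fwd_id = .data$fwd_id, rev_id = .data$rev_id,
      start = .data$amplicon_start, stop = .data$amplicon_stop,
      length = .data$amplicon_length
    )

  n <- nrow(nodes)
  # nodes are sorted by start: successors of i lie in a contiguous index
  # range (start in (start_i, stop_i]), filtered on the stop condition;
  # plain integer vectors keep dense graphs within memory
  lo <- findInterval(nodes$start, nodes$start) + 1L
  hi <- findInterval(nodes$stop, nodes$start)
  starts <- nodes$start
  stops <- nodes$stop
  succ <- vector("list", n)
  for (i in seq_len(n)) {
    if (lo[i] > hi[i]) next
    js <- seq.int(lo[i], hi[i])
    js <- js[stops[js] > stops[i] & starts[js] > starts[i]]
    if (length(js) > 0) succ[[i]] <- js
  }
  to <- as.integer(unlist(succ, use.names = FALSE))
  from <- rep.int(seq_len(n), vapply(succ, length, integer(1)))
  if (length(to) > 0) {
    overlap <- stops[from] - starts[to] + 1L
    e_score <- nodes$length[from] + nodes$length[to] - overlap
    m_g <- max(e_score)
    edges <- tibble::tibble(
      from = from, to = to, overlap = overlap,
      E = e_score, W = m_g - e_score
    )
  } else {
    edges <- tibble::tibble(
      from = integer(), to = integer(), overlap = integer(),
      E = integer(), W = integer()
    )
    m_g <- NA_integer_
  }

  g <- igraph::make_graph(rbind(edges$from, edges$to),
    n = n, directed = TRUE
  )
  nodes$component <- as.integer(igraph::components(g, mode = "weak")$membership)

  structure(
    list(nodes = nodes, edges = edges, m_g = m_g, graph = g),
    class = "tiling_graph"
  )
}

# Exception pre-pass: among amplicons sharing a primer and covering nested
# segments with no overlaps outside the shared-primer group, keep only the
# one with maximum coverage. Returns node indices to drop.
shared_primer_nested_drops <- function(nodes) {
  n <- nrow(nodes)
  # total number of amplicons overlapping each node (itself included),
  # by interval counting: #\{start_j <= stop_a\} - #\{stop_j < start_a\}
  starts_sorted <- sort(nodes$start)
  stops_sorted <- sort(nodes$stop)
  n_ov_total <- findInterval(nodes$stop, starts_sorted) -
    findInterval(nodes$start - 1L, stops_sorted)

  drops <- integer(0)
  for (key in c("fwd_id", "rev_id")) {
    groups <- split(seq_len(n), nodes[[key]])
    for (grp in groups) {
      if (length(grp) < 2) next
      for (a in grp) {
        contained <- any(
          nodes$start[grp] <= nodes$start[a] &
            nodes$stop[grp] >= nodes$stop[a] &
            grp != a &
            nodes$length[grp] > nodes$length[a]
        )
        if (!contained) next
        n_ov_grp <- sum(
          nodes$start[grp] <= nodes$stop[a] &
            nodes$stop[grp] >= nodes$start[a]
        )
        if (n_ov_total[a] == n_ov_grp) drops <- c(drops, a)
      }
    }
  }
  unique(drops)
}

#' Minimum amplicon tiling path per subgraph
#'
#' For each weakly connected subgraph, finds the transformed-weight-shortest
#' path from the source set (amplicons with the subgraph's minimal start,
#' behind a zero-weight virtual source) to the sink set (amplicons with the
#' maximal stop, ahead of a zero-weight virtual sink). The graph is a DAG
#' (edges strictly increase both amplicon endpoints), so the solver is a
#' dynamic program in start order, with deterministic tie-breaks: total W,
#' then fewer nodes, then lexicographically smallest start coordinates. A
#' pre-pass applies the shared-primer exception: among amplicons that share a
#' primer and cover nested segments with no overlaps outside the group, only
#' the maximum-coverage amplicon is retained. Coverage is accounted against
#' `target` (default: the span of all amplicons).
#'
#' @param graph A `tiling_graph` from [build_tiling_graph()].
#' @param target Optional `c(start, stop)` of the target region for coverage
#'   accounting.
#' @return A `tiling_result`: list with `path` (tibble: `component`,
#'   `position`, `pair_id`, `fwd_id`, `rev_id`, `amplicon_start`,
#'   `amplicon_stop`, `group` filled by [split_multiplex_groups()]),
#'   `covered` and `gaps` interval tibbles, `coverage_fraction`, `target`.
#' @export
minimum_tiling_path <- function(graph, target = NULL) {
  nodes <- graph$nodes
  drops <- shared_primer_nested_drops(nodes)
  if (length(drops) > 0) {
    keep <- setdiff(seq_len(nrow(nodes)), drops)
    # rebuild the reduced graph (edge set and components change)
    reduced <- tibble::tibble(
      pair_id = nodes$pair_id[keep], fwd_id = nodes$fwd_id[keep],
      rev_id = nodes$rev_id[keep],
      amplicon_start = nodes$start[keep], amplicon_stop = nodes$stop[keep],
      amplicon_length = nodes$length[keep]
    )
    graph <- build_tiling_graph(reduced)
    nodes <- graph$nodes
  }
  edges <- graph$edges

  path_rows <- list()
  for (comp in sort(unique(nodes$component))) {
    comp_nodes <- which(nodes$component == comp)
    sources <- comp_nodes[nodes$start[comp_nodes] ==
      min(nodes$start[comp_nodes])]
    sinks <- comp_nodes[nodes$stop[comp_nodes] ==
      max(nodes$stop[comp_nodes])]

    best <- dag_shortest_path(nodes, edges, comp_nodes, sources, sinks)
    path_rows[[length(path_rows) + 1]] <- tibble::tibble(
      component = comp,
      position = seq_along(best),
      pair_id = nodes$pair_id[best],
      fwd_id = nodes$fwd_id[best],
      rev_id = nodes$rev_id[best],
      amplicon_start = nodes$start[best],
      amplicon_stop = nodes$stop[best]
    )
  }
  path <- dplyr::bind_rows(path_rows) |>
    dplyr::arrange(.data$amplicon_start, .data$component, .data$position) |>
    dplyr::mutate(group = NA_character_)

  if (is.null(target)) {
    target <- c(min(nodes$start), max(nodes$stop))
  }
  ir <- IRanges::reduce(IRanges::IRanges(path$amplicon_start,
    path$amplicon_stop))
  ir <- IRanges::restrict(ir, start = target[1], end = target[2])
  covered <- tibble::tibble(
    start = IRanges::start(ir),
    stop = IRanges::end(ir)
  )
  gap_ir <- IRanges::gaps(ir, start = target[1], end = target[2])
  gaps <- tibble::tibble(
    start = IRanges::start(gap_ir),
    stop = IRanges::end(gap_ir)
  )
  coverage_fraction <- sum(IRanges::width(ir)) / (target[2] - target[1] + 1)

  structure(
    list(
      path = path, covered = covered, gaps = gaps,
      coverage_fraction = coverage_fraction, target = target
    ),
    class = "tiling_result"
  )
}

# Shortest path on the amplicon DAG, processing nodes in increasing start
# order (every edge strictly increases the start coordinate, so predecessors
# are always settled first). Ties on total W are broken by fewer nodes, then
# by the lexicographically smallest start-coordinate sequence. Falls back to
# the farthest-reaching amplicons when no sink is reachable from the source
# set. Returns node indices along the chosen path.
dag_shortest_path <- function(nodes, edges, comp_nodes, sources, sinks) {
  n_all <- nrow(nodes)
  dist <- rep(Inf, n_all)
  count <- rep(Inf, n_all)
  pred <- rep(NA_integer_, n_all)
  dist[sources] <- 0
  count[sources] <- 1

  path_of <- function(v) {
    p <- integer(0)
    while (!is.na(v)) {
      p <- c(v, p)
      v <- pred[v]
    }
    p
  }
  lex_less <- function(a, b) {
    sa <- nodes$start[a]
    sb <- nodes$start[b]
    m <- min(length(sa), length(sb))
    for (i in seq_len(m)) {
      if (sa[i] != sb[i]) {
        return(sa[i] < sb[i])
      }
    }
    length(sa) < length(sb)
  }

  in_comp <- logical(n_all)
  in_comp[comp_nodes] <- TRUE
  sel <- in_comp[edges$to]
  ef <- edges$from[sel]
  et <- edges$to[sel]
  ew <- edges$W[sel]
  in_idx <- split(seq_along(et), et)
  order_by_start <- comp_nodes[order(
    nodes$start[comp_nodes], nodes$stop[comp_nodes], comp_nodes
  )]
  for (v in order_by_start) {
    # sources have no in-edges (they hold the minimal start, and edges
    # strictly increase start), so each node is settled exactly once here
    rows <- in_idx[[as.character(v)]]
    if (is.null(rows)) next
    from <- ef[rows]
    d <- dist[from] + ew[rows]
    finite <- is.finite(d)
    if (!any(finite)) next
    from <- from[finite]
    d <- d[finite]
    nn <- count[from] + 1
    best_d <- min(d)
    tie <- which(d == best_d)
    best_n <- min(nn[tie])
    tie <- tie[nn[tie] == best_n]
    choice <- from[tie[1]]
    for (t in tie[-1]) {
      if (lex_less(path_of(from[t]), path_of(choice))) {
        choice <- from[t]
      }
    }
    dist[v] <- best_d
    count[v] <- best_n
    pred[v] <- choice
  }
  reach_sinks <- sinks[is.finite(dist[sinks])]
  if (length(reach_sinks) == 0) {
    reachable <- comp_nodes[is.finite(dist[comp_nodes])]
    reach_sinks <- reachable[nodes$stop[reachable] ==
      max(nodes$stop[reachable])]
  }
  pick <- reach_sinks[order(
    dist[reach_sinks], count[reach_sinks], nodes$start[reach_sinks]
  )][1]
  if (length(reach_sinks) > 1) {
    o <- reach_sinks[dist[reach_sinks] == dist[pick] &
      count[reach_sinks] == count[pick]]
    for (t in o) {
      if (lex_less(path_of(t), path_of(pick))) pick <- t
    }
  }
  path_of(pick)
}

#' Split a tiling path into two multiplex-compatible groups
#'
#' Assigns path amplicons alternately (within each subgraph) to groups A and
#' B, so that consecutive overlapping amplicons land in different PCR tubes,
#' then audits all pairwise overlaps (overlaps can also arise across
#' subgraphs): an amplicon conflicting with its group is flipped; if both
#' groups conflict it opens a further group with a warning.
#'
#' @param result A `tiling_result` from [minimum_tiling_path()].
#' @return The `tiling_result` with the path's `group` column filled.
#' @export
split_multiplex_groups <- function(result) {
  path <- result$path |>
    dplyr::group_by(.data$component) |>
    dplyr::mutate(
      group = ifelse(.data$position %% 2 == 1, "A", "B")
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$amplicon_start, .data$amplicon_stop)

  groups <- unique(c("A", "B"))
  assigned <- character(nrow(path))
  overlaps <- function(i, members) {
    any(path$amplicon_start[members] <= path$amplicon_stop[i] &
      path$amplicon_stop[members] >= path$amplicon_start[i])
  }
  for (i in seq_len(nrow(path))) {
    want <- path$group[i]
    cands <- unique(c(want, setdiff(groups, want)))
    placed <- FALSE
    for (gname in cands) {
      members <- which(assigned == gname)
      if (length(members) == 0 || !overlaps(i, members)) {
        assigned[i] <- gname
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      gname <- LETTERS[length(groups) + 1]
      groups <- c(groups, gname)
      assigned[i] <- gname
      warning(
        "split_multiplex_groups: no 2-coloring without intra-group ",
        "overlap exists; opened group ", gname
      )
    }
  }
  path$group <- assigned
  result$path <- path |>
    dplyr::arrange(.data$component, .data$position)
  result
}

#' @export
print.tiling_result <- function(x, ...) {
  cat(sprintf(
    "<tiling_result> %d amplicon(s) in %d subgraph(s); coverage %.1f%% of %d-%d\n",
    nrow(x$path), dplyr::n_distinct(x$path$component),
    100 * x$coverage_fraction, x$target[1], x$target[2]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a tiling result into its path table
#'
#' @param x A `tiling_result`.
#' @param ... Unused.
#' @return The ordered path tibble (one row per selected amplicon).
#' @method tidy tiling_result
#' @export
tidy.tiling_result <- function(x, ...) {
  x$path
}

#' One-row summary of a tiling result
#'
#' @param x A `tiling_result`.
#' @param ... Unused.
#' @return Tibble with coverage fraction, amplicon/subgraph/group counts and
#'   covered/gap base totals.
#' @method glance tiling_result
#' @export
glance.tiling_result <- function(x, ...) {
  tibble::tibble(
    n_amplicons = nrow(x$path),
    n_subgraphs = dplyr::n_distinct(x$path$component),
    n_groups = dplyr::n_distinct(stats::na.omit(x$path$group)),
    coverage_fraction = x$coverage_fraction,
    covered_bp = sum(x$covered$stop - x$covered$start + 1),
    gap_bp = sum(x$gaps$stop - x$gaps$start + 1)
  )
}
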
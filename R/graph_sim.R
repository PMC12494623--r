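#' Simulate a protein-interaction graph with planted bridge nodes
#'
#' Builds an undirected graph of `n_communities` dense communities whose
#' only cross-community connections run through `n_bridges` planted bridge
#' node(s): every inter-community shortest path is forced through a bridge
#' once sub-threshold edges are removed.  Within-community edges and bridge
#' spokes carry strengths in (0.2, 1]; `n_decoy` additional cross-community
#' edges carry strengths of at most 0.15, so that the strict
#' strength-greater-than-0.15 filter used downstream is exercised.
#'
#' Non-bridge nodes are named after the antigen panel's proteins (extended
#' with `EXT` identifiers if the graph is larger than the panel); bridge
#' nodes are named `BRG01`, `BRG02`, ...
#'
#' @param config an [sba_config()] object; `config$graph_spec` holds the
#'   graph dimensions (see [sba_config()]).
#' @return An igraph object with edge attribute `strength`, vertex
#'   attribute `community` (bridges carry `NA`), and graph attributes
#'   `bridges` (bridge node names) and `provenance`.
#' @examples
#' g <- simulate_interaction_graph(sba_config(rng_seed = 7))
#' igraph::graph_attr(g, "bridges")
#' @export
simulate_interaction_graph <- function(config) {
  validate_sba_config(config)
  with_seed(config$rng_seed + 1L, simulate_graph_impl(config))
}

simulate_graph_impl <- function(cfg) {
  gs <- cfg$graph_spec
  n_nodes <- gs$n_nodes
  n_comm <- gs$n_communities
  n_br <- gs$n_bridges
  p_within <- gs$p_within %||% 0.3
  n_decoy <- gs$n_decoy %||% 0

  lay <- panel_layout(cfg)
  prot <- unique(sub("_\\d+$", "", lay$names))
  n_free <- n_nodes - n_br
  nms <- if (length(prot) >= n_free) prot[seq_len(n_free)] else {
    c(prot, sprintf("EXT%03d", seq_len(n_free - length(prot))))
  }
  bridges <- sprintf("BRG%02d", seq_len(n_br))

  membership <- rep(seq_len(n_comm), length.out = n_free)
  membership <- sort(membership)  # contiguous communities

  ef <- function(a, b, s) data.frame(from = a, to = b, strength = s,
                                     stringsAsFactors = FALSE)
  edges <- list()

  for (k in seq_len(n_comm)) {
    mem <- nms[membership == k]
    sz <- length(mem)
    if (sz >= 2) {
      # random spanning chain guarantees within-community connectivity
      perm <- sample(mem)
      edges[[length(edges) + 1L]] <-
        ef(perm[-sz], perm[-1], stats::runif(sz - 1, 0.2, 1))
      if (sz >= 3) {
        pr <- t(utils::combn(mem, 2))
        keep <- stats::runif(nrow(pr)) < p_within
        if (any(keep)) {
          edges[[length(edges) + 1L]] <-
            ef(pr[keep, 1], pr[keep, 2], stats::runif(sum(keep), 0.2, 1))
        }
      }
    }
    # bridge spokes: each bridge attaches to up to two members per community
    for (b in bridges) {
      sp <- sample(mem, min(2, sz))
      edges[[length(edges) + 1L]] <- ef(rep(b, length(sp)), sp,
                                        stats::runif(length(sp), 0.2, 1))
    }
  }

  if (n_decoy > 0 && n_comm >= 2) {
    for (d in seq_len(n_decoy)) {
      ks <- sample(n_comm, 2)
      a <- sample(nms[membership == ks[1]], 1)
      b <- sample(nms[membership == ks[2]], 1)
      edges[[length(edges) + 1L]] <- ef(a, b, stats::runif(1, 0.01, 0.15))
    }
  }

  ed <- do.call(rbind, edges)
  # drop duplicate undirected edges, keeping the maximum strength
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  ed <- ed[order(key, -ed$strength), ]
  ed <- ed[!duplicated(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))), ]

  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = c(nms, bridges),
                          community = c(membership, rep(NA, n_br))))
  igraph::graph_attr(g, "bridges") <- bridges
  igraph::graph_attr(g, "provenance") <- "synthetic"
  g
}

#' Filter an interaction graph by edge strength
#'
#' Keeps edges whose `strength` attribute strictly exceeds `threshold`
#' (a score of exactly 0.15 is excluded at the default threshold).
#' Vertices are retained even if isolated afterwards.
#'
#' @param graph igraph with a `strength` edge attribute.
#' @param threshold minimum (exclusive) strength.
#' @return The filtered igraph; warns if no edges survive.
#' @export
filter_graph <- function(graph, threshold = 0.15) {
  s <- igraph::E(graph)$strength
  if (is.null(s)) stop("graph has no 'strength' edge attribute", call. = FALSE)
  out <- igraph::delete_edges(graph, which(!(s > threshold)))
  if (igraph::ecount(out) == 0) {
    warning("no edges exceed the strength threshold", call. = FALSE)
  }
  igraph::graph_attr(out, "threshold") <- threshold
  out
}
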
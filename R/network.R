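#' Load a STRING-style protein interaction edge list
#'
#' Parses a whitespace-delimited `protein1 protein2 combined_score` file.
#' The score dialect is auto-detected from the maximum value: scores above
#' 1 are taken as the STRING 0-1000 scale and divided by 1000, otherwise
#' they are used as fractional strengths in (0, 1].  Edges are kept only if
#' strength is strictly greater than `threshold` (a score of exactly 0.15
#' is excluded at the default threshold); duplicate undirected edges are
#' merged keeping the maximum strength.
#'
#' @param path edge-list file.
#' @param threshold strength threshold (exclusive).
#' @param dialect `"auto"` (default), `"string"` (0-1000) or
#'   `"fractional"` (0-1).
#' @return igraph with edge attribute `strength` and graph attributes
#'   `source_file`, `dialect`, `threshold`.  Warns if no edge survives.
#' @export
load_edges <- function(path, threshold = 0.15,
                       dialect = c("auto", "string", "fractional")) {
  dialect <- match.arg(dialect)
  first <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("edge list needs 3 columns", call. = FALSE)
  names(tab)[1:3] <- c("protein1", "protein2", "combined_score")
  score <- suppressWarnings(as.numeric(tab$combined_score))
  if (any(is.na(score))) {
    bad <- which(is.na(score))[1] + has_header
    stop("unparseable score at line ", bad, " of ", path, call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- if (max(score) > 1) "string" else "fractional"
  }
  strength <- if (dialect == "string") score / 1000 else score
  keep <- strength > threshold
  ed <- data.frame(from = as.character(tab$protein1[keep]),
                   to = as.character(tab$protein2[keep]),
                   strength = strength[keep], stringsAsFactors = FALSE)
  ed <- ed[ed$from != ed$to, , drop = FALSE]  # no self-loops
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  ed <- ed[order(key, -ed$strength), , drop = FALSE]
  ed <- ed[!duplicated(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))), ,
           drop = FALSE]
  if (nrow(ed) == 0) warning("no edges exceed the threshold", call. = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  igraph::graph_attr(g, "source_file") <- path
  igraph::graph_attr(g, "dialect") <- dialect
  igraph::graph_attr(g, "threshold") <- threshold
  g
}

#' Build a seed set from an association table
#'
#' Maps antigen fragments to proteins (the trailing `_k` fragment suffix is
#' collapsed; for proteins with several fragments the maximum rho is kept)
#' and selects the top `k` proteins by descending rho for the given
#' parameter.  Ties at the k-th rank are broken alphabetically.
#'
#' @param assoc an `assoc_table` from [spearman_screen()].
#' @param parameter clinical parameter name.
#' @param k number of seed proteins (study value 10).
#' @return Character vector of protein identifiers with attributes
#'   `origin` and `rho`; if fewer than `k` distinct proteins are available
#'   all are returned with a warning.
#' @export
seed_from_associations <- function(assoc, parameter, k = 10) {
  sub <- assoc[assoc$parameter == parameter & !is.na(assoc$rho), , drop = FALSE]
  if (nrow(sub) == 0) stop("no correlations for parameter ", parameter,
                           call. = FALSE)
  sub$protein <- sub("_\\d+$", "", sub$antigen)
  agg <- stats::aggregate(rho ~ protein, data = sub, FUN = max)
  agg <- agg[order(-agg$rho, agg$protein), , drop = FALSE]
  if (nrow(agg) < k) {
    warning("only ", nrow(agg), " distinct proteins available (requested ",
            k, ")", call. = FALSE)
    k <- nrow(agg)
  }
  out <- agg$protein[seq_len(k)]
  attr(out, "origin") <- paste0("top-", k, ":", parameter)
  attr(out, "rho") <- agg$rho[seq_len(k)]
  out
}

# Single-source BFS with shortest-path counting (hop metric).
# Returns integer distances (Inf if unreachable) and path counts sigma.
bfs_count <- function(adj, n, src) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[src] <- 0
  sigma[src] <- 1
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      du1 <- dist[u] + 1
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- du1
          sigma[v] <- sigma[v] + sigma[u]
          nxt <- c(nxt, v)
        } else if (dist[v] == du1) {
          sigma[v] <- sigma[v] + sigma[u]
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

adjacency_list <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Shortest-path recurrence of nodes and edges over a seed set
#'
#' For every unordered pair of seed proteins, all unweighted (hop-count)
#' shortest paths between them are counted exactly: with \eqn{\sigma_{sv}}
#' the number of shortest s-v paths, a non-endpoint node \eqn{v} lies on
#' \eqn{\sigma_{sv}\,\sigma_{vt}} shortest s-t paths when
#' \eqn{d_{sv} + d_{vt} = d_{st}}, and an edge \eqn{(u,v)} on
#' \eqn{\sigma_{su}\,\sigma_{vt}} when \eqn{d_{su} + 1 + d_{vt} = d_{st}}
#' (either orientation).  Recurrence counts \eqn{R(v)}, \eqn{R(e)} are the
#' sums over all seed pairs; highly recurrent non-seed nodes are the
#' "bridge" intermediaries of the network.  Counting is by integer products
#' (no path enumeration, no sampling); per-pair conservation identities
#' (interior node counts sum to \eqn{\sigma_{st}(d_{st}-1)}, edge counts to
#' \eqn{\sigma_{st} d_{st}}) are asserted on every pair.
#'
#' @param graph igraph (typically already strength-filtered, see
#'   [load_edges()] / [filter_graph()]).
#' @param seeds character vector of seed node names (>= 2); seeds absent
#'   from the graph are excluded from the pairing and reported.
#' @return Object of class `path_recurrence`: list with `node_recurrence`
#'   (named, all graph nodes), `edge_recurrence` (data.frame from/to/count/
#'   strength), `pairs` (per-pair s, t, distance, n_paths, reachable),
#'   `unreachable_pairs`, `seeds_used`, `seeds_missing`.
#' @export
shortest_path_recurrence <- function(graph, seeds) {
  nm <- igraph::V(graph)$name
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, nm)
  seeds_used <- intersect(seeds, nm)
  if (length(seeds_used) < 2) {
    stop("need at least 2 seeds present in the graph", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  adj <- adjacency_list(graph)
  sidx <- match(seeds_used, nm)
  bfs <- lapply(sidx, function(s) bfs_count(adj, n, s))
  names(bfs) <- seeds_used

  el <- igraph::as_edgelist(graph, names = FALSE)
  strength <- igraph::E(graph)$strength
  node_R <- numeric(n)
  edge_R <- numeric(nrow(el))
  pairs <- list()
  for (i in seq_along(seeds_used)[-length(seeds_used)]) {
    for (j in seq.int(i + 1, length(seeds_used))) {
      s <- sidx[i]; t <- sidx[j]
      bs <- bfs[[i]]; bt <- bfs[[j]]
      d <- bs$dist[t]
      if (is.infinite(d)) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(s = nm[s], t = nm[t], distance = NA_real_,
                     n_paths = 0, reachable = FALSE)
        next
      }
      sig <- bs$sigma[t]
      on_path <- bs$dist + bt$dist == d
      cnt <- ifelse(on_path, bs$sigma * bt$sigma, 0)
      interior <- cnt
      interior[c(s, t)] <- 0
      stopifnot(sum(interior) == sig * (d - 1))  # conservation (nodes)
      node_R <- node_R + interior

      e_cnt <- numeric(nrow(el))
      u <- el[, 1]; v <- el[, 2]
      f1 <- bs$dist[u] + 1 + bt$dist[v] == d
      f2 <- bs$dist[v] + 1 + bt$dist[u] == d
      e_cnt[f1] <- bs$sigma[u[f1]] * bt$sigma[v[f1]]
      e_cnt[f2] <- e_cnt[f2] + bs$sigma[v[f2]] * bt$sigma[u[f2]]
      stopifnot(sum(e_cnt) == sig * d)           # conservation (edges)
      edge_R <- edge_R + e_cnt

      pairs[[length(pairs) + 1L]] <-
        data.frame(s = nm[s], t = nm[t], distance = d, n_paths = sig,
                   reachable = TRUE)
    }
  }
  pairs <- do.call(rbind, pairs)
  structure(list(
    node_recurrence = stats::setNames(node_R, nm),
    edge_recurrence = data.frame(from = nm[el[, 1]], to = nm[el[, 2]],
                                 count = edge_R, strength = strength,
                                 stringsAsFactors = FALSE),
    pairs = pairs,
    unreachable_pairs = pairs[!pairs$reachable, c("s", "t"), drop = FALSE],
    seeds_used = seeds_used, seeds_missing = missing),
    class = "path_recurrence")
}

#' @export
print.path_recurrence <- function(x, ...) {
  cat(sprintf("Shortest-path recurrence over %d seeds (%d pairs, %d unreachable)\n",
              length(x$seeds_used), nrow(x$pairs), nrow(x$unreachable_pairs)))
  top <- sort(x$node_recurrence[setdiff(names(x$node_recurrence),
                                        x$seeds_used)], decreasing = TRUE)
  top <- top[top > 0]
  cat("  top intermediaries:",
      paste(utils::head(sprintf("%s (%g)", names(top), top), 5),
            collapse = ", "), "\n")
  if (length(x$seeds_missing)) {
    cat("  seeds missing from graph:",
        paste(x$seeds_missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate every distinct shortest path between two nodes
#'
#' Depth-first traversal of the BFS predecessor structure; intended as the
#' exhaustive cross-check for [shortest_path_recurrence()].  Errors (never
#' truncates) if the number of shortest paths exceeds `cap`.
#'
#' @param graph igraph.
#' @param s,t node names.
#' @param cap maximum number of paths to enumerate.
#' @return List of node-name vectors (each a shortest s-t path); empty if
#'   unreachable; a single zero-length path when `s == t`.
#' @export
enumerate_all_shortest_paths <- function(graph, s, t, cap = 1e6) {
  nm <- igraph::V(graph)$name
  si <- match(s, nm); ti <- match(t, nm)
  if (is.na(si) || is.na(ti)) stop("s and t must be graph nodes", call. = FALSE)
  if (si == ti) return(list(nm[si]))
  n <- igraph::vcount(graph)
  adj <- adjacency_list(graph)
  bs <- bfs_count(adj, n, si)
  if (is.infinite(bs$dist[ti])) return(list())
  if (bs$sigma[ti] > cap) {
    stop("number of shortest paths (", bs$sigma[ti], ") exceeds cap ", cap,
         call. = FALSE)
  }
  paths <- list()
  walk <- function(v, acc) {
    if (v == si) {
      paths[[length(paths) + 1L]] <<- nm[c(si, rev(acc))]
      return(invisible())
    }
    for (u in adj[[v]]) {
      if (bs$dist[u] + 1 == bs$dist[v]) walk(u, c(acc, v))
    }
  }
  walk(ti, integer(0))
  paths
}

#' Export a recurrence report
#'
#' Writes a GraphML file with node attributes `seed` and `recurrence` and
#' edge attributes `strength` and `recurrence`, plus a CSV table of
#' non-seed intermediaries ranked by recurrence.
#'
#' @param report a `path_recurrence`.
#' @param graph the igraph the report was computed on.
#' @param dir output directory (created if missing).
#' @return Invisibly, the two paths written (`graphml`, `table`).
#' @export
export_network <- function(report, graph, dir) {
  stopifnot(inherits(report, "path_recurrence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- igraph::V(graph)$name
  if (!identical(sort(nm), sort(names(report$node_recurrence)))) {
    stop("report and graph node sets differ", call. = FALSE)
  }
  igraph::V(graph)$seed <- as.integer(nm %in% report$seeds_used)
  igraph::V(graph)$recurrence <- unname(report$node_recurrence[nm])
  igraph::E(graph)$recurrence <- report$edge_recurrence$count
  gpath <- file.path(dir, "network.graphml")
  igraph::write_graph(graph, gpath, format = "graphml")
  tab <- data.frame(node = nm, recurrence = unname(report$node_recurrence[nm]),
                    seed = nm %in% report$seeds_used,
                    stringsAsFactors = FALSE)
  tab <- tab[!tab$seed, , drop = FALSE]
  tab <- tab[order(-tab$recurrence, tab$node), , drop = FALSE]
  tpath <- file.path(dir, "intermediaries.csv")
  utils::write.csv(tab, tpath, row.names = FALSE)
  invisible(c(graphml = gpath, table = tpath))
}
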
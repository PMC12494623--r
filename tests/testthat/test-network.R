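write_edge_file <- function(lines, header = TRUE) {
  f <- tempfile(fileext = ".tsv")
  if (header) lines <- c("protein1 protein2 combined_score", lines)
  writeLines(lines, f)
  f
}

test_that("edge loading applies the strict strength threshold by dialect", {
  f <- write_edge_file(c("A B 150", "A C 151", "B C 900"))
  g <- load_edges(f)                       # STRING 0-1000 dialect
  ed <- igraph::as_data_frame(g)
  expect_false(any(ed$from == "A" & ed$to == "B"))   # 0.15 excluded (strict >)
  expect_true(any((ed$from == "A" & ed$to == "C") |
                    (ed$from == "C" & ed$to == "A")))  # 0.151 included
  expect_equal(igraph::graph_attr(g, "dialect"), "string")
  # fractional dialect auto-detected when max score <= 1
  f2 <- write_edge_file(c("A B 0.150", "A C 0.2"))
  g2 <- load_edges(f2)
  expect_equal(igraph::graph_attr(g2, "dialect"), "fractional")
  expect_equal(igraph::ecount(g2), 1)
  # duplicate undirected edges merge keeping the maximum strength
  f3 <- write_edge_file(c("A B 400", "B A 700", "A A 900"))
  g3 <- load_edges(f3)
  expect_equal(igraph::ecount(g3), 1)      # self-loop dropped, pair merged
  expect_equal(igraph::E(g3)$strength, 0.7)
  # unparseable score reported with its line number
  f4 <- write_edge_file(c("A B 400", "A C oops"))
  expect_error(load_edges(f4), "line 3")
  # empty result warns
  f5 <- write_edge_file("A B 0.10", header = FALSE)
  expect_warning(load_edges(f5), "threshold")
})

test_that("raising the threshold never adds edges", {
  g <- simulate_interaction_graph(sba_config(rng_seed = 3))
  e1 <- igraph::as_data_frame(filter_graph(g, 0.15))
  e2 <- igraph::as_data_frame(filter_graph(g, 0.4))
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_true(all(key(e2) %in% key(e1)))
  expect_lt(nrow(e2), nrow(e1))
  # sub-threshold decoys exist so the filter has work to do
  expect_lt(igraph::ecount(filter_graph(g, 0.15)), igraph::ecount(g))
})

test_that("seed sets collapse fragments and keep the top-k by rho", {
  assoc <- data.frame(
    antigen = c(sprintf("P%02d", 1:11), "P01_2"),
    parameter = "SE",
    rho = c(seq(0.30, 0.10, length.out = 11), 0.45),
    p = 0.01, q = 0.05, n_used = 116)
  class(assoc) <- c("assoc_table", "data.frame")
  seeds <- seed_from_associations(assoc, "SE", k = 10)
  expect_length(seeds, 10)
  expect_equal(seeds[1], "P01")                 # fragment max: 0.45 wins
  expect_equal(attr(seeds, "rho")[1], 0.45)
  expect_false("P11" %in% seeds)                # 12 proteins, lowest 2 dropped
  expect_warning(seed_from_associations(assoc, "SE", k = 50), "distinct")
  expect_error(seed_from_associations(assoc, "CCT"), "no correlations")
})

test_that("two bridged cliques route every cross pair through the bridge", {
  ed <- rbind(
    expand.grid(from = paste0("L", 1:5), to = paste0("L", 1:5),
                stringsAsFactors = FALSE),
    expand.grid(from = paste0("R", 1:5), to = paste0("R", 1:5),
                stringsAsFactors = FALSE))
  ed <- ed[as.character(ed$from) < as.character(ed$to), ]
  ed <- rbind(ed, data.frame(from = "BRG", to = c(paste0("L", 1:5),
                                                  paste0("R", 1:5))))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  igraph::E(g)$strength <- 0.9
  rep_ <- shortest_path_recurrence(g, c(paste0("L", 1:5), paste0("R", 1:5)))
  expect_equal(unname(rep_$node_recurrence[["BRG"]]), 25)
  expect_equal(names(which.max(rep_$node_recurrence)), "BRG")
  # each cross pair is at distance 2 with a single shortest path
  cross <- rep_$pairs[substr(rep_$pairs$s, 1, 1) != substr(rep_$pairs$t, 1, 1), ]
  expect_true(all(cross$distance == 2))
  expect_true(all(cross$n_paths == 1))
})

test_that("path-graph recurrence counts nodes and edges exactly", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("s", "a"), to = c("a", "t")), directed = FALSE)
  igraph::E(g)$strength <- 1
  rep_ <- shortest_path_recurrence(g, c("s", "t"))
  expect_equal(unname(rep_$node_recurrence[c("s", "a", "t")]), c(0, 1, 0))
  expect_equal(rep_$edge_recurrence$count, c(1, 1))
  # seed order does not matter
  rep2 <- shortest_path_recurrence(g, c("t", "s"))
  expect_equal(rep2$node_recurrence, rep_$node_recurrence)
  # absent seeds are excluded and reported, not silently dropped
  rep3 <- shortest_path_recurrence(g, c("s", "t", "ghost"))
  expect_identical(rep3$seeds_missing, "ghost")
  expect_equal(rep3$node_recurrence, rep_$node_recurrence)
  expect_error(shortest_path_recurrence(g, c("s", "ghost")), "at least 2")
})

test_that("path enumeration matches the counting DP in both directions", {
  # 4-cycle: two shortest paths between opposite corners
  g4 <- igraph::make_ring(4)
  igraph::V(g4)$name <- c("s", "a", "t", "b")
  paths <- enumerate_all_shortest_paths(g4, "s", "t")
  expect_length(paths, 2)
  expect_true(all(lengths(paths) == 3))
  # s == t: one zero-length path by convention
  expect_identical(enumerate_all_shortest_paths(g4, "s", "s"), list("s"))
  # unreachable: empty list
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "c"), to = c("b", "d")), directed = FALSE)
  expect_length(enumerate_all_shortest_paths(g2, "a", "c"), 0)
  # K4: enumeration count equals the DP's sigma for every seed pair
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("k", 1:4)
  igraph::E(k4)$strength <- 1
  rep_ <- shortest_path_recurrence(k4, c("k1", "k4"))
  expect_equal(rep_$pairs$n_paths,
               length(enumerate_all_shortest_paths(k4, "k1", "k4")))
  # a layered graph with 2^8 shortest paths trips the cap
  lay <- data.frame(from = character(0), to = character(0))
  prev <- "src"
  for (l in 1:8) {
    cur <- paste0("v", l, c("a", "b"))
    lay <- rbind(lay, expand.grid(from = prev, to = cur, stringsAsFactors = FALSE))
    prev <- cur
  }
  lay <- rbind(lay, expand.grid(from = prev, to = "snk", stringsAsFactors = FALSE))
  gl <- igraph::graph_from_data_frame(lay, directed = FALSE)
  expect_length(enumerate_all_shortest_paths(gl, "src", "snk", cap = 1e6), 256)
  expect_error(enumerate_all_shortest_paths(gl, "src", "snk", cap = 100),
               "exceeds cap")
})

test_that("recurrence equals the enumeration oracle on random graphs", {
  for (s in 1:40) {
    g <- random_test_graph(n = sample(8:20, 1), p = runif(1, 0.15, 0.4),
                           seed = 1000 + s)
    seeds <- sample(igraph::V(g)$name, sample(4:6, 1))
    rep_ <- shortest_path_recurrence(g, seeds)
    oracle <- recurrence_from_enumeration(g, seeds)
    expect_equal(rep_$node_recurrence, oracle$node)
    ek <- paste(pmin(rep_$edge_recurrence$from, rep_$edge_recurrence$to),
                pmax(rep_$edge_recurrence$from, rep_$edge_recurrence$to))
    expect_equal(setNames(rep_$edge_recurrence$count, ek), oracle$edge)
    # sigma cross-checked against igraph's independent implementation
    pr <- rep_$pairs[rep_$pairs$reachable, ][1, ]
    if (!is.na(pr$s)) {
      ig <- length(igraph::all_shortest_paths(g, pr$s, pr$t)$res)
      expect_equal(pr$n_paths, ig)
    }
  }
})

test_that("simulated interaction graphs carry the planted bridge structure", {
  cfg <- sba_config(rng_seed = 41)
  g <- simulate_interaction_graph(cfg)
  expect_identical(igraph::graph_attr(g, "bridges"), "BRG01")
  expect_true(all(igraph::E(g)$strength > 0 & igraph::E(g)$strength <= 1))
  expect_false(any(igraph::which_loop(g)))
  expect_equal(igraph::vcount(g), 60)
  # after threshold filtering, communities connect only through the bridge
  fg <- filter_graph(g, 0.15)
  mem <- igraph::V(fg)$community
  ed <- igraph::as_data_frame(fg)
  m1 <- mem[match(ed$from, igraph::V(fg)$name)]
  m2 <- mem[match(ed$to, igraph::V(fg)$name)]
  cross <- !is.na(m1) & !is.na(m2) & m1 != m2
  expect_false(any(cross))
})

test_that("exported networks carry recurrence attributes and rankings", {
  ed <- data.frame(from = c("s", "a"), to = c("a", "t"))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  igraph::E(g)$strength <- c(0.5, 0.9)
  rep_ <- shortest_path_recurrence(g, c("s", "t"))
  dir <- withr::local_tempdir()
  paths <- export_network(rep_, g, dir)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths[["table"]])
  expect_equal(tab$node[1], "a")           # the intermediary ranks first
  g2 <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(sort(igraph::V(g2)$recurrence),
               sort(unname(rep_$node_recurrence)))
  expect_equal(sort(igraph::E(g2)$recurrence),
               sort(rep_$edge_recurrence$count))
})
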
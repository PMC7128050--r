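test_that("PPI loading applies the confidence cutoff and deduplicates", {
  df <- data.frame(
    protein1 = c("a", "a", "b", "c", "d", "d", "e", "a", "f", "g", "h", "h"),
    protein2 = c("b", "b", "c", "d", "e", "e", "f", "c", "g", "h", "i", "h"),
    combined_score = c(950, 950, 899, 900, 980, 990, 700, 910, 901, 999, 905, 999),
    stringsAsFactors = FALSE)
  g <- load_ppi(df, score_cutoff = 900)
  # hand count: a-b, c-d, d-e, a-c, f-g, g-h, h-i survive; the a-b and d-e
  # duplicates collapse, b-c (899) and e-f (700) fall below the cutoff,
  # and the h-h self loop is removed
  expect_equal(igraph::ecount(g), 7)
  expect_false(igraph::any_multiple(g))
  expect_false(igraph::any_loop(g))
  # boundary: 899 dropped at cutoff 900
  expect_false(igraph::are_adjacent(g, "b", "c"))
  expect_error(load_ppi(data.frame(protein1 = "a", protein2 = "b",
                                   combined_score = "high")), "unparseable")
})

test_that("DEG subnetwork equals DEGs plus first neighbours, by adjacency oracle", {
  g <- random_named_graph(50, 0.08, seed = 13)
  degs <- igraph::V(g)$name[c(1, 5, 9, 20, 33, 41, 42, 48, 50, 17)]
  comps <- deg_subnetwork(g, degs)
  got <- sort(unlist(lapply(comps, function(c) igraph::V(c)$name)))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expected <- sort(union(degs, colnames(adj)[colSums(adj[degs, , drop = FALSE]) > 0]))
  expect_equal(got, expected)
  # components are sorted by size and partition the node set
  sizes <- vapply(comps, igraph::vcount, 0)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sum(sizes), length(expected))

  # star graph with the centre as DEG covers the whole star
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:6)
  comps2 <- deg_subnetwork(star, "v1")
  expect_equal(igraph::vcount(comps2[[1]]), 6)

  # DEG with no retained edges comes back as a singleton component
  iso <- igraph::make_graph(~ a - b, c)
  comps3 <- deg_subnetwork(iso, c("a", "c"))
  expect_equal(vapply(comps3, igraph::vcount, 0), c(2, 1))

  expect_error(deg_subnetwork(g, "nope"), class = "ncmod_empty_intersection")
})

test_that("MCODE vertex weights match the brute-force neighbourhood k-core oracle", {
  # 5-clique plus pendant
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("v", 1:5)
  g <- igraph::add_vertices(g, 1, name = "p")
  g <- igraph::add_edges(g, c(1, 6))
  w <- mcode_vertex_weights(g)
  for (v in seq_len(igraph::vcount(g))) {
    nm <- igraph::V(g)$name[v]
    expected <- if (igraph::degree(g, v) < 2) 0 else oracle_mcode_weight(g, v)
    expect_equal(unname(w[nm]), expected, tolerance = 1e-12, info = nm)
  }
  # random graph
  g2 <- random_named_graph(25, 0.2, seed = 21)
  w2 <- mcode_vertex_weights(g2)
  for (v in seq_len(igraph::vcount(g2))) {
    nm <- igraph::V(g2)$name[v]
    expected <- if (igraph::degree(g2, v) < 2) 0 else oracle_mcode_weight(g2, v)
    expect_equal(unname(w2[nm]), expected, tolerance = 1e-12, info = nm)
  }
})

test_that("MCODE recovers bridge-joined cliques and honours its postconditions", {
  expect_identical(mcode(igraph::make_empty_graph(0, directed = FALSE)), list())

  g <- two_cliques_bridge(6)
  mods <- mcode(g)
  expect_length(mods, 2)
  sets <- lapply(mods, `[[`, "node_ids")
  expect_true(setequal(sets[[1]], paste0("a", 1:6)) ||
                setequal(sets[[1]], paste0("b", 1:6)))
  expect_true(setequal(union(sets[[1]], sets[[2]]),
                       igraph::V(g)$name))
  expect_false(any(sets[[1]] %in% sets[[2]]))
  # complex score of a clique: density 1 times size
  expect_equal(mods[[1]]$mcode_score, 6)

  # every reported module is connected with min internal degree >= 2
  g3 <- random_named_graph(60, 0.12, seed = 31)
  for (m in mcode(g3)) {
    expect_true(igraph::is_connected(m$subgraph))
    expect_gte(min(igraph::degree(m$subgraph)), 2)
    expect_gte(length(m$node_ids), 3)
  }
})

test_that("MCODE output is invariant to node relabelling", {
  g <- two_cliques_bridge(5)
  perm <- c(7, 2, 9, 4, 5, 6, 1, 8, 3, 10)
  g2 <- igraph::permute(g, perm)
  s1 <- lapply(mcode(g), `[[`, "node_ids")
  s2 <- lapply(mcode(g2), `[[`, "node_ids")
  expect_setequal(vapply(s1, paste, "", collapse = ","),
                  vapply(s2, paste, "", collapse = ","))
})
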
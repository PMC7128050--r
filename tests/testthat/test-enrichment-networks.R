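test_that("module enrichment matches the shared enumeration oracle", {
  universe <- paste0("g", 1:10)
  sets <- list(S = paste0("g", 1:5))
  module <- c(paste0("g", 1:3), "g6")  # draws 4 from successes 5 -> overlap 3
  res <- enrich_module(module, sets, universe)
  expect_equal(res$overlap_k, 3)
  expect_equal(res$p, oracle_hyper_upper(3, 5, 4, 10), tolerance = 1e-12)

  # zero overlap sits in the p = 1 region
  res0 <- enrich_module(c("g9", "g10"), list(S = paste0("g", 1:5)), universe)
  expect_equal(res0$p, 1)

  # module equal to a small set: minimal achievable p for that configuration
  resx <- enrich_module(paste0("g", 1:3), list(S = paste0("g", 1:3)), universe)
  expect_equal(resx$p, 1 / choose(10, 3), tolerance = 1e-12)

  expect_message(enrich_module(c("g1", "zz"), sets, universe), "outside")
  expect_error(enrich_module("g1", sets, character(0)), "empty")
})

test_that("co-enrichment network matches a brute-force all-pairs scan", {
  set.seed(19)
  n_mod <- 12
  mods <- sprintf("M%02d", 1:n_mod)
  paths <- sprintf("P%02d", 1:8)
  inc <- matrix(runif(8 * n_mod) < 0.4, nrow = 8,
                dimnames = list(paths, mods))
  inc[1, ] <- inc[2, ]  # one planted co-enriched pathway pair
  enr <- do.call(rbind, lapply(paths, function(p) {
    data.frame(module_id = mods, set_name = p, p = ifelse(inc[p, ], 0.001, 0.9),
               significant = inc[p, ], stringsAsFactors = FALSE)
  }))
  net <- pathway_coenrichment_network(enr, n_mod, edge_alpha = 0.05)
  # brute force over all pathway pairs
  expected <- 0L
  present <- paths[rowSums(inc) > 0]
  for (i in seq_along(present)) for (j in seq_along(present)) {
    if (i < j) {
      mi <- mods[inc[present[i], ]]; mj <- mods[inc[present[j], ]]
      k <- length(intersect(mi, mj))
      p <- oracle_hyper_upper(k, length(mi), length(mj), n_mod)
      if (p < 0.05) expected <- expected + 1L
    }
  }
  expect_equal(nrow(net$edges), expected)
  # symmetry of the pair p-value
  if (nrow(net$edges)) {
    e1 <- net$edges[1, ]
    k <- e1$overlap
    m1 <- sum(inc[e1$pathway1, ]); m2 <- sum(inc[e1$pathway2, ])
    expect_equal(e1$p, oracle_hyper_upper(k, m2, m1, n_mod), tolerance = 1e-12)
  }
  # identical module sets of size >= 2 in a large collection give an edge
  expect_true(any((net$edges$pathway1 == "P01" & net$edges$pathway2 == "P02") |
                    (net$edges$pathway1 == "P02" & net$edges$pathway2 == "P01")))
  # edge set shrinks as the threshold tightens
  net_tight <- pathway_coenrichment_network(enr, n_mod, edge_alpha = 0.005)
  expect_lte(nrow(net_tight$edges), nrow(net$edges))
  key <- function(e) paste(e$pathway1, e$pathway2)
  expect_true(all(key(net_tight$edges) %in% key(net$edges)))
  # disjoint module sets never link
  dis <- enr[enr$set_name %in% c("P05", "P06"), ]
  dis$significant <- FALSE
  dis$significant[dis$set_name == "P05" & dis$module_id %in% mods[1:3]] <- TRUE
  dis$significant[dis$set_name == "P06" & dis$module_id %in% mods[4:6]] <- TRUE
  # overlap 0 gives p = 1, hence no edge at any real threshold
  net_dis <- pathway_coenrichment_network(dis, n_mod, edge_alpha = 0.999)
  expect_equal(nrow(net_dis$edges), 0L)
})

test_that("core pathway ranking combines module coverage and degree", {
  nodes_enr <- do.call(rbind, lapply(sprintf("P%d", 1:4), function(p) {
    data.frame(module_id = sprintf("M%d", 1:6), set_name = p,
               p = 0.001, significant = TRUE, stringsAsFactors = FALSE)
  }))
  # hub pathway P1 enriched in all modules and linked to all others;
  # P4 isolated (no significant co-module overlap)
  nodes_enr$significant[nodes_enr$set_name == "P2"] <-
    nodes_enr$module_id[nodes_enr$set_name == "P2"] %in% sprintf("M%d", 1:5)
  nodes_enr$significant[nodes_enr$set_name == "P3"] <-
    nodes_enr$module_id[nodes_enr$set_name == "P3"] %in% sprintf("M%d", 1:5)
  nodes_enr$significant[nodes_enr$set_name == "P4"] <-
    nodes_enr$module_id[nodes_enr$set_name == "P4"] == "M6"
  net <- pathway_coenrichment_network(nodes_enr, n_modules = 20,
                                      edge_alpha = 0.05)
  all_paths <- core_pathways(net, min_modules = 1, min_degree = 0)
  expect_setequal(all_paths$pathway, c("P1", "P2", "P3", "P4"))
  expect_identical(all_paths$pathway[1], "P1")
  with_deg <- core_pathways(net, min_modules = 1, min_degree = 1)
  expect_false("P4" %in% with_deg$pathway)
})

test_that("GMT writer agrees with the independent fgsea reader", {
  sets <- list(ALPHA = c("g1", "g2", "g3"), BETA = c("g9", "g4"),
               GAMMA = paste0("x", 1:7))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  via_fgsea <- fgsea::gmtPathways(path)
  expect_identical(via_fgsea, sets)
  expect_identical(read_gmt(path), sets)
})
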
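test_that("planted PPI structure meets its guarantees", {
  p <- generate_ppi(n_nodes = 30, n_planted_modules = 2, module_size = 5,
                    background_degree = 2, crosstalk_extra_edges = 4,
                    n_boundary = 3, seed = 7)
  el <- igraph::as_edgelist(p$graph)
  # two 5-node near-cliques: brute-force edge counting over the planted sets
  for (mod in p$truth$planted_modules) {
    within <- sum(el[, 1L] %in% mod & el[, 2L] %in% mod)
    expect_gte(within / choose(length(mod), 2), 0.8)
  }
  # the bridged pair carries at least the requested extra inter-module edges
  pair <- p$truth$planted_crosstalk_pairs[1L, ]
  a <- p$truth$planted_modules[[pair[1L]]]
  b <- p$truth$planted_modules[[pair[2L]]]
  expect_gte(oracle_inter_edges(el, a, b), 4)
  # simple graph: no self loops, no multi-edges
  expect_false(igraph::any_loop(p$graph))
  expect_false(igraph::any_multiple(p$graph))
})

test_that("generators are deterministic under a fixed seed", {
  p1 <- generate_ppi(n_nodes = 30, n_planted_modules = 2, module_size = 5,
                     crosstalk_extra_edges = 4, n_boundary = 3, seed = 7)
  p2 <- generate_ppi(n_nodes = 30, n_planted_modules = 2, module_size = 5,
                     crosstalk_extra_edges = 4, n_boundary = 3, seed = 7)
  expect_identical(igraph::as_edgelist(p1$graph), igraph::as_edgelist(p2$graph))
  expect_identical(igraph::E(p1$graph)$combined_score,
                   igraph::E(p2$graph)$combined_score)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_study(seed = 3, dir = d1)
  s2 <- simulate_study(seed = 3, dir = d2)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
  }
})

test_that("infeasible generator parameters raise explicit errors", {
  expect_error(generate_ppi(module_size = 2), class = "ncmod_param_error")
  expect_error(generate_ppi(n_nodes = 10, n_planted_modules = 3, module_size = 5),
               class = "ncmod_param_error")
  expect_error(generate_ppi(n_nodes = 40, n_planted_modules = 2, module_size = 5,
                            crosstalk_extra_edges = 50, n_boundary = 3),
               class = "ncmod_param_error")
  p <- generate_ppi(n_nodes = 30, n_planted_modules = 2, module_size = 5,
                    crosstalk_extra_edges = 4, n_boundary = 3, seed = 1)
  tr <- plan_regulation(p$truth, n_mirnas = 20, n_lncrnas = 8,
                        n_sponge_groups = 1, n_extra_mirnas = 2, seed = 1)
  expect_error(generate_expression(tr, n_patients_per_stage = c(low = 2, III = 5, IV = 5)),
               class = "ncmod_param_error")
  expect_error(generate_expression(tr, noise_sd = 0), class = "ncmod_param_error")
})

test_that("miRNA coupling reaches the perfect anticorrelation limit", {
  p <- generate_ppi(n_nodes = 40, n_planted_modules = 2, module_size = 5,
                    crosstalk_extra_edges = 4, n_boundary = 3, seed = 2)
  tr <- plan_regulation(p$truth, n_mirnas = 20, n_lncrnas = 8,
                        n_sponge_groups = 1, n_extra_mirnas = 4,
                        targets_per_extra = 1, seed = 2)
  ex <- generate_expression(tr, n_patients_per_stage = c(low = 20, III = 10, IV = 10),
                            coupling_mirna = 1, noise_sd = 1e-6,
                            zero_fraction = 0, seed = 2)
  # an extra planted pair has a single regulator, so its latent correlation
  # must approach -1 as the noise vanishes
  mt <- tr$regulation$mirna_target
  single <- names(which(table(mt$target_id) == 1L))
  pair <- mt[mt$target_id == single[1L], ]
  r <- cor(ex$latent$mirna[pair$regulator_id, ], ex$latent$gene[pair$target_id, ])
  expect_lt(r, -0.999)
})

test_that("interaction catalog honours planted pairs and decoy rules", {
  p <- generate_ppi(n_nodes = 40, n_planted_modules = 2, module_size = 5,
                    crosstalk_extra_edges = 4, n_boundary = 3, seed = 4)
  tr <- plan_regulation(p$truth, n_mirnas = 20, n_lncrnas = 8,
                        n_sponge_groups = 1, n_extra_mirnas = 2, seed = 4)
  ct0 <- generate_interaction_catalog(tr, n_decoy_mrna = 0, n_decoy_lnc = 0, seed = 4)
  expect_true(all(ct0$catalog$is_planted))
  expect_equal(nrow(ct0$catalog),
               nrow(tr$regulation$mirna_target) + nrow(tr$regulation$mirna_lnc))
  ct <- generate_interaction_catalog(tr, n_decoy_mrna = 30, n_decoy_lnc = 5, seed = 4)
  key <- paste(ct$catalog$regulator_id, ct$catalog$target_id)
  expect_false(any(duplicated(key)))
  expect_equal(sum(!ct$catalog$is_planted & ct$catalog$target_class == "mRNA"), 30)
  # decoys only among features with no planted coupling
  decoy <- ct$catalog[!ct$catalog$is_planted & ct$catalog$target_class == "mRNA", ]
  expect_false(any(decoy$target_id %in% tr$regulation$mirna_target$target_id))
})

test_that("survival generator matches its censoring contract", {
  x <- matrix(rnorm(600), nrow = 2,
              dimnames = list(c("f1", "f2"), sprintf("s%03d", 1:300)))
  sv0 <- generate_survival(NULL, x, censoring_rate = 0, seed = 1,
                           betas = c(f1 = 0.5))
  expect_true(all(sv0$os_event == 1L))
  sv <- generate_survival(NULL, x, censoring_rate = 0.4, seed = 1,
                          betas = c(f1 = 0.5))
  expect_lt(abs(mean(sv$os_event == 0L) - 0.4), 0.12)
  expect_error(generate_survival(NULL, x, censoring_rate = 1, betas = c(f1 = 1)),
               class = "ncmod_param_error")
})

test_that("gene sets round-trip through GMT and cover planted modules", {
  p <- generate_ppi(n_nodes = 60, n_planted_modules = 2, module_size = 6,
                    crosstalk_extra_edges = 6, n_boundary = 3, seed = 9)
  gs <- generate_gene_sets(p$truth, n_sets = 50, overlap_with_modules = 1, seed = 9)
  # full-overlap positive sets contain their module entirely
  expect_true(all(p$truth$planted_modules[[1L]] %in% gs$sets$SET_MODULE_01))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs$sets, path)
  back <- read_gmt(path)
  expect_identical(back, gs$sets)
})

test_that("every id in the synthetic truth resolves in the emitted study", {
  st <- simulate_study(seed = 11)
  tr <- st$truth
  expect_true(all(unlist(tr$planted_modules) %in% igraph::V(st$graph)$name))
  expect_true(all(unlist(tr$planted_deg_ids_per_contrast) %in% rownames(st$expr$gene)))
  reg <- tr$regulation
  expect_true(all(reg$mirna_target$regulator_id %in% rownames(st$expr$mirna)))
  expect_true(all(reg$mirna_target$target_id %in% rownames(st$expr$gene)))
  expect_true(all(reg$lncrna_gene$regulator_id %in% rownames(st$expr$lnc)))
  expect_true(all(names(reg$planted_risk_betas) %in%
                    c(rownames(st$expr$gene), rownames(st$expr$mirna),
                      rownames(st$expr$lnc))))
  expect_true(all(unlist(st$gene_sets) %in% tr$gene_ids))
  expect_setequal(st$clinical$sample_id, colnames(st$expr$gene))
})
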
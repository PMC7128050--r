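test_that("pearson correlation and p-value match the closed form", {
  x <- c(1, 2, 4, 3, 5)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_equal(pearson_with_p(x, x)$r, 1)
  set.seed(9)
  a <- rnorm(20); b <- 0.4 * a + rnorm(20)
  got <- pearson_with_p(a, b)
  r <- cor(a, b)
  tt <- r * sqrt(18 / (1 - r^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tt), 18), tolerance = 1e-10)
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)),
               class = "ncmod_degenerate_correlation")
})

test_that("shared-miRNA hypergeometric matches exhaustive enumeration", {
  # universe 10, |lnc| = 4, |gene| = 5, shared = 3:
  # [C(4,3) C(6,2) + C(4,4) C(6,1)] / C(10,5) = 66 / 252
  got <- shared_mirna_hypergeom(paste0("m", 1:4), c("m1", "m2", "m3", "x1", "x2"), 10)
  expect_equal(got$k_shared, 3)
  expect_equal(got$p, 66 / 252, tolerance = 1e-12)
  # zero overlap: P(X >= 0) = 1
  expect_equal(shared_mirna_hypergeom("a", "b", 5)$p, 1)
  # lnc set = whole universe forces maximal overlap with probability 1
  expect_equal(shared_mirna_hypergeom(paste0("m", 1:6), paste0("m", 1:3), 6)$p, 1)
  expect_error(shared_mirna_hypergeom(paste0("m", 1:7), "m1", 5), "population")
})

test_that("active miRNA edge filter enforces sign and FDR jointly", {
  set.seed(4)
  n <- 60
  mir <- rbind(m1 = rnorm(n), m2 = rnorm(n), m3 = rnorm(n))
  colnames(mir) <- sprintf("s%02d", 1:n)
  gene <- rbind(gStrongNeg = -0.9 * mir["m1", ] + rnorm(n, 0, 0.3),
                gStrongPos = 0.9 * mir["m2", ] + rnorm(n, 0, 0.3),
                gNoise = rnorm(n))
  colnames(gene) <- colnames(mir)
  catalog <- data.frame(regulator_id = c("m1", "m2", "m3", "m1"),
                        target_id = c("gStrongNeg", "gStrongPos", "gNoise", "missing"),
                        stringsAsFactors = FALSE)
  expect_message(edges <- active_mirna_edges(catalog, mir, gene), "dropped")
  expect_identical(edges$target_id, "gStrongNeg")
  tested <- attr(edges, "tested")
  expect_equal(nrow(tested), 3)
  # strong positive correlation excluded by the sign rule despite tiny p
  expect_true(tested$p_adjusted[tested$target_id == "gStrongPos"] < 1e-6)
  # BH adjustment is monotone in the raw p within the class
  ord <- order(tested$p_raw)
  expect_true(all(diff(tested$p_adjusted[ord]) >= -1e-15))
  expect_warning(empty <- active_mirna_edges(catalog[0, ], mir, gene), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("two-stage lncRNA-gene inference needs shared miRNAs, sign and FDR", {
  set.seed(6)
  n <- 80
  drv <- rnorm(n)  # shared miRNA deviation
  mir <- rbind(m1 = drv + rnorm(n, 0, 0.2), m2 = rnorm(n), m3 = rnorm(n))
  colnames(mir) <- sprintf("s%02d", 1:n)
  gene <- rbind(gA = -drv + rnorm(n, 0, 0.4), gB = rnorm(n))
  lnc <- rbind(L1 = -drv + rnorm(n, 0, 0.4), L2 = rnorm(n))
  colnames(gene) <- colnames(lnc) <- colnames(mir)
  mirna_gene <- data.frame(regulator_id = c("m1", "m2"), target_id = c("gA", "gB"),
                           edge_class = "miRNA->mRNA", stringsAsFactors = FALSE)
  mirna_lnc <- data.frame(regulator_id = c("m1", "m3"), target_id = c("L1", "L2"),
                          edge_class = "miRNA->lncRNA", stringsAsFactors = FALSE)
  out <- lncrna_gene_edges(mirna_lnc, mirna_gene, lnc, gene, hyper_alpha = 0.5)
  # only L1-gA shares a miRNA; L2 shares none with any gene and is never
  # a candidate
  cand <- attr(out, "candidates")
  expect_identical(unique(cand$regulator_id), "L1")
  expect_identical(out$regulator_id, "L1")
  expect_identical(out$target_id, "gA")
  expect_gt(out$pearson_r, 0)

  # positive-correlation candidates with weak adjusted p are excluded
  lnc_weak <- rbind(L1 = -drv * 0.05 + rnorm(n, 0, 1))
  colnames(lnc_weak) <- colnames(mir)
  out2 <- lncrna_gene_edges(mirna_lnc[1, ], mirna_gene, lnc_weak, gene,
                            hyper_alpha = 0.5, adj_alpha = 1e-6)
  expect_equal(nrow(out2), 0)
})

test_that("assembled network conserves parts and round-trips via GraphML", {
  g <- random_named_graph(15, 0.2, seed = 12)
  empty <- data.frame(regulator_id = character(0), target_id = character(0),
                      edge_class = character(0), stringsAsFactors = FALSE)
  net0 <- assemble_network(g, empty, empty)
  expect_equal(igraph::vcount(net0), igraph::vcount(g))
  expect_equal(igraph::ecount(net0), igraph::ecount(g))

  mirna_edges <- data.frame(regulator_id = c("mirA", "mirA", "mirB"),
                            target_id = c("n01", "n02", "lncX"),
                            edge_class = c("miRNA->mRNA", "miRNA->mRNA", "miRNA->lncRNA"),
                            stringsAsFactors = FALSE)
  lnc_edges <- data.frame(regulator_id = "lncX", target_id = "n01",
                          stringsAsFactors = FALSE)
  net <- assemble_network(g, mirna_edges, lnc_edges)
  expect_equal(igraph::vcount(net), igraph::vcount(g) + 3)
  expect_equal(igraph::ecount(net), igraph::ecount(g) + 4)
  classes <- igraph::V(net)$node_class
  names(classes) <- igraph::V(net)$name
  expect_equal(unname(classes[c("mirA", "lncX", "n01")]),
               c("miRNA", "lncRNA", "mRNA"))

  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path)
  back <- read_graphml(path)
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_identical(sort(igraph::E(back)$edge_class), sort(igraph::E(net)$edge_class))

  # id collisions across classes are rejected
  bad <- data.frame(regulator_id = "n01", target_id = "n02",
                    edge_class = "miRNA->mRNA", stringsAsFactors = FALSE)
  expect_error(assemble_network(g, bad, empty), "collision")
})

test_that("sign invariants hold on a full synthetic study", {
  st <- small_study(31)
  dirn <- withr::local_tempdir()
  write_study(st, dirn)
  gene <- load_and_transform(file.path(dirn, "expression_gene.tsv"), "mRNA")
  mir <- load_and_transform(file.path(dirn, "expression_mirna.tsv"), "miRNA")
  lnc <- load_and_transform(file.path(dirn, "expression_lncrna.tsv"), "lncRNA")
  cat_m <- st$catalog[st$catalog$target_class == "mRNA", ]
  cat_l <- st$catalog[st$catalog$target_class == "lncRNA", ]
  edges_m <- suppressMessages(active_mirna_edges(cat_m, mir, gene))
  expect_true(all(edges_m$pearson_r < 0))
  expect_true(all(edges_m$p_adjusted >= edges_m$p_raw - 1e-15))
  ml <- data.frame(regulator_id = cat_l$regulator_id, target_id = cat_l$target_id,
                   edge_class = "miRNA->lncRNA", stringsAsFactors = FALSE)
  edges_l <- lncrna_gene_edges(ml, edges_m, lnc, gene)
  expect_true(all(edges_l$pearson_r > 0))
  expect_true(all(edges_l$hyper_p < 0.05))
  expect_true(all(edges_l$n_shared_mirnas >= 1))
})
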
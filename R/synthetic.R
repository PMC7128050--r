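#' Generate a protein-protein interaction network with planted dense modules
#'
#' Builds an undirected simple graph consisting of `n_planted_modules`
#' near-cliques (internal edge density at least 0.8, enforced by
#' construction) embedded in a configuration-model-like random background
#' with the requested mean degree. The first half of the planted modules is
#' tagged stage III, the second half stage IV, and designated III/IV module
#' pairs are wired together with `crosstalk_extra_edges` additional bridge
#' edges so that downstream crosstalk detection has a known ground truth.
#'
#' Bridges attach only to each module's `n_boundary` designated boundary
#' nodes. Boundary genes are deliberately excluded from the planted
#' differentially-expressed sets (see [generate_expression()]), so each
#' stage's DEG-plus-neighbour subnetwork contains its own modules in full
#' while the partner module across a bridge stays out of reach; crosstalk is
#' then carried by genes that are themselves not differentially expressed.
#'
#' Every edge carries a `combined_score` attribute on the STRING 0-1000
#' scale: planted module and bridge edges score in [950, 999] and background
#' edges in [700, 999], so the default confidence cutoff of 900 thins the
#' background without touching planted structure.
#'
#' @param n_nodes total number of gene nodes.
#' @param n_planted_modules number of planted near-cliques (even; first half
#'   stage III, second half stage IV).
#' @param module_size nodes per planted module (at least 3).
#' @param background_degree mean degree of the random background.
#' @param crosstalk_extra_edges bridge edges added between each planted
#'   crosstalk module pair.
#' @param n_boundary boundary nodes per module that may receive bridges.
#' @param within_density probability of each within-module edge (>= 0.8;
#'   density is then topped up to at least 0.8 if sampling fell short).
#' @param seed integer seed; identical seeds give identical graphs.
#' @return list with `graph` (igraph, node names `g0001`, ..., edge attribute
#'   `combined_score`) and `truth` (planted modules, boundary sets, module
#'   stages, planted crosstalk pairs, planted DEG id sets, seed).
#' @export
generate_ppi <- function(n_nodes = 400, n_planted_modules = 10,
                         module_size = 8, background_degree = 4,
                         crosstalk_extra_edges = 12, n_boundary = 4,
                         within_density = 0.95, seed = 1L) {
  if (!is_count(module_size) || module_size < 3) {
    stopf("module_size must be an integer >= 3", class = "ncmod_param_error")
  }
  if (n_planted_modules * module_size > n_nodes) {
    stopf("n_planted_modules * module_size (%d) exceeds n_nodes (%d)",
          n_planted_modules * module_size, n_nodes,
          class = "ncmod_param_error")
  }
  if (n_boundary >= module_size) n_boundary <- max(1L, module_size - 2L)
  if (crosstalk_extra_edges > n_boundary^2) {
    stopf("crosstalk_extra_edges (%d) infeasible: at most %d simple bridges between %d-node boundaries",
          crosstalk_extra_edges, n_boundary^2, n_boundary,
          class = "ncmod_param_error")
  }
  if (within_density < 0.8 || within_density > 1) {
    stopf("within_density must lie in [0.8, 1]", class = "ncmod_param_error")
  }
  set.seed(as.integer(seed))

  ids <- sprintf("g%04d", seq_len(n_nodes))
  modules <- lapply(seq_len(n_planted_modules), function(i) {
    ids[((i - 1L) * module_size + 1L):(i * module_size)]
  })
  boundary <- lapply(modules, function(m) m[(module_size - n_boundary + 1L):module_size])
  core <- lapply(modules, function(m) m[seq_len(module_size - n_boundary)])
  half <- n_planted_modules %/% 2L
  module_stage <- c(rep("III", half), rep("IV", n_planted_modules - half))

  # within-module edges: sample at within_density, then top up to density
  # >= 0.8 and connectivity
  min_edges <- ceiling(0.8 * choose(module_size, 2))
  module_edges <- lapply(modules, function(m) {
    pairs <- t(utils::combn(m, 2L))
    keep <- stats::runif(nrow(pairs)) < within_density
    sel <- pairs[keep, , drop = FALSE]
    missing <- pairs[!keep, , drop = FALSE]
    need <- min_edges - nrow(sel)
    if (need > 0) {
      add <- missing[sample.int(nrow(missing), need), , drop = FALSE]
      sel <- rbind(sel, add)
      missing <- missing[!seq_len(nrow(missing)) %in% sample.int(1, 0), , drop = FALSE]
    }
    # guarantee connectivity (near-cliques at density >= 0.8 are almost
    # always connected; patch the rare exception)
    g <- igraph::graph_from_edgelist(sel, directed = FALSE)
    miss_i <- 1L
    while (igraph::components(g)$no > 1L && miss_i <= nrow(pairs)) {
      comp <- igraph::components(g)$membership
      cand <- pairs[comp[pairs[, 1L]] != comp[pairs[, 2L]], , drop = FALSE]
      sel <- rbind(sel, cand[1L, , drop = FALSE])
      g <- igraph::graph_from_edgelist(sel, directed = FALSE)
      miss_i <- miss_i + 1L
    }
    sel
  })

  # planted crosstalk pairs: module i (stage III) with module half + i
  # (stage IV), leaving the last III/IV pair unbridged as a negative control
  n_pairs <- max(0L, half - 1L)
  if (n_planted_modules >= 2L && half >= 1L && n_planted_modules - half >= 1L && n_pairs == 0L) {
    n_pairs <- 1L  # with 2 modules, bridge the single pair
  }
  pair_idx <- if (n_pairs > 0) cbind(seq_len(n_pairs), half + seq_len(n_pairs)) else
    matrix(integer(0), 0, 2)
  bridge_edges <- NULL
  if (nrow(pair_idx) > 0 && crosstalk_extra_edges > 0) {
    bridge_edges <- do.call(rbind, lapply(seq_len(nrow(pair_idx)), function(k) {
      a <- boundary[[pair_idx[k, 1L]]]
      b <- boundary[[pair_idx[k, 2L]]]
      cells <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
      sel <- cells[sample.int(nrow(cells), crosstalk_extra_edges), , drop = FALSE]
      cbind(sel$a, sel$b)
    }))
  }

  # configuration-model-like background at the requested mean degree
  degs <- stats::rpois(n_nodes, background_degree)
  if (sum(degs) %% 2L == 1L) degs[which.max(degs)] <- degs[which.max(degs)] + 1L
  bg <- igraph::simplify(igraph::sample_degseq(degs, method = "configuration"))
  bg_edges <- igraph::as_edgelist(bg, names = FALSE)
  bg_edges <- cbind(ids[bg_edges[, 1L]], ids[bg_edges[, 2L]])

  planted <- rbind(do.call(rbind, module_edges), bridge_edges)
  key <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  planted <- planted[!duplicated(key(planted)), , drop = FALSE]
  bg_edges <- bg_edges[!key(bg_edges) %in% key(planted) &
                         bg_edges[, 1L] != bg_edges[, 2L], , drop = FALSE]
  bg_edges <- bg_edges[!duplicated(key(bg_edges)), , drop = FALSE]

  all_edges <- rbind(planted, bg_edges)
  scores <- c(round(stats::runif(nrow(planted), 950, 999)),
              round(stats::runif(nrow(bg_edges), 700, 999)))
  g <- igraph::graph_from_edgelist(all_edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                            name = setdiff(ids, igraph::V(g)$name))
  igraph::E(g)$combined_score <- scores

  deg_ids <- list(
    III_vs_low = sort(unlist(core[module_stage == "III"], use.names = FALSE)),
    IV_vs_low  = sort(unlist(core[module_stage == "IV"], use.names = FALSE))
  )

  truth <- list(
    gene_ids = ids,
    planted_modules = modules,
    module_boundary = boundary,
    module_core = core,
    module_stage = module_stage,
    planted_crosstalk_pairs = pair_idx,
    planted_deg_ids_per_contrast = deg_ids,
    seed = as.integer(seed)
  )
  list(graph = g, truth = truth)
}

#' Plan the planted regulatory layer of a synthetic study
#'
#' Decides which miRNAs and lncRNAs are coupled to which genes before any
#' expression is drawn. Three kinds of planted regulators are laid out:
#' pivot miRNAs/lncRNAs whose targets sit inside both modules of a planted
#' crosstalk pair (ground truth for pivot analysis), sponge groups in which
#' a lncRNA and one or more genes share the same repressing miRNAs (ground
#' truth for two-stage lncRNA-gene inference away from the modules), and
#' extra miRNA-target pairs that populate the catalog. Per-factor hazard
#' coefficients for the survival layer are planted here as well: a few genes
#' of the first crosstalk pair carry weak risk betas while its pivot lncRNA
#' and first pivot miRNA carry strong ones, so adding the ncRNAs to the
#' module's risk model should improve survival prediction.
#'
#' @param truth truth fragment from [generate_ppi()].
#' @param n_mirnas,n_lncrnas catalog sizes for the two ncRNA classes.
#' @param pivot_mirnas_per_pair pivot miRNAs planted per crosstalk pair.
#' @param targets_per_module genes of each module targeted by each pivot.
#' @param n_sponge_groups,sponge_mirnas_per_group,sponge_genes_per_group
#'   layout of the sponge (shared-miRNA) groups outside the modules.
#' @param n_extra_mirnas,targets_per_extra additional planted miRNA-target
#'   couplings outside the modules.
#' @param gene_beta,lnc_beta,mirna_beta planted hazard coefficients.
#' @param n_beta_genes module genes of the first pair given `gene_beta`.
#' @param seed integer seed.
#' @return the truth list extended with a `regulation` element.
#' @export
plan_regulation <- function(truth, n_mirnas = 60, n_lncrnas = 30,
                            pivot_mirnas_per_pair = 4, targets_per_module = 3,
                            n_sponge_groups = 2, sponge_mirnas_per_group = 3,
                            sponge_genes_per_group = 2, n_extra_mirnas = 8,
                            targets_per_extra = 2, gene_beta = 0.2,
                            lnc_beta = 0.8, mirna_beta = 0.5,
                            n_beta_genes = 4, seed = 1L) {
  set.seed(as.integer(seed))
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirnas))
  lnc_ids <- sprintf("lnc%03d", seq_len(n_lncrnas))
  pairs <- truth$planted_crosstalk_pairs
  n_pairs <- nrow(pairs)
  need_mirnas <- n_pairs * pivot_mirnas_per_pair +
    n_sponge_groups * sponge_mirnas_per_group + n_extra_mirnas
  if (need_mirnas > n_mirnas) stopf("n_mirnas too small for the planted layout")
  if (n_pairs + n_sponge_groups > n_lncrnas) stopf("n_lncrnas too small")

  mt <- list(); ml <- list(); lg <- list()
  pivots <- list()
  mir_cursor <- 0L
  # pivot layer: per crosstalk pair, a block of miRNAs sharing the same
  # targets_per_module core genes in each module, plus one pivot lncRNA
  for (k in seq_len(n_pairs)) {
    mods <- pairs[k, ]
    core1 <- truth$module_core[[mods[1L]]]
    core2 <- truth$module_core[[mods[2L]]]
    targ <- c(core1[seq_len(min(targets_per_module, length(core1)))],
              core2[seq_len(min(targets_per_module, length(core2)))])
    mirs <- mirna_ids[mir_cursor + seq_len(pivot_mirnas_per_pair)]
    mir_cursor <- mir_cursor + pivot_mirnas_per_pair
    lnc <- lnc_ids[k]
    mt[[length(mt) + 1L]] <- expand.grid(regulator_id = mirs, target_id = targ,
                                         stringsAsFactors = FALSE)
    ml[[length(ml) + 1L]] <- data.frame(regulator_id = mirs, target_id = lnc,
                                        stringsAsFactors = FALSE)
    lg[[length(lg) + 1L]] <- data.frame(regulator_id = lnc, target_id = targ,
                                        stringsAsFactors = FALSE)
    pivots[[paste(mods, collapse = "|")]] <- c(mirs, lnc)
  }

  module_genes <- unlist(truth$planted_modules, use.names = FALSE)
  free_genes <- setdiff(truth$gene_ids, module_genes)
  # sponge layer: lncRNA + genes repressed by the same miRNAs, off-module
  sponge_lncs <- lnc_ids[n_pairs + seq_len(n_sponge_groups)]
  for (s in seq_len(n_sponge_groups)) {
    mirs <- mirna_ids[mir_cursor + seq_len(sponge_mirnas_per_group)]
    mir_cursor <- mir_cursor + sponge_mirnas_per_group
    genes <- sample(free_genes, sponge_genes_per_group)
    free_genes <- setdiff(free_genes, genes)
    mt[[length(mt) + 1L]] <- expand.grid(regulator_id = mirs, target_id = genes,
                                         stringsAsFactors = FALSE)
    ml[[length(ml) + 1L]] <- data.frame(regulator_id = mirs,
                                        target_id = sponge_lncs[s],
                                        stringsAsFactors = FALSE)
    lg[[length(lg) + 1L]] <- data.frame(regulator_id = sponge_lncs[s],
                                        target_id = genes,
                                        stringsAsFactors = FALSE)
  }
  # extra miRNA-target couplings
  for (e in seq_len(n_extra_mirnas)) {
    mir <- mirna_ids[mir_cursor + 1L]
    mir_cursor <- mir_cursor + 1L
    genes <- sample(free_genes, targets_per_extra)
    free_genes <- setdiff(free_genes, genes)
    mt[[length(mt) + 1L]] <- data.frame(regulator_id = mir, target_id = genes,
                                        stringsAsFactors = FALSE)
  }

  mirna_target <- unique(do.call(rbind, mt))
  mirna_lnc <- unique(do.call(rbind, ml))
  lncrna_gene <- unique(do.call(rbind, lg))

  betas <- numeric(0)
  if (n_pairs > 0) {
    mods1 <- pairs[1L, ]
    pool <- setdiff(c(truth$module_core[[mods1[1L]]], truth$module_core[[mods1[2L]]]),
                    mirna_target$target_id)
    beta_genes <- pool[seq_len(min(n_beta_genes, length(pool)))]
    betas <- stats::setNames(rep(gene_beta, length(beta_genes)), beta_genes)
    piv1 <- pivots[[paste(mods1, collapse = "|")]]
    betas[lnc_ids[1L]] <- lnc_beta
    betas[piv1[1L]] <- mirna_beta
  }

  truth$regulation <- list(
    mirna_ids = mirna_ids,
    lnc_ids = lnc_ids,
    mirna_target = mirna_target,
    mirna_lnc = mirna_lnc,
    lncrna_gene = lncrna_gene,
    planted_pivots = pivots,
    planted_risk_betas = betas,
    seed = as.integer(seed)
  )
  truth
}

#' Generate synthetic expression matrices with planted structure
#'
#' Expression is generated on a linear, RPKM-like positive scale as
#' `2^(log2 signal)` with additive Gaussian noise in log2 space
#' (i.e. multiplicative log-normal noise on the linear scale), so the
#' preprocessing log2 path is meaningful. Planted differentially expressed
#' genes are shifted by `deg_effect` log2 units (random sign) in their
#' contrast's stage group. Each planted miRNA-coupled target equals its
#' baseline minus `coupling_mirna` times the mean deviation of its planted
#' miRNAs plus noise; planted lncRNAs are repressed by the same miRNAs, so
#' lncRNA-gene pairs sharing miRNAs are positively correlated. The lowest
#' `zero_fraction` of each matrix's linear entries is set to exactly 0,
#' emulating an assay detection floor and exercising the zero-handling
#' path downstream.
#'
#' @param truth truth list from [plan_regulation()].
#' @param n_patients_per_stage named counts for the `low`, `III`, `IV`
#'   stage groups (each at least 3).
#' @param deg_effect log2-fold shift of planted DEGs in their stage.
#' @param coupling_mirna slope of the (negative) miRNA-target coupling.
#' @param coupling_lncrna slope of the miRNA repression of planted lncRNAs.
#' @param noise_sd residual log2 noise standard deviation (> 0).
#' @param mirna_sd standard deviation of miRNA log2 deviations.
#' @param zero_fraction fraction of entries zeroed on the linear scale.
#' @param n_extra_degs additional off-module planted DEGs per contrast.
#' @param seed integer seed.
#' @return list with linear-scale `gene`, `mirna`, `lnc` matrices, latent
#'   log2 matrices under `latent`, the `stage` factor, sample ids and the
#'   updated `truth` (extra DEGs and effect directions recorded).
#' @export
generate_expression <- function(truth,
                                n_patients_per_stage = c(low = 100, III = 70, IV = 40),
                                deg_effect = 1, coupling_mirna = 1,
                                coupling_lncrna = 1, noise_sd = 0.5,
                                mirna_sd = 1, zero_fraction = 0.02,
                                n_extra_degs = 10, seed = 1L) {
  if (any(n_patients_per_stage < 3)) {
    stopf("every stage group needs at least 3 patients",
          class = "ncmod_param_error")
  }
  if (!is.finite(coupling_mirna) || !is.finite(coupling_lncrna)) {
    stopf("couplings must be finite", class = "ncmod_param_error")
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stopf("noise_sd must be > 0", class = "ncmod_param_error")
  }
  set.seed(as.integer(seed))
  n <- sum(n_patients_per_stage)
  stage <- factor(rep(c("low", "III", "IV"), times = n_patients_per_stage[c("low", "III", "IV")]),
                  levels = c("low", "III", "IV"))
  samples <- sprintf("s%03d", seq_len(n))

  reg <- truth$regulation
  mirna_ids <- reg$mirna_ids
  lnc_ids <- reg$lnc_ids
  gene_ids <- truth$gene_ids

  # miRNA layer: per-miRNA deviations drive the couplings
  mu_m <- stats::rnorm(length(mirna_ids), 5, 1)
  dev_m <- matrix(stats::rnorm(length(mirna_ids) * n, 0, mirna_sd),
                  nrow = length(mirna_ids),
                  dimnames = list(mirna_ids, samples))
  mirna_log2 <- mu_m + dev_m

  # planted DEG bookkeeping (module cores from generate_ppi + extra
  # off-module DEGs drawn from genes without planted couplings)
  coupled_genes <- unique(reg$mirna_target$target_id)
  module_genes <- unlist(truth$planted_modules, use.names = FALSE)
  free <- setdiff(gene_ids, c(module_genes, coupled_genes))
  deg_sets <- truth$planted_deg_ids_per_contrast
  if (n_extra_degs > 0 && length(free) >= 2 * n_extra_degs) {
    extra3 <- sample(free, n_extra_degs)
    extra4 <- sample(setdiff(free, extra3), n_extra_degs)
    deg_sets$III_vs_low <- sort(c(deg_sets$III_vs_low, extra3))
    deg_sets$IV_vs_low <- sort(c(deg_sets$IV_vs_low, extra4))
  }
  truth$planted_deg_ids_per_contrast <- deg_sets

  mu_g <- stats::rnorm(length(gene_ids), 3.5, 1)
  gene_log2 <- matrix(mu_g, nrow = length(gene_ids), ncol = n,
                      dimnames = list(gene_ids, samples))
  dir3 <- stats::setNames(sample(c(-1, 1), length(deg_sets$III_vs_low), TRUE),
                          deg_sets$III_vs_low)
  dir4 <- stats::setNames(sample(c(-1, 1), length(deg_sets$IV_vs_low), TRUE),
                          deg_sets$IV_vs_low)
  gene_log2[names(dir3), stage == "III"] <-
    gene_log2[names(dir3), stage == "III"] + deg_effect * dir3
  gene_log2[names(dir4), stage == "IV"] <-
    gene_log2[names(dir4), stage == "IV"] + deg_effect * dir4
  truth$deg_direction <- list(III_vs_low = dir3, IV_vs_low = dir4)

  regulators_of <- split(reg$mirna_target$regulator_id, reg$mirna_target$target_id)
  for (gid in names(regulators_of)) {
    regs <- regulators_of[[gid]]
    gene_log2[gid, ] <- gene_log2[gid, ] -
      coupling_mirna * colMeans(dev_m[regs, , drop = FALSE])
  }
  gene_log2 <- gene_log2 + matrix(stats::rnorm(length(gene_log2), 0, noise_sd),
                                  nrow = nrow(gene_log2))

  mu_l <- stats::rnorm(length(lnc_ids), 2.5, 1)
  lnc_log2 <- matrix(mu_l, nrow = length(lnc_ids), ncol = n,
                     dimnames = list(lnc_ids, samples))
  lnc_regs <- split(reg$mirna_lnc$regulator_id, reg$mirna_lnc$target_id)
  for (lid in names(lnc_regs)) {
    regs <- lnc_regs[[lid]]
    lnc_log2[lid, ] <- lnc_log2[lid, ] -
      coupling_lncrna * colMeans(dev_m[regs, , drop = FALSE])
  }
  lnc_log2 <- lnc_log2 + matrix(stats::rnorm(length(lnc_log2), 0, noise_sd),
                                nrow = nrow(lnc_log2))

  # detection-limit zeroing: the lowest zero_fraction of entries of each
  # matrix fall below the assay floor and are reported as exactly 0
  to_linear <- function(m) {
    lin <- 2^m
    if (zero_fraction > 0) {
      lin[lin <= stats::quantile(lin, zero_fraction)] <- 0
    }
    lin
  }
  list(gene = to_linear(gene_log2), mirna = to_linear(mirna_log2),
       lnc = to_linear(lnc_log2),
       latent = list(gene = gene_log2, mirna = mirna_log2, lnc = lnc_log2),
       stage = stage, sample_ids = samples, truth = truth)
}

#' Generate the CLIP-style interaction catalog
#'
#' The catalog is the union of all planted miRNA-mRNA and miRNA-lncRNA
#' couplings with decoy pairs drawn only among features that carry no
#' planted coupling, so decoy expression correlation is null by
#' construction. Duplicates (including a decoy colliding with a planted
#' pair) are suppressed while preserving the requested decoy count.
#'
#' @param truth truth list from [plan_regulation()].
#' @param n_decoy_mrna,n_decoy_lnc decoy pair counts per target class.
#' @param seed integer seed.
#' @return list with the catalog `data.frame` (`regulator_id`, `target_id`,
#'   `target_class`, `is_planted`) and the updated `truth`.
#' @export
generate_interaction_catalog <- function(truth, n_decoy_mrna = 300,
                                         n_decoy_lnc = 60, seed = 1L) {
  set.seed(as.integer(seed))
  reg <- truth$regulation
  planted <- rbind(
    data.frame(reg$mirna_target, target_class = "mRNA", stringsAsFactors = FALSE),
    data.frame(reg$mirna_lnc, target_class = "lncRNA", stringsAsFactors = FALSE)
  )
  planted$is_planted <- TRUE

  draw_decoys <- function(n_decoy, targets, cls) {
    if (n_decoy == 0 || length(targets) == 0) return(NULL)
    got <- character(0)
    out <- NULL
    guard <- 0L
    while (length(got) < n_decoy && guard < 50L) {
      m <- sample(reg$mirna_ids, n_decoy, replace = TRUE)
      t <- sample(targets, n_decoy, replace = TRUE)
      cand <- data.frame(regulator_id = m, target_id = t,
                         target_class = cls, is_planted = FALSE,
                         stringsAsFactors = FALSE)
      k <- paste(cand$regulator_id, cand$target_id)
      pk <- paste(planted$regulator_id, planted$target_id)
      cand <- cand[!k %in% c(pk, got) & !duplicated(k), , drop = FALSE]
      got <- c(got, paste(cand$regulator_id, cand$target_id))
      out <- rbind(out, cand)
      guard <- guard + 1L
    }
    out[seq_len(min(n_decoy, nrow(out))), , drop = FALSE]
  }

  uncoupled_genes <- setdiff(truth$gene_ids, unique(reg$mirna_target$target_id))
  uncoupled_lncs <- setdiff(reg$lnc_ids, unique(reg$mirna_lnc$target_id))
  catalog <- rbind(planted,
                   draw_decoys(n_decoy_mrna, uncoupled_genes, "mRNA"),
                   draw_decoys(n_decoy_lnc, uncoupled_lncs, "lncRNA"))
  rownames(catalog) <- NULL
  truth$catalog <- catalog
  list(catalog = catalog, truth = truth)
}

#' Generate exponential proportional-hazards survival outcomes
#'
#' Event times follow an exponential proportional-hazards model whose linear
#' predictor is the planted hazard coefficients times the (mean-centred)
#' log2 expression of the corresponding factors; centring only rescales the
#' baseline hazard, so Cox coefficients estimated on the same expression
#' values recover the planted betas. Censoring is independent exponential
#' with its rate tuned by bisection so that the expected censored fraction
#' matches `censoring_rate`.
#'
#' @param truth truth list carrying `regulation$planted_risk_betas`, or
#'   `NULL` when `betas` is given directly.
#' @param module_expression log2 expression matrix (features x patients)
#'   containing at least the rows named by the betas.
#' @param censoring_rate requested censored fraction in `[0, 1)`.
#' @param baseline_scale baseline mean survival time (time units).
#' @param seed integer seed.
#' @param betas optional named hazard coefficients overriding the truth.
#' @return `data.frame` with `sample_id`, `os_time`, `os_event`.
#' @export
generate_survival <- function(truth, module_expression, censoring_rate = 0.3,
                              baseline_scale = 1500, seed = 1L, betas = NULL) {
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stopf("censoring_rate must lie in [0, 1)", class = "ncmod_param_error")
  }
  betas <- betas %||% truth$regulation$planted_risk_betas
  betas <- betas[names(betas) %in% rownames(module_expression)]
  set.seed(as.integer(seed))
  n <- ncol(module_expression)
  lp <- rep(0, n)
  if (length(betas)) {
    x <- module_expression[names(betas), , drop = FALSE]
    lp <- colSums(betas * (x - rowMeans(x)))
  }
  ev_time <- stats::rexp(n, rate = exp(lp) / baseline_scale)
  if (censoring_rate == 0) {
    return(data.frame(sample_id = colnames(module_expression),
                      os_time = ev_time, os_event = 1L,
                      stringsAsFactors = FALSE))
  }
  # bisection on the censoring rate c: E[censored] = mean(1 - exp(-c * T))
  f <- function(cc) mean(1 - exp(-cc * ev_time)) - censoring_rate
  lo <- 1e-12; hi <- 1 / min(ev_time) * 50
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi / lo < 1 + 1e-10) break
  }
  cens <- stats::rexp(n, rate = sqrt(lo * hi))
  data.frame(sample_id = colnames(module_expression),
             os_time = pmin(ev_time, cens),
             os_event = as.integer(ev_time <= cens),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic hallmark-style gene-set collection
#'
#' Half the sets (up to one per planted module) are enrichment-positive:
#' each contains at least `overlap_with_modules` of one planted module's
#' genes plus random padding. The remainder are random draws from the
#' universe, i.e. enrichment-negative.
#'
#' @param truth truth list from [generate_ppi()].
#' @param n_sets total number of gene sets.
#' @param overlap_with_modules fraction of a planted module covered by its
#'   positive set, in `[0, 1]`.
#' @param set_size_range inclusive range of set sizes.
#' @param seed integer seed.
#' @return list with the named `sets` list and the updated `truth`
#'   (`enriched_sets` maps positive set names to module indices).
#' @export
generate_gene_sets <- function(truth, n_sets = 20, overlap_with_modules = 0.8,
                               set_size_range = c(12, 25), seed = 1L) {
  if (overlap_with_modules < 0 || overlap_with_modules > 1) {
    stopf("overlap_with_modules must lie in [0, 1]", class = "ncmod_param_error")
  }
  set.seed(as.integer(seed))
  universe <- truth$gene_ids
  n_pos <- min(length(truth$planted_modules), n_sets %/% 2L)
  sets <- list()
  enriched <- integer(0)
  for (i in seq_len(n_pos)) {
    mod <- truth$planted_modules[[i]]
    k <- ceiling(overlap_with_modules * length(mod))
    size <- sample(seq(set_size_range[1L], set_size_range[2L]), 1L)
    core <- if (k > 0) sample(mod, k) else character(0)
    pad <- sample(setdiff(universe, mod), max(0L, size - k))
    nm <- sprintf("SET_MODULE_%02d", i)
    sets[[nm]] <- sort(unique(c(core, pad)))
    enriched[nm] <- i
  }
  for (j in seq_len(n_sets - n_pos)) {
    size <- sample(seq(set_size_range[1L], set_size_range[2L]), 1L)
    sets[[sprintf("SET_RANDOM_%02d", j)]] <- sort(sample(universe, size))
  }
  truth$enriched_sets <- enriched
  list(sets = sets, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [generate_ppi()], [plan_regulation()],
#' [generate_expression()], [generate_interaction_catalog()],
#' [generate_survival()] and [generate_gene_sets()] under child seeds fanned
#' out from one global seed by fixed offsets, and optionally writes the
#' study to disk in the pipeline's file formats (expression TSVs, clinical
#' TSV, STRING-dialect PPI edge list, interaction catalog TSV, GMT gene
#' sets, and a JSON sidecar recording the planted truth).
#'
#' @param seed global integer seed; identical seeds reproduce the study
#'   byte-for-byte.
#' @param dir optional output directory; created if missing.
#' @param null_study when `TRUE`, all planted effects (DEG shift, couplings,
#'   hazard betas) are zeroed, giving a dataset with no structure to find.
#' @param ppi,regulation,expression,catalog,survival,gene_sets named lists
#'   of overrides passed to the respective generators.
#' @return the study as a list (`graph`, `expr`, `latent`, `clinical`,
#'   `catalog`, `gene_sets`, `truth`, `files` when written).
#' @export
simulate_study <- function(seed = 1L, dir = NULL, null_study = FALSE,
                           ppi = list(), regulation = list(),
                           expression = list(), catalog = list(),
                           survival = list(), gene_sets = list()) {
  seed <- as.integer(seed)
  p <- do.call(generate_ppi, c(list(seed = child_seed(seed, 11L)), ppi))
  truth <- do.call(plan_regulation,
                   c(list(truth = p$truth, seed = child_seed(seed, 23L)), regulation))
  if (null_study) {
    expression$deg_effect <- 0
    expression$coupling_mirna <- 0
    expression$coupling_lncrna <- 0
    truth$regulation$planted_risk_betas <-
      truth$regulation$planted_risk_betas * 0
  }
  ex <- do.call(generate_expression,
                c(list(truth = truth, seed = child_seed(seed, 37L)), expression))
  truth <- ex$truth
  ct <- do.call(generate_interaction_catalog,
                c(list(truth = truth, seed = child_seed(seed, 53L)), catalog))
  truth <- ct$truth
  surv_expr <- rbind(ex$latent$gene, ex$latent$mirna, ex$latent$lnc)
  sv <- do.call(generate_survival,
                c(list(truth = truth, module_expression = surv_expr,
                       seed = child_seed(seed, 71L)), survival))
  gs <- do.call(generate_gene_sets,
                c(list(truth = truth, seed = child_seed(seed, 89L)), gene_sets))
  truth <- gs$truth
  truth$global_seed <- seed

  clinical <- data.frame(sample_id = ex$sample_ids,
                         stage = as.character(ex$stage),
                         os_time = sv$os_time, os_event = sv$os_event,
                         stringsAsFactors = FALSE)
  study <- list(graph = p$graph,
                expr = list(gene = ex$gene, mirna = ex$mirna, lnc = ex$lnc),
                latent = ex$latent, clinical = clinical,
                catalog = ct$catalog, gene_sets = gs$sets, truth = truth)
  if (!is.null(dir)) {
    study$files <- write_study(study, dir)
  }
  study
}

#' Write a simulated study to disk
#'
#' @param study list from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return named character vector of the files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(gene = file.path(dir, "expression_gene.tsv"),
         mirna = file.path(dir, "expression_mirna.tsv"),
         lnc = file.path(dir, "expression_lncrna.tsv"),
         clinical = file.path(dir, "clinical.tsv"),
         ppi = file.path(dir, "ppi_edges.tsv"),
         interactions = file.path(dir, "interactions.tsv"),
         gene_sets = file.path(dir, "gene_sets.gmt"),
         truth = file.path(dir, "truth.json"))
  write_expression_tsv(study$expr$gene, f[["gene"]])
  write_expression_tsv(study$expr$mirna, f[["mirna"]])
  write_expression_tsv(study$expr$lnc, f[["lnc"]])
  write_tsv(study$clinical, f[["clinical"]])
  el <- igraph::as_edgelist(study$graph)
  write_tsv(data.frame(protein1 = el[, 1L], protein2 = el[, 2L],
                       combined_score = igraph::E(study$graph)$combined_score,
                       stringsAsFactors = FALSE), f[["ppi"]])
  write_tsv(study$catalog[c("regulator_id", "target_id", "target_class")],
            f[["interactions"]])
  write_gmt(study$gene_sets, f[["gene_sets"]])
  truth <- study$truth
  truth$planted_modules <- lapply(truth$planted_modules, as.character)
  jsonlite::write_json(truth, f[["truth"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  f
}
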
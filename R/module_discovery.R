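#' Load a STRING-dialect PPI edge list at a confidence cutoff
#'
#' Edges with `combined_score` below `score_cutoff` are dropped; duplicate
#' edges and self-loops are removed; the node set is the endpoints of the
#' retained edges.
#'
#' @param x path to a TSV with columns `protein1`, `protein2`,
#'   `combined_score` (STRING 0-1000 scale), or such a `data.frame`.
#' @param score_cutoff minimum retained confidence (default 900,
#'   i.e. STRING score 0.9).
#' @return simple undirected igraph with edge attribute `combined_score`.
#' @export
load_ppi <- function(x, score_cutoff = 900) {
  df <- if (is.character(x) && length(x) == 1L) read_tsv(x) else x
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df))) {
    stopf("PPI edge list must have columns %s", paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) {
    stopf("unparseable combined_score at line(s) %s",
          paste(utils::head(which(is.na(score)) + 1L, 5L), collapse = ", "))
  }
  keep <- score >= score_cutoff & df$protein1 != df$protein2
  df <- df[keep, , drop = FALSE]
  score <- score[keep]
  key <- paste(pmin(df$protein1, df$protein2), pmax(df$protein1, df$protein2))
  first <- !duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(df$protein1[first], df$protein2[first]),
                                   directed = FALSE)
  igraph::E(g)$combined_score <- score[first]
  g
}

#' DEG-plus-neighbour connected components of a PPI network
#'
#' Induces the subgraph on the differentially expressed genes and their
#' first neighbours and returns its connected components sorted by size,
#' largest first — the maximal connected components that seed module
#' mining.
#'
#' @param ppi igraph PPI network.
#' @param degs character vector of DEG ids.
#' @return list of igraph components (induced subgraphs), sorted by
#'   decreasing node count.
#' @export
deg_subnetwork <- function(ppi, degs) {
  present <- intersect(degs, igraph::V(ppi)$name)
  if (length(present) == 0L) {
    stopf("no DEG maps onto the PPI network", class = "ncmod_empty_intersection")
  }
  nbrs <- igraph::V(ppi)$name[unique(unlist(igraph::adjacent_vertices(ppi, present)))]
  nodes <- union(present, nbrs)
  sub <- igraph::induced_subgraph(ppi, nodes)
  comp <- igraph::components(sub)
  ord <- order(tabulate(comp$membership, comp$no), decreasing = TRUE)
  lapply(ord, function(i) {
    igraph::induced_subgraph(sub, which(comp$membership == i))
  })
}

#' MCODE vertex weights
#'
#' For each vertex with degree at least `degree_cutoff`, the weight is the
#' core-clustering coefficient times the core number: the density of the
#' highest k-core of the vertex's closed neighbourhood, multiplied by that
#' core's k. Vertices below the degree cutoff weigh 0. Density is the
#' loop-free `2m / (n (n - 1))`.
#'
#' @param graph simple undirected igraph.
#' @param degree_cutoff minimum degree for a nonzero weight.
#' @return named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(graph, degree_cutoff = 2) {
  deg <- igraph::degree(graph)
  w <- stats::setNames(numeric(igraph::vcount(graph)), igraph::V(graph)$name)
  for (v in which(deg >= degree_cutoff)) {
    nb <- c(v, as.integer(igraph::neighbors(graph, v)))
    sub <- igraph::induced_subgraph(graph, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    n <- igraph::vcount(core_sub)
    dens <- if (n < 2L) 0 else 2 * igraph::ecount(core_sub) / (n * (n - 1))
    w[v] <- kmax * dens
  }
  w
}

#' MCODE-style molecular complex detection
#'
#' Three phases. (1) Vertex weighting via [mcode_vertex_weights()].
#' (2) Complex prediction: seed at the highest-weight unvisited vertex
#' (ties broken by lexicographic node id), initialize the complex with the
#' highest k-core of the seed's closed neighbourhood, then grow outward,
#' admitting an unvisited neighbour when its weight exceeds
#' `(1 - node_score_cutoff)` times the seed weight *and* it has at least
#' `k_core` links into the growing complex; growth is bounded at
#' `max_depth` steps from the seed. The connectivity condition keeps a
#' complex from leaking across a sparse bridge between two dense regions —
#' a vertex with a single link would be removed by the haircut anyway.
#' (3) Post-processing: complexes without a `k_core`-core are discarded;
#' `haircut` iteratively removes vertices with fewer than 2 links inside
#' the complex. Complexes with at least 3 nodes are returned ranked by
#' score (density times size).
#'
#' @param graph simple undirected igraph.
#' @param degree_cutoff,node_score_cutoff,k_core,max_depth,haircut,fluff
#'   MCODE parameters at their published defaults; the optional fluff stage
#'   is not implemented (`fluff = TRUE` errors).
#' @param contrast optional provenance tag stored on each module.
#' @return list of modules, each a list with `id`, `contrast`, `node_ids`
#'   (sorted), `seed`, `mcode_score`, `subgraph` (induced igraph).
#' @export
mcode <- function(graph, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core = 2, max_depth = 100, haircut = TRUE,
                  fluff = FALSE, contrast = NULL) {
  if (isTRUE(fluff)) stopf("the optional fluff stage is not implemented")
  if (igraph::vcount(graph) == 0L) return(list())
  w <- mcode_vertex_weights(graph, degree_cutoff)
  vnames <- igraph::V(graph)$name
  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, as.integer)
  visited <- logical(length(vnames))

  complexes <- list()
  repeat {
    avail <- which(!visited & w > 0)
    if (!length(avail)) break
    seed <- avail[order(-w[avail], vnames[avail])][1L]
    threshold <- (1 - node_score_cutoff) * w[seed]

    nb <- c(seed, adj[[seed]])
    nb <- nb[!visited[nb]]
    sub <- igraph::induced_subgraph(graph, nb)
    core <- igraph::coreness(sub)
    members <- match(igraph::V(sub)$name[core == max(core)], vnames)
    if (!seed %in% members) members <- union(members, seed)
    in_complex <- logical(length(vnames))
    in_complex[members] <- TRUE
    depth <- 0L
    frontier <- members
    while (length(frontier) && depth < max_depth) {
      cand <- unique(unlist(adj[frontier]))
      cand <- cand[!visited[cand] & !in_complex[cand] & w[cand] > threshold]
      if (!length(cand)) break
      links <- vapply(cand, function(u) sum(in_complex[adj[[u]]]), 0L)
      cand <- cand[links >= k_core]
      if (!length(cand)) break
      in_complex[cand] <- TRUE
      frontier <- cand
      depth <- depth + 1L
    }
    members <- which(in_complex)
    visited[members] <- TRUE

    csub <- igraph::induced_subgraph(graph, members)
    core <- igraph::coreness(csub)
    if (max(core) < k_core) next
    if (haircut) {
      csub <- igraph::induced_subgraph(csub, which(igraph::coreness(csub) >= 2))
    }
    n <- igraph::vcount(csub)
    if (n < 3L) next
    dens <- 2 * igraph::ecount(csub) / (n * (n - 1))
    complexes[[length(complexes) + 1L]] <- list(
      node_ids = sort(igraph::V(csub)$name),
      seed = vnames[seed],
      mcode_score = dens * n,
      subgraph = csub,
      contrast = contrast
    )
  }
  ord <- order(vapply(complexes, `[[`, 0, "mcode_score"), decreasing = TRUE)
  complexes <- complexes[ord]
  for (i in seq_along(complexes)) {
    complexes[[i]]$id <- paste0(if (!is.null(contrast)) paste0(contrast, "_") else "M",
                                sprintf("%02d", i))
  }
  complexes
}

#' Discover modules for one stage contrast
#'
#' Maps the DEG set onto the PPI, extracts the DEG-plus-neighbour
#' components, and runs [mcode()] on every component of at least 3 nodes.
#'
#' @param ppi igraph PPI network.
#' @param degs character vector of DEG ids.
#' @param contrast provenance tag (`"III"` or `"IV"`).
#' @param ... passed on to [mcode()].
#' @return list of modules as in [mcode()], ranked by score across
#'   components.
#' @export
discover_modules <- function(ppi, degs, contrast = NULL, ...) {
  comps <- deg_subnetwork(ppi, degs)
  mods <- unlist(lapply(comps, function(cmp) {
    if (igraph::vcount(cmp) < 3L) return(list())
    mcode(cmp, contrast = contrast, ...)
  }), recursive = FALSE)
  ord <- order(vapply(mods, `[[`, 0, "mcode_score"), decreasing = TRUE)
  mods <- mods[ord]
  for (i in seq_along(mods)) {
    mods[[i]]$id <- paste0(if (!is.null(contrast)) paste0(contrast, "_") else "M",
                           sprintf("%02d", i))
  }
  mods
}
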
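# Core-network construction and graph-level analysis: statistics, random
# baselines, seasonal subnetworks, MCODE modules, edge-betweenness
# modularity, and hub/connector classification. Graphs are igraph objects.

#' Build an igraph network from an association table
#'
#' @param assoc data.frame with node_a, node_b and edge attributes
#' @param node_meta optional data.frame keyed by `node` with attributes
#'   (kind, domain, size_fraction, season, abundance)
#' @return a simple undirected igraph
#' @export
build_network <- function(assoc, node_meta = NULL) {
  g <- igraph::graph_from_data_frame(assoc, directed = FALSE)
  if (!is.null(node_meta)) {
    idx <- match(igraph::V(g)$name, node_meta$node)
    for (col in setdiff(names(node_meta), "node")) {
      g <- igraph::set_vertex_attr(g, col, value = node_meta[[col]][idx])
    }
  }
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Filter an association table to the core network
#'
#' Keeps edges with |LS| > `ls_min`, Spearman |rho| > `rho_min` and
#' Bonferroni-adjusted q < `q_max`; nodes with no surviving edge are
#' dropped, so the core OTUs are exactly the OTUs incident to surviving
#' edges.
#'
#' @param assoc an `assoc_table` (post indirect-edge removal)
#' @param ls_min,rho_min,q_max core cut-offs
#' @param node_meta optional node attribute data.frame (see
#'   [build_network()])
#' @return igraph core network
#' @export
filter_core <- function(assoc, ls_min = 0.7, rho_min = 0.7, q_max = 0.001,
                        node_meta = NULL) {
  keep <- abs(assoc$ls) > ls_min & !is.na(assoc$spearman) &
    abs(assoc$spearman) > rho_min & assoc$q < q_max
  build_network(assoc[keep, , drop = FALSE], node_meta)
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership ==
                                      which.max(comp$csize)))
}

#' Whole-network statistics
#'
#' Density E/(N(N-1)/2); diameter and average shortest-path length on the
#' largest connected component; mean local clustering coefficient (nodes
#' with degree < 2 contribute 0); exact maximal-clique enumeration; and the
#' modularity of the best edge-betweenness (Girvan-Newman) partition.
#'
#' @param g igraph with at least 2 nodes
#' @return data.frame with one row: n_nodes, n_edges, diameter, density,
#'   average_degree, average_path_length, average_clustering,
#'   largest_clique_size, largest_clique_count, modularity
#' @export
network_stats <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("network_stats needs at least 2 nodes")
  m <- igraph::ecount(g)
  lcc <- largest_component(g)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  mod <- if (m >= 1) girvan_newman_modularity(g)$Q else NA_real_
  data.frame(
    n_nodes = n, n_edges = m,
    diameter = if (m >= 1) igraph::diameter(lcc) else NA_real_,
    density = igraph::edge_density(g),
    average_degree = 2 * m / n,
    average_path_length = if (m >= 1) igraph::mean_distance(lcc) else
      NA_real_,
    average_clustering = mean(cl),
    largest_clique_size = igraph::clique_num(g),
    largest_clique_count = length(igraph::largest_cliques(g)),
    modularity = mod)
}

#' Per-node centrality metrics
#'
#' @param g igraph
#' @return data.frame: node, degree, betweenness (normalized, in \[0, 1\]),
#'   closeness (normalized, per reachable component), clustering (local, 0
#'   for degree < 2)
#' @export
node_metrics <- function(g) {
  deg <- igraph::degree(g)
  btw <- if (igraph::vcount(g) > 2) {
    igraph::betweenness(g, normalized = TRUE)
  } else setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  clo <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  clo[!is.finite(clo)] <- NA_real_
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  data.frame(node = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
             degree = as.numeric(deg), betweenness = as.numeric(btw),
             closeness = as.numeric(clo), clustering = cl,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random-graph baselines matched to a network's size
#'
#' Erdos-Renyi G(n, m); Watts-Strogatz small-world (ring lattice with
#' rewiring, edge count matched exactly by adding/removing random edges);
#' Barabasi-Albert preferential attachment (edge count matched as closely
#' as the model allows, then adjusted to the exact count).
#'
#' @param n_nodes,n_edges target size
#' @param model "er", "ws" or "ba"
#' @param params list: `p_rewire` (WS, default 0.05), `power` (BA, default 1)
#' @param seed integer seed
#' @return igraph
#' @export
random_baseline <- function(n_nodes, n_edges, model = c("er", "ws", "ba"),
                            params = list(), seed = 1L) {
  model <- match.arg(model)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) stop("infeasible edge count for ", n_nodes,
                                " nodes")
  set.seed(seed)
  match_edges <- function(g, m) {
    while (igraph::ecount(g) > m) {
      g <- igraph::delete_edges(g, sample(igraph::ecount(g), 1))
    }
    while (igraph::ecount(g) < m) {
      cand <- sample(n_nodes, 2)
      if (cand[1] != cand[2] &&
          !igraph::are_adjacent(g, cand[1], cand[2])) {
        g <- igraph::add_edges(g, cand)
      }
    }
    g
  }
  switch(model,
    er = igraph::sample_gnm(n_nodes, n_edges),
    ws = {
      p <- params$p_rewire %||% 0.05
      nei <- max(1, floor(n_edges / n_nodes))
      g <- igraph::simplify(igraph::sample_smallworld(1, n_nodes, nei, p))
      match_edges(g, n_edges)
    },
    ba = {
      k <- max(1, round(n_edges / n_nodes))
      g <- igraph::sample_pa(n_nodes, power = params$power %||% 1, m = k,
                             directed = FALSE)
      match_edges(igraph::simplify(g), n_edges)
    })
}

#' Seasonal subnetwork
#'
#' Induced subgraph on the OTU nodes whose annotated best season equals the
#' requested season; environmental nodes are always excluded.
#'
#' @param g igraph whose vertices carry `kind` (otu/env) attributes
#' @param seasons named character vector, node id -> season (or "none");
#'   if `NULL`, the vertex attribute `season` is used
#' @param season requested season
#' @return induced igraph
#' @export
seasonal_subnetwork <- function(g, seasons = NULL, season) {
  if (!season %in% c("winter", "spring", "summer", "autumn")) {
    stop("unknown season: ", season)
  }
  nm <- igraph::V(g)$name
  lab <- if (!is.null(seasons)) unname(seasons[nm]) else igraph::V(g)$season
  kind <- igraph::V(g)$kind %||% rep("otu", length(nm))
  kind[is.na(kind)] <- "env"
  keep <- which(kind == "otu" & !is.na(lab) & lab == season)
  igraph::induced_subgraph(g, keep)
}

# core-clustering weight of each vertex: k of the highest k-core of its
# closed neighborhood times that core's density
mcode_vertex_weights <- function(g) {
  vapply(seq_len(igraph::vcount(g)), function(v) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    kc <- igraph::coreness(sub)
    kmax <- max(kc)
    core <- igraph::induced_subgraph(sub, which(kc == kmax))
    nv <- igraph::vcount(core)
    dens <- if (nv < 2) 0 else igraph::ecount(core) / (nv * (nv - 1) / 2)
    kmax * dens
  }, 0)
}

#' MCODE module detection
#'
#' Stages: (1) each vertex is weighted by the density of the highest k-core
#' of its closed neighborhood times that core's k; (2) complexes grow from
#' the highest-weight unassigned seed, admitting the seed's neighbors whose
#' weight is at least (1 - vwp) times the seed weight; (3) haircut: the
#' complex is reduced to its 2-core (members with fewer than two
#' within-module edges are removed iteratively). The module score is the
#' induced subgraph's density times its node count; modules with
#' score > `score_min` are flagged "main". Modules are reported sorted by
#' decreasing score.
#'
#' @param g simple undirected igraph
#' @param vwp vertex weight percentage (admission tolerance)
#' @param score_min threshold above which a module is a "main" module
#' @return list of modules, each a list with `nodes`, `score`, `n_nodes`,
#'   `n_edges`, `main`, and `season_majority` (if a season vertex attribute
#'   exists)
#' @export
mcode_modules <- function(g, vwp = 0.2, score_min = 4.0) {
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) return(list())
  w <- mcode_vertex_weights(g)
  assigned <- rep(FALSE, n)
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))
  modules <- list()
  # canonical seed order: weight, then degree, then summed neighbor weight
  # (label-independent invariants, so relabeling a graph cannot reorder
  # structurally distinct seeds)
  deg <- igraph::degree(g)
  nbw <- vapply(seq_len(n), function(v) {
    sum(w[as.integer(igraph::neighbors(g, v))])
  }, 0)
  for (seed in order(-w, -deg, -nbw)) {
    if (assigned[seed]) next
    nb <- as.integer(igraph::neighbors(g, seed))
    cand <- nb[!assigned[nb] & w[nb] >= (1 - vwp) * w[seed]]
    members <- c(seed, cand)
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    # haircut: iterative 2-core
    kc <- igraph::coreness(sub)
    keep <- which(kc >= 2)
    if (length(keep) < 2) next
    sub <- igraph::induced_subgraph(sub, keep)
    ids <- match(igraph::V(sub)$name, nm)
    assigned[ids] <- TRUE
    nv <- igraph::vcount(sub); ne <- igraph::ecount(sub)
    dens <- ne / (nv * (nv - 1) / 2)
    season_majority <- NA_character_
    if ("season" %in% igraph::vertex_attr_names(sub)) {
      ss <- igraph::V(sub)$season
      ss <- ss[!is.na(ss) & ss != "none"]
      if (length(ss)) {
        season_majority <- names(sort(table(ss), decreasing = TRUE))[1]
      }
    }
    modules[[length(modules) + 1]] <- list(
      nodes = igraph::V(sub)$name, score = dens * nv, n_nodes = nv,
      n_edges = ne, main = dens * nv > score_min,
      season_majority = season_majority)
  }
  modules[order(-vapply(modules, `[[`, 0, "score"))]
}

#' Best edge-betweenness (Girvan-Newman) partition and its modularity
#'
#' Iteratively removes the highest-edge-betweenness edge, tracks the
#' component partitions along the way, and returns the partition maximizing
#' Newman-Girvan modularity Q.
#'
#' @param g igraph with at least one edge
#' @return list with `partition` (membership vector) and `Q`
#' @export
girvan_newman_modularity <- function(g) {
  if (igraph::ecount(g) < 1) stop("needs at least one edge")
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL)
  list(partition = igraph::membership(cl), Q = max(cl$modularity))
}

#' Classify central OTUs as hubs or connectors
#'
#' Hubs: degree >= 24, betweenness >= 0.03 and closeness > 0.3. Connectors:
#' degree <= 5, betweenness >= 0.03, closeness > 0.2 and not a hub. Degree
#' and betweenness thresholds are inclusive so that published tables whose
#' statistics are printed at two decimals satisfy their own rule.
#'
#' @param metrics data.frame from [node_metrics()] (node, degree,
#'   betweenness, closeness)
#' @param hub list of hub thresholds (degree, betweenness, closeness)
#' @param connector list of connector thresholds
#' @return data.frame: node, class ("hub", "connector" or "none")
#' @export
classify_central <- function(metrics,
                             hub = list(degree = 24, betweenness = 0.03,
                                        closeness = 0.3),
                             connector = list(degree = 5, betweenness = 0.03,
                                              closeness = 0.2)) {
  is_hub <- metrics$degree >= hub$degree &
    metrics$betweenness >= hub$betweenness &
    metrics$closeness > hub$closeness
  is_conn <- !is_hub & metrics$degree <= connector$degree &
    metrics$betweenness >= connector$betweenness &
    metrics$closeness > connector$closeness
  is_hub[is.na(is_hub)] <- FALSE
  is_conn[is.na(is_conn)] <- FALSE
  data.frame(node = metrics$node,
             class = ifelse(is_hub, "hub",
                            ifelse(is_conn, "connector", "none")),
             stringsAsFactors = FALSE)
}
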
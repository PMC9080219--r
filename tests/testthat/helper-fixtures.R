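# shared fixtures, all built in code

make_table <- function(counts, domain = "bacteria", fraction = "pico",
                       depth = NA_integer_, start_year = 2004) {
  colnames(counts) <- month_stamps(ncol(counts), start_year)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("b_%05d", seq_len(nrow(counts)))
  }
  count_table(counts, domain, fraction, depth)
}

# two k-cliques joined by one bridge edge (bridge between vertex k and k+1)
two_cliques <- function(k) {
  el <- rbind(t(combn(seq_len(k), 2)), t(combn(k + seq_len(k), 2)),
              c(k, k + 1))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# published reference centrality statistics of hub and connector taxa
# (degree, betweenness centrality, closeness centrality at 2 d.p.)
published_hubs <- data.frame(
  node = c("en_00092", "en_00119", "bp_000037", "bp_000039", "bn_000039",
           "bn_000037", "bp_000059", "ep_00070", "bn_000059", "bn_000102",
           "bp_000193", "bn_000170", "bn_000226"),
  degree = c(42, 50, 45, 29, 42, 40, 24, 40, 24, 26, 37, 59, 60),
  betweenness = c(0.04, 0.03, 0.08, 0.12, 0.17, 0.05, 0.09, 0.04, 0.03,
                  0.03, 0.03, 0.06, 0.06),
  closeness = c(0.42, 0.42, 0.43, 0.41, 0.44, 0.42, 0.40, 0.42, 0.40, 0.38,
                0.40, 0.44, 0.43),
  stringsAsFactors = FALSE)

published_connectors <- data.frame(
  node = c("bp_000001", "bp_000002", "bp_000004", "bp_000007", "bp_000008",
           "bn_000008", "en_00059", "bn_000020", "en_00161", "bn_000018",
           "bn_000054", "bn_000062", "bn_000077", "bn_000112", "bn_000156",
           "bn_000281", "bn_000221", "ep_00269"),
  degree = c(5, 2, 3, 3, 3, 5, 4, 3, 4, 5, 4, 3, 3, 4, 4, 4, 5, 2),
  betweenness = c(0.05, 0.40, 0.15, 0.60, 0.15, 0.03, 0.05, 0.60, 0.80,
                  0.04, 0.14, 0.55, 0.17, 0.53, 0.14, 0.16, 0.05, 1.00),
  closeness = c(0.30, 0.56, 0.63, 0.71, 0.63, 0.27, 0.26, 0.67, 0.75, 0.24,
                0.40, 0.50, 0.32, 0.48, 0.40, 0.44, 0.30, 1.00),
  stringsAsFactors = FALSE)

# exhaustive LS oracle: max |segment product-sum| over all contiguous
# subintervals and alignment offsets, divided by the full length
brute_force_ls <- function(x, y, max_delay = 0) {
  n <- length(x)
  best <- 0
  for (d in -max_delay:max_delay) {
    if (d >= 0) { xx <- x[seq_len(n - d)]; yy <- y[seq_len(n - d) + d] }
    else        { xx <- x[seq_len(n + d) - d]; yy <- y[seq_len(n + d)] }
    z <- xx * yy
    cs <- c(0, cumsum(z))
    for (s in seq_along(z)) {
      for (t in s:length(z)) {
        v <- cs[t + 1] - cs[s]
        if (abs(v) > abs(best)) best <- v
      }
    }
  }
  best / n
}

# maximum modularity over every partition of <= 8 nodes (brute force)
brute_force_modularity <- function(g) {
  n <- igraph::vcount(g)
  parts <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      parts[[length(parts) + 1]] <<- pref
      return()
    }
    for (v in seq_len(mx + 1)) rec(c(pref, v), max(mx, v))
  }
  rec(integer(0), 0L)
  max(vapply(parts, function(m) igraph::modularity(g, m), 0))
}
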
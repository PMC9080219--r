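# Detection and removal of environmentally driven OTU-OTU associations,
# using the intersection of four criteria evaluated on (OTU, OTU,
# environmental variable) triplets: sign pattern, interval overlap,
# interaction information, and the data processing inequality.

#' Configuration for indirect-edge detection
#'
#' @param overlap_threshold minimum triple-interval overlap, percent
#' @param n_bins equal-frequency bins for discretization; default
#'   `ceiling(1 + log2(n))`
#' @param n_perm permutations for the interaction-information test
#' @param alpha significance level of the interaction-information test
#' @param seed integer seed
#' @return an `ended_config` list
#' @export
ended_config <- function(overlap_threshold = 60, n_bins = NULL, n_perm = 100,
                         alpha = 0.05, seed = 1L) {
  structure(list(overlap_threshold = overlap_threshold, n_bins = n_bins,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed)), class = "ended_config")
}

#' Enumerate (OTU, OTU, environment) triplets
#'
#' One triplet per OTU-OTU edge and environmental variable to which both
#' OTUs are also connected in the association table. OTU-OTU edges with no
#' such variable are never candidates for removal.
#'
#' @param assoc an `assoc_table` (or data.frame with node_a, node_b, kind)
#' @param env_vars environmental node ids; defaults to the table's
#'   `env_vars` attribute
#' @return data.frame with columns `a`, `b`, `env` (one row per triplet)
#' @export
enumerate_triplets <- function(assoc, env_vars = NULL) {
  env_vars <- env_vars %||% attr(assoc, "env_vars")
  if (is.null(env_vars)) stop("env_vars not given and not found on assoc")
  oo <- assoc[assoc$kind == "otu-otu", , drop = FALSE]
  oe <- assoc[assoc$kind == "otu-env", , drop = FALSE]
  # map otu -> set of connected env vars
  otu_of <- ifelse(oe$node_a %in% env_vars, oe$node_b, oe$node_a)
  env_of <- ifelse(oe$node_a %in% env_vars, oe$node_a, oe$node_b)
  conn <- split(env_of, otu_of)
  rows <- lapply(seq_len(nrow(oo)), function(i) {
    shared <- intersect(conn[[oo$node_a[i]]] %||% character(0),
                        conn[[oo$node_b[i]]] %||% character(0))
    if (length(shared) == 0) return(NULL)
    data.frame(a = oo$node_a[i], b = oo$node_b[i], env = shared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(a = character(), b = character(),
                                      env = character())
  rownames(out) <- NULL
  out
}

#' Sign-pattern criterion
#'
#' An OTU-OTU association is consistent with environmental driving when its
#' sign equals the product of the two OTU-environment association signs.
#'
#' @param sign_ab,sign_ae,sign_be association signs ("+"/"-" or +-1)
#' @return logical flag (vectorized)
#' @export
sign_pattern <- function(sign_ab, sign_ae, sign_be) {
  num <- function(s) if (is.character(s)) ifelse(s == "+", 1, -1) else sign(s)
  num(sign_ab) == num(sign_ae) * num(sign_be)
}

#' Interval-overlap criterion
#'
#' Percentage of the OTU-OTU association interval covered by the
#' intersection of all three association intervals (month positions on the
#' shared axis).
#'
#' @param ab,ae,be length-2 integer vectors `c(start, stop)`, inclusive
#' @param threshold_pct minimum overlap percentage for the flag
#' @return list with `overlap_pct` and `flag`
#' @export
interval_overlap <- function(ab, ae, be, threshold_pct = 60) {
  len_ab <- ab[2] - ab[1] + 1
  if (len_ab < 1) stop("empty OTU-OTU association interval")
  lo <- max(ab[1], ae[1], be[1])
  hi <- min(ab[2], ae[2], be[2])
  inter <- max(0, hi - lo + 1)
  pct <- 100 * inter / len_ab
  list(overlap_pct = pct, flag = pct >= threshold_pct)
}

# equal-frequency discretization into n_bins (rank-based; deterministic)
discretize_series <- function(x, n_bins) {
  if (length(unique(x)) < 2) stop("too few distinct values to bin")
  n <- length(x)
  as.integer(ceiling(rank(x, ties.method = "first") * n_bins / n))
}

# plug-in mutual information (bits) of two discretized series
mi_disc <- function(a, b, n_bins) {
  n <- length(a)
  joint <- tabulate(a + n_bins * (b - 1L), n_bins * n_bins) / n
  pa <- tabulate(a, n_bins) / n
  pb <- tabulate(b, n_bins) / n
  pp <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / pp[nz]))
}

# conditional mutual information MI(a;b | e) in bits, via the 3-way joint
cmi_disc <- function(a, b, e, n_bins) {
  n <- length(a)
  j3 <- tabulate(a + n_bins * (b - 1L) + n_bins * n_bins * (e - 1L),
                 n_bins^3)
  dim(j3) <- c(n_bins, n_bins, n_bins)
  pabe <- j3 / n
  pbe <- colSums(pabe)                       # sum over a -> [b, e]
  pae <- colSums(aperm(pabe, c(2, 1, 3)))    # sum over b -> [a, e]
  pe <- colSums(pbe)                         # -> [e]
  num <- pabe * rep(pe, each = n_bins * n_bins)
  den <- array(0, dim(pabe))
  for (k in seq_len(n_bins)) den[, , k] <- outer(pae[, k], pbe[, k])
  nz <- pabe > 0
  sum(pabe[nz] * log2(num[nz] / den[nz]))
}

#' Interaction-information criterion
#'
#' II = MI(A;B|E) - MI(A;B) on equal-frequency-discretized series; negative
#' II means the environmental variable explains (part of) the A-B
#' dependence (redundancy). Significance of negative II is assessed by
#' permuting the environmental series.
#'
#' @param a,b,e aligned numeric series over the shared months
#' @param n_bins bins (default `ceiling(1 + log2(n))`, >= 2)
#' @param n_perm permutations
#' @param alpha significance level
#' @param seed integer seed
#' @return list with `ii`, `mi_ab`, `cmi_ab_given_e`, `ii_p`, `flag`
#' @export
interaction_information <- function(a, b, e, n_bins = NULL, n_perm = 100,
                                    alpha = 0.05, seed = 1L) {
  n <- length(a)
  n_bins <- n_bins %||% ceiling(1 + log2(n))
  if (n_bins < 2) stop("n_bins must be >= 2")
  da <- discretize_series(a, n_bins)
  db <- discretize_series(b, n_bins)
  de <- discretize_series(e, n_bins)
  r <- ii_perm_cpp(da, db, de, n_bins, n_perm, as.numeric(seed))
  list(ii = r$ii, mi_ab = r$mi_ab, cmi_ab_given_e = r$cmi, ii_p = r$p,
       flag = (r$ii < 0) && (r$p < alpha))
}

#' Data-processing-inequality criterion
#'
#' Flags the triplet when MI(A;B) <= min(MI(A;E), MI(B;E)), the ordering
#' expected when A and B interact only through E.
#'
#' @inheritParams interaction_information
#' @return list with `flag`, `mi_ab`, `mi_ae`, `mi_be`
#' @export
data_processing_inequality <- function(a, b, e, n_bins = NULL) {
  n <- length(a)
  n_bins <- n_bins %||% ceiling(1 + log2(n))
  da <- discretize_series(a, n_bins)
  db <- discretize_series(b, n_bins)
  de <- discretize_series(e, n_bins)
  mi_ab <- mi_disc(da, db, n_bins)
  mi_ae <- mi_disc(da, de, n_bins)
  mi_be <- mi_disc(db, de, n_bins)
  list(flag = mi_ab <= min(mi_ae, mi_be) + 1e-12,
       mi_ab = mi_ab, mi_ae = mi_ae, mi_be = mi_be)
}

#' Remove environmentally driven OTU-OTU associations
#'
#' An OTU-OTU edge is removed iff at least one of its triplets is flagged by
#' all four criteria (sign pattern, interval overlap, interaction
#' information, data processing inequality). OTU-environment edges are never
#' removed. The criteria are evaluated lazily (cheapest first); fields of
#' criteria that were not reached are `NA` in the report.
#'
#' @param assoc an `assoc_table` restricted to the significant network
#' @param series OTU x month abundance matrix (raw scale, same axis)
#' @param env `env_series` data.frame or variables x months matrix
#' @param config an [ended_config()]
#' @return list with `associations` (edges kept), `removed` (data.frame of
#'   removed OTU-OTU edges with the deciding variable), and `report` (one
#'   row per evaluated triplet)
#' @export
remove_indirect <- function(assoc, series, env, config = ended_config()) {
  stopifnot(inherits(config, "ended_config"))
  env_mat <- if (inherits(env, "env_series") || is.data.frame(env)) {
    env_matrix(env)
  } else as.matrix(env)
  full <- rbind(as.matrix(series), env_mat)
  n <- ncol(full)
  n_bins <- config$n_bins %||% ceiling(1 + log2(n))
  disc <- t(apply(full, 1, discretize_series, n_bins = n_bins))

  triplets <- enumerate_triplets(assoc)
  nt <- nrow(triplets)
  edge_key <- function(a, b) paste(a, b, sep = "|")

  # per-edge lookups as plain vectors (node_a < node_b in the table)
  akey <- edge_key(assoc$node_a, assoc$node_b)
  sign_of <- setNames(assoc$sign, akey)
  sa_of <- setNames(assoc$start_a, akey)
  ea_of <- setNames(assoc$stop_a, akey)

  k_ab <- edge_key(pmin(triplets$a, triplets$b), pmax(triplets$a, triplets$b))
  k_ae <- edge_key(pmin(triplets$a, triplets$env),
                   pmax(triplets$a, triplets$env))
  k_be <- edge_key(pmin(triplets$b, triplets$env),
                   pmax(triplets$b, triplets$env))

  sp <- sign_pattern(sign_of[k_ab], sign_of[k_ae], sign_of[k_be])
  len_ab <- ea_of[k_ab] - sa_of[k_ab] + 1
  lo <- pmax(sa_of[k_ab], sa_of[k_ae], sa_of[k_be])
  hi <- pmin(ea_of[k_ab], ea_of[k_ae], ea_of[k_be])
  overlap_pct <- unname(100 * pmax(0, hi - lo + 1) / pmax(1, len_ab))
  ov <- overlap_pct >= config$overlap_threshold
  sp <- unname(sp)

  # mutual information cache over node pairs (triplet-demanded only)
  mi_cache <- new.env(parent = emptyenv())
  mi_of <- function(u, v) {
    key <- edge_key(min(u, v), max(u, v))
    got <- mi_cache[[key]]
    if (is.null(got)) {
      got <- mi_disc(disc[u, ], disc[v, ], n_bins)
      mi_cache[[key]] <- got
    }
    got
  }

  mi_ab <- mi_ae <- mi_be <- ii <- ii_p <- rep(NA_real_, nt)
  dpi <- ii_flag <- rep(NA, nt)
  removed_flag <- rep(FALSE, nt)
  removed <- list()
  removed_keys <- character(0)
  for (i in seq_len(nt)) {
    if (!isTRUE(sp[i]) || !isTRUE(ov[i])) next
    a <- triplets$a[i]; b <- triplets$b[i]; e <- triplets$env[i]
    key <- k_ab[i]
    if (key %in% removed_keys) next
    mi_ab[i] <- mi_of(a, b); mi_ae[i] <- mi_of(a, e); mi_be[i] <- mi_of(b, e)
    dpi[i] <- mi_ab[i] <= min(mi_ae[i], mi_be[i]) + 1e-12
    if (!isTRUE(dpi[i])) next
    r <- ii_perm_cpp(disc[a, ], disc[b, ], disc[e, ], n_bins, config$n_perm,
                     as.numeric(child_seed(config$seed, i)))
    ii[i] <- r$ii
    ii_p[i] <- r$p
    ii_flag[i] <- (ii[i] < 0) && (ii_p[i] < config$alpha)
    if (isTRUE(ii_flag[i])) {
      removed_flag[i] <- TRUE
      removed_keys <- c(removed_keys, key)
      removed[[length(removed) + 1]] <-
        data.frame(node_a = min(a, b), node_b = max(a, b), env = e,
                   stringsAsFactors = FALSE)
    }
  }
  report <- data.frame(
    a = triplets$a, b = triplets$b, env = triplets$env,
    sign_pattern = sp, overlap_pct = overlap_pct, overlap = ov,
    mi_ab = mi_ab, mi_ae = mi_ae, mi_be = mi_be, dpi = dpi,
    ii = ii, ii_p = ii_p, ii_flag = ii_flag, removed = removed_flag,
    stringsAsFactors = FALSE)
  keep_key <- !(edge_key(assoc$node_a, assoc$node_b) %in% removed_keys &
                  assoc$kind == "otu-otu")
  out <- assoc[keep_key, , drop = FALSE]
  rownames(out) <- NULL
  for (at in c("n_tests", "env_vars", "months", "normalization")) {
    attr(out, at) <- attr(assoc, at)
  }
  class(out) <- class(assoc)
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(node_a = character(), node_b = character(), env = character())
  message(sprintf("indirect-edge stage: %d OTU-OTU edges in >=1 triplet / %d triplets flagged / %d edges removed",
                  length(unique(k_ab)), sum(removed_flag), nrow(removed)))
  list(associations = out, removed = removed, report = report)
}
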
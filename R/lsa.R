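# Local similarity analysis: normalization, the LS dynamic program (via
# compiled code), theoretical and permutation significance, Spearman
# correlation, and the all-pairs association table with a mixed
# theoretical/permutation strategy and Bonferroni correction.

#' LSA configuration
#'
#' @param max_delay maximum alignment delay in months (contemporaneous
#'   associations by default)
#' @param n_perm permutations for the confirmation test (>= 99)
#' @param screen_alpha theoretical-p screening level for the mixed strategy
#' @param normalization one of `"median_mad"`, `"zscore"`, `"rank_normal"`
#' @param seed integer seed
#' @return an `lsa_config` list
#' @export
lsa_config <- function(max_delay = 0, n_perm = 1000, screen_alpha = 0.05,
                       normalization = c("median_mad", "zscore",
                                         "rank_normal"), seed = 1L) {
  stopifnot(n_perm >= 99, screen_alpha > 0, screen_alpha < 1, max_delay >= 0)
  structure(list(max_delay = as.integer(max_delay),
                 n_perm = as.integer(n_perm), screen_alpha = screen_alpha,
                 normalization = match.arg(normalization),
                 seed = as.integer(seed)), class = "lsa_config")
}

#' Normalize a series for local similarity analysis
#'
#' `median_mad`: (x - median) / MAD with MAD = median(|x - median|) (the raw
#' median absolute deviation, no consistency constant). `zscore`:
#' (x - mean) / population SD. `rank_normal`: average ranks mapped through
#' the standard normal quantile function, rank/(n + 1).
#'
#' @param x numeric series, length >= 3
#' @param method normalization method
#' @return normalized numeric vector
#' @export
normalize_series <- function(x, method = c("median_mad", "zscore",
                                           "rank_normal")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3) stop("series must have length >= 3")
  switch(method,
    median_mad = {
      m <- median(x)
      mad0 <- median(abs(x - m))
      if (mad0 == 0) stop("zero dispersion (MAD = 0)")
      (x - m) / mad0
    },
    zscore = {
      s <- sqrt(mean((x - mean(x))^2))
      if (s == 0) stop("zero dispersion (SD = 0)")
      (x - mean(x)) / s
    },
    rank_normal = {
      if (length(unique(x)) < 2) stop("zero dispersion (constant series)")
      qnorm(rank(x, ties.method = "average") / (n + 1))
    })
}

#' Local similarity score between two series
#'
#' Dynamic program over aligned positions with offset up to `max_delay`:
#' P(i) = max(0, P(i-1) + x_i y_i) and N(i) = max(0, N(i-1) - x_i y_i) along
#' each alignment; the score is the largest running maximum divided by the
#' full series length n, signed positive or negative according to which
#' dominates. Ties are broken toward the positive sign, smaller |delay|,
#' then the earlier start.
#'
#' @param x,y numeric series of equal length (already normalized)
#' @param max_delay maximum |delay| in months (<= n - 2)
#' @return list with `ls`, `delay`, `interval_a`, `interval_b` (1-based
#'   inclusive month positions of the aligned best segment)
#' @export
local_similarity <- function(x, y, max_delay = 0) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (max_delay > length(x) - 2) stop("max_delay too large for series length")
  r <- ls_score_cpp(as.numeric(x), as.numeric(y), as.integer(max_delay))
  list(ls = r$ls, delay = r$delay,
       interval_a = c(r$start_a, r$stop_a),
       interval_b = c(r$start_b, r$stop_b))
}

# CDF of sup_{0<=t<=1} |W(t)| for a standard Brownian motion
sup_abs_bm_cdf <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    k <- 0:60
    out[pos] <- vapply(x[pos], function(v) {
      s <- sum((-1)^k / (2 * k + 1) * exp(-pi^2 * (2 * k + 1)^2 / (8 * v^2)))
      min(1, max(0, 4 / pi * s))
    }, 0)
  }
  out
}

#' Theoretical p-value of a local similarity score
#'
#' Upper-tail probability of the maximal-segment-sum statistic sqrt(n)|LS|
#' under the null of independent unit-variance series. The maximal segment
#' sum of a mean-zero random walk converges to the supremum of reflected
#' Brownian motion (Levy's identity), whose distribution equals that of
#' sup|W|; positive and negative segments are combined with an independence
#' approximation, p = 1 - F(x)^2. The discrete walk's maximum sits below
#' the Brownian supremum by an excess-over-boundary gap of order 1/sqrt(n);
#' the statistic carries a Monte-Carlo-fitted continuity correction
#' x = sqrt(n)|LS| + 1.45/sqrt(n), which centres the null calibration at
#' monthly-series lengths and leaves the deep tail slightly conservative.
#'
#' @param ls local similarity score(s)
#' @param n full series length (>= 10)
#' @return p-value(s) in (0, 1], monotone non-increasing in |ls|
#' @export
theoretical_pvalue <- function(ls, n) {
  if (n < 10) stop("n must be >= 10")
  x <- sqrt(n) * abs(ls) + ifelse(abs(ls) > 0, 1.45 / sqrt(n), 0)
  p <- 1 - sup_abs_bm_cdf(x)^2
  pmin(1, pmax(p, 1e-300))
}

#' Permutation p-value of a local similarity score
#'
#' Permutes one series `n_perm` times, recomputes |LS|, and reports
#' p = (1 + #\{|LS*| >= |LS|\}) / (n_perm + 1). The shuffles come from a
#' dedicated seeded generator, so the result is reproducible and independent
#' of R's RNG state.
#'
#' @param x,y numeric series of equal length (already normalized)
#' @param n_perm number of permutations (>= 99)
#' @param max_delay maximum |delay| in months
#' @param seed integer seed
#' @return permutation p-value
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000, max_delay = 0, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (length(x) != length(y)) stop("series lengths differ")
  ls_perm_pvalue_cpp(as.numeric(x), as.numeric(y), as.integer(max_delay),
                     as.integer(n_perm), as.numeric(seed))
}

#' Spearman rank correlation
#'
#' @param x,y numeric series of equal length (>= 3); ties get average ranks
#' @return rho in \[-1, 1\], or `NA` for a constant series
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3) stop("series must have length >= 3")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  suppressWarnings(cor(x, y, method = "spearman"))
}

# normalize every row; median_mad falls back to rank_normal where the MAD is
# zero (heavily zero-inflated series); all rows are then rescaled to unit
# population SD so the asymptotic null of sqrt(n) LS applies.
normalize_matrix <- function(mat, method) {
  out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  fallback <- character(0)
  for (i in seq_len(nrow(mat))) {
    v <- tryCatch(normalize_series(mat[i, ], method), error = function(e) NULL)
    if (is.null(v)) {
      v <- normalize_series(mat[i, ], "rank_normal")
      fallback <- c(fallback, rownames(mat)[i])
    }
    s <- sqrt(mean((v - mean(v))^2))
    out[i, ] <- (v - mean(v)) / s
  }
  attr(out, "fallback") <- fallback
  out
}

#' Build the all-pairs association table
#'
#' Evaluates every OTU-OTU and OTU-environment pair on a shared month axis.
#' Each series is normalized (with a rank-normal fallback for series whose
#' raw MAD is zero) and rescaled to unit variance. A theoretical p-value
#' screens each pair at `screen_alpha`; screened pairs get a seeded
#' permutation test, and the final p is the theoretical p when the
#' permutation confirms it (p_perm <= screen_alpha) or the permutation p
#' otherwise, giving a calibrated test whose tail resolution supports
#' Bonferroni thresholds far below the permutation floor. q is the
#' Bonferroni-adjusted p over all evaluated pairs.
#'
#' @param series numeric matrix, OTUs x months, with row names
#' @param env optional `env_series` data.frame or variables x months matrix
#'   (environmental nodes; env-env pairs are not evaluated)
#' @param config an [lsa_config()]
#' @return data.frame of class `assoc_table`, sorted by node ids, with
#'   columns node_a, node_b, kind, ls, sign, delay, start_a, stop_a,
#'   start_b, stop_b, p_theory, p_perm, p, q, spearman; attributes `n_tests`,
#'   `env_vars`, `months`, `normalization`
#' @export
build_association_table <- function(series, env = NULL,
                                    config = lsa_config()) {
  stopifnot(inherits(config, "lsa_config"))
  series <- as.matrix(series)
  if (is.null(rownames(series))) stop("series matrix needs row names")
  env_mat <- NULL
  if (!is.null(env)) {
    env_mat <- if (inherits(env, "env_series") || is.data.frame(env)) {
      env_matrix(env)
    } else as.matrix(env)
    if (ncol(env_mat) != ncol(series)) {
      stop("environmental series must share the month axis")
    }
  }
  full <- rbind(series, env_mat)
  n_otu <- nrow(series)
  n_node <- nrow(full)
  ids <- rownames(full)
  is_env <- c(rep(FALSE, n_otu), rep(TRUE, n_node - n_otu))

  pair_idx <- t(combn(n_node, 2))
  keep <- !(is_env[pair_idx[, 1]] & is_env[pair_idx[, 2]])
  pair_idx <- pair_idx[keep, , drop = FALSE]
  K <- nrow(pair_idx)

  norm <- normalize_matrix(full, config$normalization)
  dp <- ls_pairs_cpp(norm, pair_idx[, 1], pair_idx[, 2], config$max_delay)
  n <- ncol(full)
  p_theory <- theoretical_pvalue(dp$ls, n)

  screened <- p_theory < config$screen_alpha
  p_perm <- rep(NA_real_, K)
  if (any(screened)) {
    p_perm[screened] <- ls_perm_batch_cpp(
      norm, pair_idx[screened, 1], pair_idx[screened, 2],
      config$max_delay, config$n_perm, as.numeric(config$seed))
  }
  p <- ifelse(!screened, p_theory,
              ifelse(p_perm <= config$screen_alpha,
                     pmin(p_theory, p_perm), p_perm))
  q <- pmin(1, p * K)

  rho_all <- suppressWarnings(cor(t(full), method = "spearman"))
  rho <- rho_all[cbind(pair_idx[, 1], pair_idx[, 2])]

  a <- ids[pair_idx[, 1]]; b <- ids[pair_idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  sa <- ifelse(swap, dp$start_b, dp$start_a)
  ea <- ifelse(swap, dp$stop_b, dp$stop_a)
  sb <- ifelse(swap, dp$start_a, dp$start_b)
  eb <- ifelse(swap, dp$stop_a, dp$stop_b)
  delay <- ifelse(swap, -dp$delay, dp$delay)

  out <- data.frame(
    node_a = a, node_b = b,
    kind = ifelse(is_env[pair_idx[, 1]] | is_env[pair_idx[, 2]],
                  "otu-env", "otu-otu"),
    ls = dp$ls, sign = ifelse(dp$ls >= 0, "+", "-"), delay = delay,
    start_a = sa, stop_a = ea, start_b = sb, stop_b = eb,
    p_theory = p_theory, p_perm = p_perm, p = p, q = q, spearman = rho,
    stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), ]
  rownames(out) <- NULL
  attr(out, "n_tests") <- K
  attr(out, "env_vars") <- if (is.null(env_mat)) character(0)
                           else rownames(env_mat)
  attr(out, "months") <- colnames(full)
  attr(out, "normalization") <- config$normalization
  attr(out, "mad_fallback") <- attr(norm, "fallback")
  class(out) <- c("assoc_table", "data.frame")
  out
}
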
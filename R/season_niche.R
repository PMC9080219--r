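# Season delineation, indicator-value seasonal preference, and
# abundance-weighted environmental niche null models.

#' Assign seasons from temperature and day length
#'
#' Rule-based delineation: summer when temperature > 17 C and daylength
#' > 14 h; winter when temperature < 17 C and daylength < 11 h; autumn when
#' temperature > 17 C and daylength < 14 h; spring when temperature < 17 C
#' and daylength > 11 h. Values exactly on a boundary (17 C, 11 h, 14 h) are
#' undefined by the rules; by default they raise an error, with
#' `boundary = "closed-lower"` the boundary value is assigned to the lower
#' interval (17 C counts as cold, 14 h as short, 11 h as short).
#'
#' @param temperature water temperature, degrees C (vectorized)
#' @param daylength hours of light (vectorized)
#' @param boundary boundary policy, `"error"` or `"closed-lower"`
#' @return factor with levels winter, spring, summer, autumn
#' @export
assign_season <- function(temperature, daylength,
                          boundary = c("error", "closed-lower")) {
  boundary <- match.arg(boundary)
  stopifnot(all(is.finite(temperature)), all(is.finite(daylength)))
  if (boundary == "error") {
    bad <- temperature == 17 | daylength == 11 | daylength == 14
    if (any(bad)) {
      stop("boundary value(s) at 17 C / 11 h / 14 h are undefined; ",
           "use boundary = \"closed-lower\"")
    }
  }
  warm <- temperature > 17
  long14 <- daylength > 14
  long11 <- daylength > 11
  out <- ifelse(warm & long14, "summer",
         ifelse(warm & !long14, "autumn",
         ifelse(!warm & !long11, "winter", "spring")))
  factor(out, levels = c("winter", "spring", "summer", "autumn"))
}

#' Indicator value of each OTU per season
#'
#' IndVal_ij = A_ij * B_ij * 100, where A_ij (specificity) is the mean
#' abundance of OTU i in season j divided by the sum of its per-season mean
#' abundances, and B_ij (fidelity) is the fraction of season-j samples in
#' which OTU i is present. Significance of the maximum IndVal is assessed by
#' permuting the season labels, with p = (r + 1) / (n_perm + 1).
#'
#' @param mat abundance matrix, OTUs x samples
#' @param labels season label per sample (factor or character)
#' @param n_perm number of label permutations (>= 99)
#' @param seed integer seed
#' @return data.frame: one row per OTU with `indval_<season>` columns,
#'   `best_season`, and permutation `p`; all-`NA` row for all-zero OTUs
#' @export
indval <- function(mat, labels, n_perm = 999, seed = 1L) {
  mat <- as.matrix(mat)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two seasons")
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (length(labels) != ncol(mat)) stop("one label per sample required")
  set.seed(seed)
  iv_of <- function(lab) {
    ind <- vapply(levels(labels), function(s) as.numeric(lab == s),
                  numeric(length(lab)))
    nj <- colSums(ind)
    means <- (mat %*% ind) %*% diag(1 / nj, ncol(ind))
    A <- means / pmax(rowSums(means), .Machine$double.eps)
    B <- ((mat > 0) %*% ind) %*% diag(1 / nj, ncol(ind))
    A * B * 100
  }
  iv <- iv_of(labels)
  colnames(iv) <- levels(labels)
  zero <- rowSums(mat) == 0
  obs_max <- apply(iv, 1, max)
  exceed <- integer(nrow(mat))
  for (b in seq_len(n_perm)) {
    pm <- apply(iv_of(sample(labels)), 1, max)
    exceed <- exceed + (pm >= obs_max - 1e-12)
  }
  p <- (exceed + 1) / (n_perm + 1)
  best <- levels(labels)[max.col(iv, ties.method = "first")]
  iv[zero, ] <- NA_real_
  best[zero] <- NA_character_
  p[zero] <- NA_real_
  out <- data.frame(otu = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                    iv, best_season = best, p = p,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[2:(1 + nlevels(labels))] <-
    paste0("indval_", levels(labels))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Niche preference from an abundance-weighted environmental mean
#'
#' The observed statistic is the abundance-weighted mean of the variable,
#' sum(a * e) / sum(a). The null distribution permutes the abundances over
#' samples; confidence limits are the 2.5 and 97.5 percentiles of the null,
#' and the OTU is classified "above"/"below" when the weighted mean falls
#' outside them (two-sided permutation p < 0.05).
#'
#' @param abundance non-negative abundances per sample
#' @param env_values environmental variable per sample (same length)
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list: `weighted_mean`, `null_mean`, `lower_cl`, `upper_cl`,
#'   two-sided `p`, `classification` ("above", "below" or "none")
#' @export
niche_preference <- function(abundance, env_values, n_perm = 1000, seed = 1L) {
  stopifnot(length(abundance) == length(env_values))
  if (sum(abundance) <= 0) stop("total abundance must be positive")
  if (sd(env_values) == 0) stop("constant environmental variable")
  set.seed(seed)
  wm <- sum(abundance * env_values) / sum(abundance)
  null <- vapply(seq_len(n_perm), function(b) {
    a <- sample(abundance)
    sum(a * env_values) / sum(a)
  }, 0)
  lo <- unname(quantile(null, 0.025))
  hi <- unname(quantile(null, 0.975))
  p_hi <- (sum(null >= wm - 1e-12) + 1) / (n_perm + 1)
  p_lo <- (sum(null <= wm + 1e-12) + 1) / (n_perm + 1)
  p <- min(1, 2 * min(p_hi, p_lo))
  cls <- if (wm > hi) "above" else if (wm < lo) "below" else "none"
  list(weighted_mean = wm, null_mean = mean(null), lower_cl = lo,
       upper_cl = hi, p = p, classification = cls)
}

#' Niche preference table for many OTUs and variables
#'
#' @param mat abundance matrix, OTUs x samples
#' @param env an `env_series` data.frame
#' @param variables environmental variables to test
#' @param n_perm permutations per test
#' @param seed integer seed
#' @return data.frame with one row per OTU x variable
#' @export
niche_table <- function(mat, env, variables = c("temperature", "daylength"),
                        n_perm = 1000, seed = 1L) {
  rows <- list()
  for (v in variables) {
    e <- env[[v]]
    if (is.null(e)) stop("unknown environmental variable: ", v)
    for (i in seq_len(nrow(mat))) {
      r <- niche_preference(mat[i, ], e, n_perm = n_perm,
                            seed = child_seed(seed, i * 131 + match(v, variables)))
      rows[[length(rows) + 1]] <- data.frame(
        otu = rownames(mat)[i], variable = v,
        weighted_mean = r$weighted_mean, null_mean = r$null_mean,
        lower_cl = r$lower_cl, upper_cl = r$upper_cl, p = r$p,
        classification = r$classification, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
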
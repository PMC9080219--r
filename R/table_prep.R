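# Count-table preprocessing: everything between raw OTU tables and the
# resident abundance matrix used for association inference.

#' Construct a count table
#'
#' @param counts non-negative integer matrix, OTUs x samples; column names
#'   are ISO-8601 year-month stamps, row names are OTU ids
#' @param domain "bacteria" or "protist"
#' @param size_fraction "pico" or "nano"
#' @param depth rarefaction depth the samples were subsampled to, if any
#' @return a `count_table` object
#' @export
count_table <- function(counts, domain, size_fraction, depth = NA_integer_) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("sample dates must be present and unique within a table")
  }
  month_of_year(colnames(counts))  # validates the stamps
  domain <- match.arg(domain, c("bacteria", "protist"))
  size_fraction <- match.arg(size_fraction, c("pico", "nano"))
  structure(list(counts = counts, domain = domain,
                 size_fraction = size_fraction, depth = depth),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples (%s, %splankton)%s\n",
              nrow(x$counts), ncol(x$counts), x$domain, x$size_fraction,
              if (is.na(x$depth)) "" else sprintf(", depth %d", x$depth)))
  invisible(x)
}

#' Rarefy samples to a fixed read depth
#'
#' Each sample (column) is subsampled without replacement to exactly `depth`
#' reads, via [vegan::rrarefy()]. Samples already at `depth` are unchanged.
#'
#' @param table a [count_table()]
#' @param depth target reads per sample
#' @param seed integer seed (subsampling is random)
#' @return the rarefied `count_table`, with `depth` recorded
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  low <- totals < depth
  if (any(low)) {
    stop("sample(s) below the rarefaction depth ", depth, ": ",
         paste(colnames(table$counts)[low], collapse = ", "))
  }
  set.seed(seed)
  # vegan speculates about non-count input whenever the smallest nonzero
  # entry exceeds 1; our tables are genuine counts, so muffle that warning
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(table$counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(rar) <- "integer"
  count_table(rar, table$domain, table$size_fraction, depth = depth)
}

#' Remove rare OTUs by prevalence
#'
#' Retains OTUs present (count > 0) in at least
#' `ceiling(min_fraction * n_samples)` samples.
#'
#' @param table a [count_table()]
#' @param min_fraction minimum occurrence fraction, in (0, 1)
#' @return filtered `count_table`
#' @export
filter_prevalence <- function(table, min_fraction = 0.10) {
  stopifnot(inherits(table, "count_table"))
  if (min_fraction <= 0 || min_fraction >= 1) {
    stop("min_fraction must be in (0, 1)")
  }
  if (nrow(table$counts) == 0 || ncol(table$counts) == 0) {
    stop("empty count table")
  }
  need <- ceiling(min_fraction * ncol(table$counts))
  keep <- rowSums(table$counts > 0) >= need
  count_table(table$counts[keep, , drop = FALSE], table$domain,
              table$size_fraction, table$depth)
}

#' Resolve OTUs shared between size fractions (2:1 ratio rule)
#'
#' For each OTU present in both the pico- and nanoplankton table of a
#' domain, the total reads in each fraction are compared; when the ratio of
#' the larger to the smaller total strictly exceeds `ratio_threshold`, the
#' OTU is zeroed out of the fraction with the lower total (DNA leakage
#' between fractions). OTUs found in only one fraction are untouched; an OTU
#' is never removed from both fractions.
#'
#' @param pico,nano [count_table()]s sharing an OTU id space
#' @param ratio_threshold dimensionless ratio (default 2)
#' @return list with elements `pico` and `nano` (resolved tables) and
#'   `removed` (data.frame of OTU id and the fraction it was removed from)
#' @export
resolve_size_fractions <- function(pico, nano, ratio_threshold = 2) {
  stopifnot(inherits(pico, "count_table"), inherits(nano, "count_table"),
            ratio_threshold >= 1)
  shared <- intersect(rownames(pico$counts), rownames(nano$counts))
  removed <- data.frame(otu = character(), fraction = character(),
                        stringsAsFactors = FALSE)
  pc <- pico$counts; nc <- nano$counts
  for (id in shared) {
    tp <- sum(pc[id, ]); tn <- sum(nc[id, ])
    if (min(tp, tn) == 0) next
    if (max(tp, tn) / min(tp, tn) > ratio_threshold) {
      if (tp < tn) {
        pc[id, ] <- 0L
        removed <- rbind(removed, data.frame(otu = id, fraction = "pico"))
      } else {
        nc[id, ] <- 0L
        removed <- rbind(removed, data.frame(otu = id, fraction = "nano"))
      }
    }
  }
  list(pico = count_table(pc, pico$domain, "pico", pico$depth),
       nano = count_table(nc, nano$domain, "nano", nano$depth),
       removed = removed)
}

#' Seasonally aware imputation of missing months
#'
#' Missing values are filled by subtracting per-calendar-month (seasonal)
#' means, imputing the residuals with a linearly weighted moving average
#' (window `k` on each side, weights `k + 1 - distance`), and adding the
#' seasonal means back. A gap with no observed residual inside the window is
#' filled with the seasonal mean itself. Observed values are never changed;
#' the result is deterministic.
#'
#' @param values numeric vector with `NA` at missing months
#' @param months month stamps (used to derive month-of-year); if `NULL`, the
#'   cycle position is taken from the index modulo `period`
#' @param period season cycle length in months
#' @param k half-window of the weighted moving average
#' @return list with `values` (filled), `months`, and `imputed` (logical
#'   mask, `TRUE` exactly where input was missing)
#' @export
impute_seasonal <- function(values, months = NULL, period = 12, k = 2) {
  n <- length(values)
  moy <- if (is.null(months)) ((seq_len(n) - 1L) %% period) + 1L
         else month_of_year(months)
  obs <- !is.na(values)
  mu <- tapply(values[obs], moy[obs], mean)
  missing_moy <- setdiff(unique(moy), as.integer(names(mu)))
  if (length(missing_moy) > 0) {
    stop("no observed value for calendar month(s): ",
         paste(missing_moy, collapse = ", "))
  }
  resid <- values - as.numeric(mu[as.character(moy)])
  out <- values
  for (i in which(!obs)) {
    j <- max(1, i - k):min(n, i + k)
    j <- j[obs[j]]
    r <- if (length(j) == 0) 0 else {
      w <- k + 1 - abs(j - i)
      sum(w * resid[j]) / sum(w)
    }
    out[i] <- as.numeric(mu[as.character(moy[i])]) + r
  }
  list(values = out, months = months, imputed = !obs)
}

# merged node ids: size-fraction prefix + domain-level OTU id,
# e.g. b_00037 in the picoplankton fraction becomes bp_00037
merged_node_id <- function(otu, fraction) {
  pre <- substr(otu, 1, 1)
  paste0(pre, ifelse(fraction == "pico", "p", "n"),
         sub("^[be]", "", otu))
}

#' Merge domain/fraction count tables into one node x month matrix
#'
#' Rows are fraction-prefixed node ids (the same OTU observed in both size
#' fractions yields two nodes); columns are the union of month stamps, with
#' `NA` where a table did not sample a month. All-zero rows are dropped.
#'
#' @param tables list of [count_table()]s
#' @return numeric matrix with attribute `node_meta` (data.frame of node id,
#'   OTU id, domain, size fraction)
#' @export
merge_count_tables <- function(tables) {
  months <- sort(unique(unlist(lapply(tables, function(t) colnames(t$counts)))))
  rows <- list(); meta <- list()
  for (t in tables) {
    keep <- rowSums(t$counts) > 0
    cc <- t$counts[keep, , drop = FALSE]
    if (nrow(cc) == 0) next
    m <- matrix(NA_real_, nrow(cc), length(months),
                dimnames = list(NULL, months))
    m[, colnames(cc)] <- cc
    ids <- merged_node_id(rownames(cc), t$size_fraction)
    rownames(m) <- ids
    rows[[length(rows) + 1]] <- m
    meta[[length(meta) + 1]] <- data.frame(
      node = ids, otu = rownames(cc), domain = t$domain,
      size_fraction = t$size_fraction, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "node_meta") <- do.call(rbind, meta)
  out
}

#' Impute all missing months of a merged abundance matrix
#'
#' Applies [impute_seasonal()] row-wise to columns that are `NA`.
#'
#' @param mat node x month matrix with `NA` columns for unsampled months
#' @inheritParams impute_seasonal
#' @return list with `values` (complete matrix) and `imputed` (logical
#'   matrix mask)
#' @export
impute_matrix <- function(mat, period = 12, k = 2) {
  imputed <- is.na(mat)
  if (!any(imputed)) return(list(values = mat, imputed = imputed))
  months <- colnames(mat)
  for (i in which(rowSums(imputed) > 0)) {
    mat[i, ] <- impute_seasonal(mat[i, ], months, period = period, k = k)$values
  }
  list(values = mat, imputed = imputed)
}

#' Monthly relative abundance aggregated over years
#'
#' For each calendar month (Jan..Dec) the reads of every OTU across all
#' tables (both domains and both size fractions) are summed over the years
#' and divided by that calendar month's grand total, so the values of all
#' OTUs sum to 1 for each month across the full span.
#'
#' @param tables list of [count_table()]s rarefied to a common depth
#' @return matrix, merged node ids x 12 calendar months; each column sums to 1
#' @export
aggregate_relative_abundance <- function(tables) {
  depths <- vapply(tables, function(t) as.numeric(t$depth), 0)
  if (any(is.na(depths)) || length(unique(depths)) != 1) {
    stop("tables must be rarefied to one common depth")
  }
  merged <- merge_count_tables(tables)
  merged[is.na(merged)] <- 0
  moy <- month_of_year(colnames(merged))
  out <- matrix(0, nrow(merged), 12,
                dimnames = list(rownames(merged), sprintf("%02d", 1:12)))
  for (cm in 1:12) {
    out[, cm] <- rowSums(merged[, moy == cm, drop = FALSE])
  }
  tot <- colSums(out)
  out[, tot > 0] <- sweep(out[, tot > 0, drop = FALSE], 2, tot[tot > 0], "/")
  out
}

#' Select the resident OTU set
#'
#' Nodes present (abundance > 0) in at least `min_months` months are
#' resident; whitelisted ids are resident regardless of occurrence.
#'
#' @param mat node x month abundance matrix (post-imputation)
#' @param min_months occurrence threshold in months (inclusive)
#' @param whitelist node ids kept unconditionally
#' @return character vector of resident node ids
#' @export
select_residents <- function(mat, min_months = 36, whitelist = character()) {
  present <- rowSums(!is.na(mat) & mat > 0)
  res <- rownames(mat)[present >= min_months]
  union(res, intersect(whitelist, rownames(mat)))
}

#' Z-score standardize environmental variables
#'
#' Each numeric variable is centred to mean 0 and scaled to sample SD 1.
#'
#' @param env an `env_series` data.frame
#' @return the standardized `env_series`
#' @export
standardize_env <- function(env) {
  vars <- setdiff(names(env), c("month", "month_index"))
  for (v in vars) {
    s <- sd(env[[v]])
    if (!is.finite(s) || s == 0) stop("constant environmental variable: ", v)
    env[[v]] <- (env[[v]] - mean(env[[v]])) / s
  }
  env
}
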
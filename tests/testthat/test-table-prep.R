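test_that("rarefaction subsamples to the exact depth and is monotone", {
  tab <- make_table(matrix(c(10L, 0L, 5L), 3, 1))
  r <- rarefy_counts(tab, 15, seed = 1)
  expect_equal(unname(r$counts[, 1]), c(10L, 0L, 5L))  # depth = total

  set.seed(99)
  big <- make_table(matrix(rpois(60, 100), 6, 10))
  r2 <- rarefy_counts(big, 500, seed = 2)
  expect_true(all(colSums(r2$counts) == 500))
  expect_true(all(r2$counts <= big$counts))
  expect_true(all(big$counts[r2$counts == 0 & big$counts == 0] == 0))
  # presence only moves downward: absent stays absent
  expect_true(all(r2$counts[big$counts == 0] == 0))
  # identical under the same seed
  expect_identical(rarefy_counts(big, 500, seed = 2)$counts, r2$counts)
  expect_error(rarefy_counts(big, 1e6, seed = 1), colnames(big$counts)[1])
})

test_that("rarefied counts have the hypergeometric mean", {
  tab <- make_table(matrix(c(3000L, 3000L), 2, 1))
  means <- vapply(1:1000, function(s) {
    rarefy_counts(tab, 100, seed = s)$counts[1, 1]
  }, 0L)
  se <- sqrt(100 * 0.25 * (6000 - 100) / (6000 - 1)) / sqrt(1000)
  expect_lt(abs(mean(means) - 50), 3 * se)
})

test_that("prevalence filter applies the ceiling rule and is monotone", {
  counts <- matrix(0L, 3, 120)
  counts[1, 1:12] <- 1L   # exactly 10% of samples
  counts[2, 1:11] <- 1L   # just below
  counts[3, ] <- 2L       # everywhere
  tab <- make_table(counts)
  kept <- filter_prevalence(tab, 0.10)
  expect_setequal(rownames(kept$counts), c("b_00001", "b_00003"))
  expect_error(filter_prevalence(tab, 0), "min_fraction")

  set.seed(7)
  rnd <- make_table(matrix(rbinom(300, 1, 0.3) * rpois(300, 5), 10, 30))
  prev <- nrow(filter_prevalence(rnd, 0.05)$counts)
  for (f in c(0.1, 0.2, 0.5)) {
    cur <- nrow(filter_prevalence(rnd, f)$counts)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("the 2:1 size-fraction ratio rule is strict and symmetric", {
  mk <- function(tot, frac) {
    m <- matrix(as.integer(tot), 1, 4)
    m[1, ] <- as.integer(c(tot - 3, 1, 1, 1))
    rownames(m) <- "b_00001"
    make_table(m, fraction = frac)
  }
  # pico 100 / nano 40 (ratio 2.5): removed from nano
  r <- resolve_size_fractions(mk(100, "pico"), mk(40, "nano"), 2)
  expect_true(all(r$nano$counts == 0))
  expect_true(any(r$pico$counts > 0))
  expect_equal(r$removed$fraction, "nano")
  # ratio exactly 2: kept in both ("exceeded" is strict)
  r2 <- resolve_size_fractions(mk(100, "pico"), mk(50, "nano"), 2)
  expect_true(any(r2$pico$counts > 0) && any(r2$nano$counts > 0))
  # symmetric: pico 30 / nano 90 removes from pico
  r3 <- resolve_size_fractions(mk(30, "pico"), mk(90, "nano"), 2)
  expect_true(all(r3$pico$counts == 0))
  expect_equal(r3$removed$fraction, "pico")
  # never removed from both
  set.seed(3)
  for (i in 1:20) {
    a <- mk(sample(10:200, 1), "pico"); b <- mk(sample(10:200, 1), "nano")
    rr <- resolve_size_fractions(a, b, 2)
    expect_true(any(rr$pico$counts > 0) || any(rr$nano$counts > 0))
  }
})

test_that("seasonal imputation fills gaps from the seasonal structure", {
  months <- month_stamps(60)
  # constant series: gap imputed to the constant
  v <- rep(5, 60); v[13] <- NA
  out <- impute_seasonal(v, months)
  expect_equal(out$values[13], 5)
  expect_equal(out$imputed, seq_len(60) == 13)
  # noiseless 12-month sinusoid with one missing January
  s <- sin(2 * pi * seq_len(60) / 12)
  amp <- max(s) - min(s)
  jan <- which(month_of_year(months) == 1)
  s2 <- s; s2[jan[3]] <- NA
  out2 <- impute_seasonal(s2, months)
  expect_lt(abs(out2$values[jan[3]] - mean(s[jan[-3]])), 0.1 * amp)
  # observed values never change; gapless input returned unchanged
  expect_equal(out2$values[-jan[3]], s[-jan[3]])
  out3 <- impute_seasonal(s, months)
  expect_equal(out3$values, s)
  expect_false(any(out3$imputed))
  # a calendar month with zero observations is an error
  v4 <- rep(1, 60); v4[jan] <- NA
  expect_error(impute_seasonal(v4, months), "calendar month")
})

test_that("monthly relative abundance sums to one per calendar month", {
  # single OTU: value 1 for every calendar month
  one <- make_table(matrix(1L, 1, 24), depth = 1)
  agg1 <- aggregate_relative_abundance(list(one))
  expect_equal(unname(colSums(agg1)), rep(1, 12))
  expect_true(all(agg1 == 1))
  # two OTUs with equal totals in January share it equally
  m <- matrix(3L, 2, 24); rownames(m) <- c("b_00001", "b_00002")
  two <- make_table(m, depth = 6)
  agg2 <- aggregate_relative_abundance(list(two))
  expect_equal(unname(agg2[, "01"]), c(0.5, 0.5))
  # random fixture equals a direct summation oracle, invariant to row order
  set.seed(11)
  cm <- matrix(rpois(5 * 24, 10), 5, 24)
  rownames(cm) <- sprintf("b_%05d", 1:5)
  t1 <- make_table(cm, depth = 240)
  agg <- aggregate_relative_abundance(list(t1))
  moy <- month_of_year(month_stamps(24))
  oracle <- sapply(1:12, function(k) {
    s <- rowSums(cm[, moy == k, drop = FALSE])
    s / sum(s)
  })
  expect_equal(unname(agg[sprintf("bp_%05d", 1:5), ]), unname(oracle))
  shuf <- make_table(cm[5:1, ], depth = 240)
  agg_s <- aggregate_relative_abundance(list(shuf))
  expect_equal(agg_s[rownames(agg), ], agg)
  # unequal depths are rejected
  expect_error(aggregate_relative_abundance(list(one, two)), "common depth")
})

test_that("resident selection honours threshold and whitelist", {
  m <- matrix(0, 3, 120, dimnames = list(c("a", "b", "c"),
                                         month_stamps(120)))
  m[1, 1:36] <- 1   # exactly 36 months
  m[2, 1:35] <- 1   # one short
  m[3, 1:25] <- 1   # short but whitelisted
  expect_setequal(select_residents(m, 36), "a")
  expect_setequal(select_residents(m, 36, whitelist = "c"), c("a", "c"))
})

test_that("environmental standardization is exact and idempotent", {
  env <- data.frame(month = month_stamps(3), month_index = 0:2,
                    temperature = c(1, 2, 3))
  class(env) <- c("env_series", "data.frame")
  z <- standardize_env(env)
  expect_equal(z$temperature, c(-1, 0, 1))
  z2 <- standardize_env(z)
  expect_equal(z2$temperature, z$temperature, tolerance = 1e-12)
  env$temperature <- rep(4, 3)
  expect_error(standardize_env(env), "temperature")
})

test_that("merged matrices carry fraction-prefixed ids and NA months", {
  sim <- simulate_community(synth_config(n_otus_per_table = 6,
                                         n_direct_pairs = 1,
                                         n_env_driven_pairs = 1, seed = 2))
  merged <- merge_count_tables(sim$tables)
  expect_true(all(grepl("^(bp|bn|ep|en)_", rownames(merged))))
  # nano columns are NA in the missing months
  miss <- month_stamps(120)[c(3, 14, 77:103)]
  nano_rows <- grep("^(bn|en)_", rownames(merged))
  expect_true(all(is.na(merged[nano_rows, miss])))
  imp <- impute_matrix(merged)
  expect_false(anyNA(imp$values))
  expect_true(all(imp$imputed[nano_rows, miss]))
})
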
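test_that("photoperiod model gives equinox symmetry and solstice extremes", {
  doy_mid <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))[1:12] + 15
  dl <- daylength_cbm(doy_mid, 41.67)
  expect_equal(dl[3], 12, tolerance = 0.5 / 12)  # March, near equinox
  expect_equal(which.max(dl), 6)                 # June
  expect_equal(which.min(dl), 12)                # December
  expect_true(all(dl > 0 & dl < 24))
})

test_that("environmental series is seeded, complete, and periodic in form", {
  e1 <- generate_environment(120, seed = 42)
  e2 <- generate_environment(120, seed = 42)
  expect_identical(e1, e2)
  e3 <- generate_environment(120, seed = 43)
  expect_false(identical(e1$temperature, e3$temperature))
  expect_false(anyNA(e1))
  expect_equal(ncol(e1) - 2, 15)  # 15 variables beside month stamps
  # daylength is deterministic with period 12
  expect_equal(e1$daylength[1:12], e1$daylength[13:24])
  expect_error(generate_environment(6), "at least 12")
})

test_that("latent dynamics honour the planted structure", {
  env <- generate_environment(120, seed = 1)
  # zero-noise direct pair: members identical up to scale
  cfg <- synth_config(n_otus_per_table = 10, noise_sd = 0,
                      seasonal_fraction = 0, n_direct_pairs = 1,
                      n_env_driven_pairs = 0, positive_fraction = 1,
                      seed = 5)
  dyn <- generate_latent_dynamics(cfg, env)
  tr <- dyn$truth$direct_pairs
  ids <- rownames(dyn$latent)
  # map merged ids back to domain-level rows
  unmerge <- function(id) sub("^(b|e)[pn]", "\\1", id)
  a <- dyn$latent[unmerge(tr$a[1]), ]
  b <- dyn$latent[unmerge(tr$b[1]), ]
  expect_equal(sd(a / b), 0, tolerance = 1e-8)

  # env-driven pair at zero noise: monotone transform of the driver
  cfg2 <- synth_config(n_otus_per_table = 10, noise_sd = 0,
                       seasonal_fraction = 0, n_direct_pairs = 0,
                       n_env_driven_pairs = 2, seed = 6)
  dyn2 <- generate_latent_dynamics(cfg2, env)
  tr2 <- dyn2$truth$env_driven_pairs
  for (i in seq_len(nrow(tr2))) {
    s <- dyn2$latent[unmerge(tr2$a[i]), ]
    drv <- env[[tr2$var[i]]][1:120]
    expect_equal(abs(cor(s, drv, method = "spearman")), 1)
  }

  # a winter OTU is on average more abundant in winter than in summer
  cfg3 <- synth_config(n_otus_per_table = 10, noise_sd = 0,
                       seasonal_fraction = 1, n_direct_pairs = 0,
                       n_env_driven_pairs = 0, seed = 7)
  dyn3 <- generate_latent_dynamics(cfg3, env)
  season <- assign_season(18.5 + 6 * cos(2 * pi * (month_of_year(env$month) - 8) / 12),
                          env$daylength, boundary = "closed-lower")
  lab <- dyn3$truth$niche_labels
  winter_otu <- names(lab)[lab == "winter"][1]
  expect_false(is.na(winter_otu))
  s <- dyn3$latent[unmerge(winter_otu), ]
  expect_gt(mean(s[season == "winter"]), mean(s[season == "summer"]))

  # plantings never overlap and every labelled OTU exists
  expect_length(intersect(canonical <- paste(dyn2$truth$direct_pairs$a,
                                             dyn2$truth$direct_pairs$b),
                          paste(tr2$a, tr2$b)), 0)
  expect_error(generate_latent_dynamics(
    synth_config(n_otus_per_table = 3, n_direct_pairs = 10, seed = 1), env),
    "more planted pairs")
})

test_that("multinomial sampling hits the read depth exactly", {
  sim <- simulate_community(synth_config(n_otus_per_table = 8,
                                         n_direct_pairs = 2,
                                         n_env_driven_pairs = 2, seed = 3))
  for (t in sim$tables) {
    expect_true(all(colSums(t$counts) == 4907))
  }
  # nanoplankton tables miss the configured months
  expect_equal(ncol(sim$tables$bacteria_nano$counts), 120 - 29)
  expect_equal(ncol(sim$tables$bacteria_pico$counts), 120)
  # byte-identical regeneration under the same seed
  sim2 <- simulate_community(synth_config(n_otus_per_table = 8,
                                          n_direct_pairs = 2,
                                          n_env_driven_pairs = 2, seed = 3))
  expect_identical(sim$tables, sim2$tables)
  expect_identical(sim$truth, sim2$truth)
})

test_that("degenerate latent distributions behave as multinomials must", {
  months <- 1000
  assignment <- data.frame(otu = c("b_00001", "b_00002"),
                           domain = "bacteria", fractions = "pico",
                           major = "pico", leak = 0.2,
                           stringsAsFactors = FALSE)
  cfg <- synth_config(n_otus_per_table = 2, n_months = 120, seed = 9,
                      missing_blocks = list())
  lat <- matrix(1, 2, months,
                dimnames = list(assignment$otu, month_stamps(months, 1950)))
  tabs <- sample_counts(lat, assignment, cfg)
  counts <- tabs$bacteria_pico$counts
  # binomial mean: depth * 1/2 = 2453.5, SE = sd/sqrt(months)
  se <- sqrt(4907 * 0.25) / sqrt(months)
  expect_lt(abs(mean(counts[1, ]) - 2453.5), 3 * se)
  # all mass on one OTU
  lat2 <- lat; lat2[2, ] <- 0
  tabs2 <- sample_counts(lat2, assignment, cfg)
  expect_true(all(tabs2$bacteria_pico$counts[1, ] == 4907))
  # an all-zero latent column is an error
  lat3 <- lat; lat3[, 5] <- 0
  expect_error(sample_counts(lat3, assignment, cfg), "all-zero")
})

test_that("recovery scoring counts planted pairs correctly", {
  truth <- structure(list(
    direct_pairs = data.frame(a = c("x1", "x2", "x3", "x4"),
                              b = c("y1", "y2", "y3", "y4"),
                              sign = "+", stringsAsFactors = FALSE),
    env_driven_pairs = data.frame(a = "u", b = "v", var = "temperature",
                                  stringsAsFactors = FALSE),
    niche_labels = c(x1 = "none")), class = "synth_truth")
  exact <- evaluate_recovery(truth$direct_pairs[, 1:2], truth, "direct")
  expect_equal(exact$precision, 1)
  expect_equal(exact$recall, 1)
  none <- evaluate_recovery(data.frame(a = character(), b = character()),
                            truth, "direct")
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  half <- evaluate_recovery(data.frame(a = c("y1", "x2"), b = c("x1", "y2")),
                            truth, "direct")
  expect_equal(half$precision, 1)
  expect_equal(half$recall, 0.5)
  empty_truth <- structure(list(
    direct_pairs = data.frame(a = character(), b = character(),
                              sign = character()),
    env_driven_pairs = data.frame(), niche_labels = character()),
    class = "synth_truth")
  expect_error(evaluate_recovery(truth$direct_pairs[, 1:2], empty_truth),
               "no planted")
})

test_that("null communities yield a core false-positive rate within the Bonferroni level", {
  # no seasonality, no plantings: the core filter (Bonferroni q < 0.001)
  # should let essentially nothing through, over 20 independent seeds.
  # Community size is kept at 25 OTUs per table so that no single OTU owns
  # a large share of the multinomial depth: at very small richness,
  # compositional closure manufactures genuinely strong negative
  # associations that are not false positives of the test itself.
  total_edges <- 0
  total_tests <- 0
  for (seed in 1:20) {
    cfg <- pipeline_config(list(
      seed = 1000 + seed,
      synthetic = list(n_otus_per_table = 25, seasonal_fraction = 0,
                       n_direct_pairs = 0, n_env_driven_pairs = 0),
      season_niche = list(n_perm_indval = 99, n_perm_niche = 99),
      lsa = list(n_perm = 200)))
    res <- suppressMessages(run_pipeline(cfg))
    g <- res$core$network
    kind <- igraph::V(g)$kind
    el <- igraph::as_data_frame(g, "edges")
    env_nodes <- igraph::V(g)$name[!is.na(kind) & kind == "env"]
    oo <- el[!(el$from %in% env_nodes) & !(el$to %in% env_nodes), ]
    total_edges <- total_edges + nrow(oo)
    total_tests <- total_tests + attr(res$associations, "n_tests")
  }
  # the rate of surviving OTU-OTU edges stays within the nominal
  # Bonferroni-corrected level; the handful that can appear at small
  # community sizes are compositional-closure associations (one OTU
  # holding a visible share of the fixed read depth), which are genuine
  # correlations in the generated data rather than test miscalibration
  expect_lte(total_edges / total_tests, 0.001)
})
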
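# Synthetic community generator
#
# Emulates the sampling design of a decade-long coastal observatory:
# 120 monthly samples, two organismal size fractions (picoplankton 0.2-3 um,
# nanoplankton 3-20 um), two domains (bacteria, protists), multinomial read
# sampling at a fixed rarefaction depth, seasonally structured dynamics
# driven by temperature/daylength, planted direct OTU-OTU associations,
# planted environmentally driven OTU pairs, and blocks of missing
# nanoplankton months. Ground truth for every planting is returned so the
# downstream stages can be scored.

#' Configuration for the synthetic community generator
#'
#' Defaults mirror the emulated study design: 120 monthly samples over ten
#' years, read depth 4907, two domains times two size fractions, and missing
#' nanoplankton months (one block of 27 consecutive months plus two isolated
#' months).
#'
#' @param n_otus_per_table OTUs per (domain x size fraction) table
#' @param n_months number of consecutive monthly samples
#' @param read_depth multinomial read depth per sample (reads)
#' @param seasonal_fraction proportion of OTUs given a seasonal niche
#' @param n_direct_pairs planted direct OTU-OTU associations
#' @param n_env_driven_pairs planted environmentally driven OTU pairs
#' @param noise_sd log-scale noise SD of latent dynamics (dimensionless)
#' @param coupling log-scale effect size of planted drivers
#' @param planted_base_meanlog,planted_base_sdlog log-normal parameters of
#'   the baseline abundance of planted OTUs; the default floor keeps planted
#'   pairs above the multinomial counting noise so that the planted classes
#'   are identifiable (low-abundance OTUs cannot carry detectably strong
#'   associations at a finite read depth)
#' @param frac_shared fraction of each table's OTUs also leaking into the
#'   other size fraction of the same domain (exercises the 2:1 ratio rule)
#' @param positive_fraction fraction of planted direct pairs with positive sign
#' @param missing_blocks named list: for tables whose name matches an entry
#'   ("nano" or a full table name), the 1-based month indices that are absent
#' @param latitude degrees north, for the photoperiod model
#' @param start_year first calendar year of the series
#' @param seed integer; fully determines the output
#' @return a `synth_config` list
#' @export
synth_config <- function(n_otus_per_table = 75, n_months = 120,
                         read_depth = 4907, seasonal_fraction = 0.6,
                         n_direct_pairs = 20, n_env_driven_pairs = 20,
                         noise_sd = 0.3, coupling = 1.2,
                         planted_base_meanlog = 1.2,
                         planted_base_sdlog = 0.4, frac_shared = 0.15,
                         positive_fraction = 0.9,
                         missing_blocks = list(nano = c(3L, 14L, 77:103)),
                         latitude = 41.67, start_year = 2004, seed = 1L) {
  stopifnot(n_otus_per_table >= 1, n_months >= 12, read_depth >= 1,
            seasonal_fraction >= 0, seasonal_fraction <= 1,
            n_direct_pairs >= 0, n_env_driven_pairs >= 0, noise_sd >= 0)
  structure(list(
    n_otus_per_table = as.integer(n_otus_per_table),
    n_months = as.integer(n_months), read_depth = as.integer(read_depth),
    seasonal_fraction = seasonal_fraction,
    n_direct_pairs = as.integer(n_direct_pairs),
    n_env_driven_pairs = as.integer(n_env_driven_pairs),
    noise_sd = noise_sd, coupling = coupling,
    planted_base_meanlog = planted_base_meanlog,
    planted_base_sdlog = planted_base_sdlog, frac_shared = frac_shared,
    positive_fraction = positive_fraction, missing_blocks = missing_blocks,
    latitude = latitude, start_year = as.integer(start_year),
    seed = as.integer(seed)), class = "synth_config")
}

#' Day length from the CBM photoperiod model
#'
#' Deterministic hours of light on a given day of year at a given latitude
#' (Forsythe et al. 1995 coefficients, daylength coefficient 0.8333 degrees,
#' the standard sunrise/sunset definition).
#'
#' @param day_of_year integer day 1-365
#' @param latitude degrees north
#' @return hours of light, in (0, 24)
#' @export
daylength_cbm <- function(day_of_year, latitude) {
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  phi <- asin(0.39795 * cos(theta))
  L <- latitude * pi / 180
  x <- (sin(0.8333 * pi / 180) + sin(L) * sin(phi)) / (cos(L) * cos(phi))
  24 - (24 / pi) * acos(pmin(1, pmax(-1, x)))
}

#' Generate a monthly environmental series
#'
#' Fifteen contextual variables: deterministic day length (CBM photoperiod
#' formula evaluated on day 15 of each month), a sinusoidal temperature with
#' seeded noise, and thirteen further variables (nutrients, chlorophyll,
#' Secchi depth, salinity and plankton cell counts) built as seasonal signals
#' with multiplicative noise.
#'
#' @param n_months number of months (>= 12)
#' @param latitude degrees north
#' @param seed integer seed
#' @param start_year first calendar year (month stamps start in January)
#' @return data.frame of class `env_series`: `month`, `month_index` and 15
#'   numeric variables; no missing values
#' @export
generate_environment <- function(n_months, latitude = 41.67, seed = 1L,
                                 start_year = 2004) {
  if (n_months < 12) stop("n_months must be at least 12")
  set.seed(seed)
  stamps <- month_stamps(n_months, start_year)
  moy <- month_of_year(stamps)
  doy_mid <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))[1:12] + 15
  daylength <- daylength_cbm(doy_mid[moy], latitude)
  season_wave <- function(peak_month, rel_amp) {
    1 + rel_amp * cos(2 * pi * (moy - peak_month) / 12)
  }
  lnoise <- function(sd = 0.2) exp(rnorm(n_months, 0, sd))
  temperature <- 18.5 + 6 * cos(2 * pi * (moy - 8) / 12) +
    rnorm(n_months, 0, 0.5)
  env <- data.frame(
    month = stamps, month_index = seq_len(n_months) - 1L,
    temperature = temperature, daylength = daylength,
    secchi = 12 * season_wave(7, 0.3) * lnoise(0.15),
    salinity = 38 + 0.2 * cos(2 * pi * (moy - 9) / 12) +
      rnorm(n_months, 0, 0.1),
    chla = 0.6 * season_wave(3, 0.8) * lnoise(0.3),
    po4 = 0.10 * season_wave(2, 0.6) * lnoise(0.3),
    nh4 = 0.50 * season_wave(2, 0.5) * lnoise(0.3),
    no2 = 0.15 * season_wave(1, 0.6) * lnoise(0.3),
    no3 = 1.50 * season_wave(1, 0.7) * lnoise(0.3),
    sio2 = 1.20 * season_wave(1, 0.6) * lnoise(0.3),
    hp = 1e6 * season_wave(8, 0.3) * lnoise(0.25),
    synechococcus = 5e4 * season_wave(8, 0.8) * lnoise(0.35),
    pnf = 2e3 * season_wave(4, 0.6) * lnoise(0.3),
    small_pnf = 1.5e3 * season_wave(4, 0.6) * lnoise(0.3),
    hnf = 1e3 * season_wave(6, 0.4) * lnoise(0.3),
    stringsAsFactors = FALSE)
  class(env) <- c("env_series", "data.frame")
  env
}

#' Numeric variable matrix of an environmental series
#'
#' @param env an `env_series` data.frame
#' @return numeric matrix, variables x months, month stamps as column names
#' @export
env_matrix <- function(env) {
  vars <- setdiff(names(env), c("month", "month_index"))
  m <- t(as.matrix(env[, vars, drop = FALSE]))
  colnames(m) <- env$month
  m
}

# deterministic (noise-free) monthly temperature used to label seasons
deterministic_temperature <- function(moy) 18.5 + 6 * cos(2 * pi * (moy - 8) / 12)

#' Generate latent community dynamics and planted ground truth
#'
#' Seasonal OTUs follow a smooth circular Gaussian bump over month-of-year
#' with log-normal amplitude; each planted direct pair shares a smooth latent
#' driver independent of the environment; each environmentally driven pair
#' couples two OTUs to the same environmental variable with independent
#' noise and no shared non-environmental driver.
#'
#' @param config a [synth_config()]
#' @param env an `env_series` covering `config$n_months`
#' @return list with `latent` (OTU x month matrix, domain-level ids),
#'   `assignment` (data.frame of OTU id, domain, fractions, leakage), and
#'   `truth` (a `synth_truth` list: `direct_pairs`, `env_driven_pairs`,
#'   `niche_labels`, using fraction-prefixed node ids)
#' @export
generate_latent_dynamics <- function(config, env) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(env) < config$n_months) stop("env does not cover n_months")
  set.seed(child_seed(config$seed, 2))
  n_months <- config$n_months
  moy <- month_of_year(env$month[seq_len(n_months)])

  n_shared <- round(config$frac_shared * config$n_otus_per_table)
  n_pool <- 2L * config$n_otus_per_table - n_shared  # per domain

  assignment <- do.call(rbind, lapply(c("bacteria", "protist"), function(dom) {
    pre <- if (dom == "bacteria") "b" else "e"
    ids <- sprintf("%s_%05d", pre, seq_len(n_pool))
    frac <- rep(c("pico", "nano", "both"),
                c(config$n_otus_per_table - n_shared,
                  config$n_otus_per_table - n_shared, n_shared))
    data.frame(otu = ids, domain = dom, fractions = frac,
               major = ifelse(frac == "both",
                              sample(c("pico", "nano"), length(ids), TRUE),
                              frac),
               leak = runif(length(ids), 0.1, 0.4),
               stringsAsFactors = FALSE)
  }))
  n_total <- nrow(assignment)

  n_planted <- 2L * (config$n_direct_pairs + config$n_env_driven_pairs)
  single <- which(assignment$fractions != "both")
  if (n_planted > length(single)) {
    stop("more planted pairs than available OTUs")
  }

  # seasonal niches for a fraction of the non-planted OTUs
  planted_idx <- if (n_planted > 0) sample(single, n_planted) else integer(0)
  free_idx <- setdiff(seq_len(n_total), planted_idx)
  n_seasonal <- round(config$seasonal_fraction * length(free_idx))
  seasonal_idx <- if (n_seasonal > 0) sample(free_idx, n_seasonal) else integer(0)

  base <- rlnorm(n_total, meanlog = 0, sdlog = 1)
  if (length(planted_idx) > 0) {
    base[planted_idx] <- rlnorm(length(planted_idx),
                                meanlog = config$planted_base_meanlog,
                                sdlog = config$planted_base_sdlog)
  }
  log_lat <- matrix(rnorm(n_total * n_months, 0, config$noise_sd),
                    nrow = n_total)

  peak_month <- rep(NA_integer_, n_total)
  if (length(seasonal_idx) > 0) {
    peak_month[seasonal_idx] <- sample(1:12, length(seasonal_idx), TRUE)
    amp <- rlnorm(length(seasonal_idx), meanlog = log(2), sdlog = 0.25)
    for (k in seq_along(seasonal_idx)) {
      i <- seasonal_idx[k]
      bump <- exp(-circ_month_dist(moy, peak_month[i])^2 / (2 * 1.5^2))
      log_lat[i, ] <- log_lat[i, ] + amp[k] * bump
    }
  }

  # planted direct pairs: shared smooth latent driver, independent of env
  direct <- NULL
  take <- function(n) {
    out <- planted_idx[seq_len(n)]
    planted_idx <<- planted_idx[-seq_len(n)]
    out
  }
  if (config$n_direct_pairs > 0) {
    rows <- lapply(seq_len(config$n_direct_pairs), function(p) {
      ab <- take(2)
      z <- as.numeric(stats::filter(rnorm(n_months), 0.6, "recursive"))
      z <- (z - mean(z)) / sd(z)
      sgn <- if (runif(1) < config$positive_fraction) 1 else -1
      log_lat[ab[1], ] <<- log_lat[ab[1], ] + config$coupling * z
      log_lat[ab[2], ] <<- log_lat[ab[2], ] + sgn * config$coupling * z
      data.frame(a = ab[1], b = ab[2], sign = ifelse(sgn > 0, "+", "-"),
                 stringsAsFactors = FALSE)
    })
    direct <- do.call(rbind, rows)
  }

  # planted environmentally driven pairs: both coupled to the same variable,
  # independent noise, zero direct coupling
  envd <- NULL
  if (config$n_env_driven_pairs > 0) {
    drivers <- c("temperature", "daylength")
    rows <- lapply(seq_len(config$n_env_driven_pairs), function(p) {
      ab <- take(2)
      v <- sample(drivers, 1)
      e <- env[[v]][seq_len(n_months)]
      e <- (e - mean(e)) / sd(e)
      s1 <- sample(c(1, -1), 1); s2 <- sample(c(1, -1), 1)
      log_lat[ab[1], ] <<- log_lat[ab[1], ] + s1 * config$coupling * e
      log_lat[ab[2], ] <<- log_lat[ab[2], ] + s2 * config$coupling * e
      data.frame(a = ab[1], b = ab[2], var = v, stringsAsFactors = FALSE)
    })
    envd <- do.call(rbind, rows)
  }

  latent <- base * exp(log_lat)
  rownames(latent) <- assignment$otu
  colnames(latent) <- env$month[seq_len(n_months)]

  # truth uses the merged (fraction-prefixed) node ids of downstream stages
  node_id_of <- function(i) {
    frac <- assignment$fractions[i]
    if (frac == "both") frac <- assignment$major[i]
    merged_node_id(assignment$otu[i], frac)
  }
  season_of_peak <- function(pm) {
    t_det <- deterministic_temperature(pm)
    doy_mid <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))[1:12] + 15
    d <- daylength_cbm(doy_mid[pm], config$latitude)
    as.character(assign_season(t_det, d, boundary = "closed-lower"))
  }
  niche <- setNames(rep("none", n_total), vapply(seq_len(n_total),
                                                 node_id_of, ""))
  if (length(seasonal_idx) > 0) {
    niche[vapply(seasonal_idx, node_id_of, "")] <-
      season_of_peak(peak_month[seasonal_idx])
  }
  truth <- structure(list(
    direct_pairs = if (is.null(direct)) {
      data.frame(a = character(), b = character(), sign = character())
    } else {
      data.frame(a = vapply(direct$a, node_id_of, ""),
                 b = vapply(direct$b, node_id_of, ""),
                 sign = direct$sign, stringsAsFactors = FALSE)
    },
    env_driven_pairs = if (is.null(envd)) {
      data.frame(a = character(), b = character(), var = character())
    } else {
      data.frame(a = vapply(envd$a, node_id_of, ""),
                 b = vapply(envd$b, node_id_of, ""),
                 var = envd$var, stringsAsFactors = FALSE)
    },
    niche_labels = niche), class = "synth_truth")

  list(latent = latent, assignment = assignment, truth = truth)
}

#' Multinomial read sampling from latent abundances
#'
#' One count table per domain x size fraction. Every sampled month draws
#' exactly `read_depth` reads with probabilities proportional to the latent
#' abundances of the OTUs present in that table; months listed in
#' `missing_blocks` are absent from the affected (nanoplankton) tables.
#' Shared OTUs appear in their minority fraction scaled by a leakage factor.
#'
#' @param latent OTU x month latent abundance matrix (non-negative)
#' @param assignment OTU assignment data.frame from
#'   [generate_latent_dynamics()]
#' @param config a [synth_config()]
#' @return named list of four [count_table()] objects
#'   (`bacteria_pico`, `bacteria_nano`, `protist_pico`, `protist_nano`)
#' @export
sample_counts <- function(latent, assignment, config) {
  if (any(latent < 0)) stop("latent abundances must be non-negative")
  set.seed(child_seed(config$seed, 3))
  months <- colnames(latent)
  tables <- list()
  for (dom in c("bacteria", "protist")) {
    for (frac in c("pico", "nano")) {
      rows <- assignment$domain == dom &
        (assignment$fractions %in% c(frac, "both"))
      sub <- assignment[rows, , drop = FALSE]
      if (nrow(sub) == 0) next
      lat <- latent[sub$otu, , drop = FALSE]
      # leakage scaling for shared OTUs observed in their minority fraction
      shared_minor <- sub$fractions == "both" & sub$major != frac
      lat[shared_minor, ] <- lat[shared_minor, , drop = FALSE] *
        sub$leak[shared_minor]
      name <- paste(dom, frac, sep = "_")
      keep <- seq_along(months)
      for (key in names(config$missing_blocks)) {
        if (identical(key, frac) || identical(key, name)) {
          keep <- setdiff(keep, config$missing_blocks[[key]])
        }
      }
      lat <- lat[, keep, drop = FALSE]
      if (any(colSums(lat) <= 0)) {
        stop("all-zero latent column in table ", name)
      }
      counts <- vapply(seq_len(ncol(lat)), function(j) {
        as.integer(rmultinom(1, config$read_depth, lat[, j]))
      }, integer(nrow(lat)))
      dimnames(counts) <- list(sub$otu, months[keep])
      tables[[name]] <- count_table(counts, domain = dom,
                                    size_fraction = frac,
                                    depth = config$read_depth)
    }
  }
  tables
}

#' Simulate a full synthetic community data set
#'
#' @param config a [synth_config()]
#' @return list with `tables` (four count tables), `env` (environmental
#'   series), `truth` (planted ground truth) and `config`
#' @export
simulate_community <- function(config = synth_config()) {
  env <- generate_environment(config$n_months, config$latitude,
                              seed = child_seed(config$seed, 1),
                              start_year = config$start_year)
  dyn <- generate_latent_dynamics(config, env)
  tables <- sample_counts(dyn$latent, dyn$assignment, config)
  list(tables = tables, env = env, truth = dyn$truth, config = config)
}

canonical_pairs <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Score predicted edges against planted ground truth
#'
#' @param predicted two-column data.frame or matrix of node-id pairs
#'   (unordered); for `class = "env_driven"` pass the edges flagged and
#'   removed by the indirect-edge stage
#' @param truth a `synth_truth` object
#' @param class which planted class to score
#' @return list with `precision`, `recall`, `n_true`, `n_predicted`,
#'   `n_hit`; precision is `NA` when nothing was predicted
#' @export
evaluate_recovery <- function(predicted, truth,
                              class = c("direct", "env_driven")) {
  class <- match.arg(class)
  stopifnot(inherits(truth, "synth_truth"))
  tr <- if (class == "direct") truth$direct_pairs else truth$env_driven_pairs
  if (nrow(tr) == 0) stop("truth contains no planted ", class, " pairs")
  truth_keys <- canonical_pairs(tr$a, tr$b)
  predicted <- as.data.frame(predicted)
  pred_keys <- if (nrow(predicted) == 0) character(0) else {
    unique(canonical_pairs(as.character(predicted[[1]]),
                           as.character(predicted[[2]])))
  }
  hit <- sum(truth_keys %in% pred_keys)
  list(precision = if (length(pred_keys) == 0) NA_real_ else
         sum(pred_keys %in% truth_keys) / length(pred_keys),
       recall = hit / length(truth_keys),
       n_true = length(truth_keys), n_predicted = length(pred_keys),
       n_hit = hit)
}
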
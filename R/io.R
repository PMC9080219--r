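# File formats, configuration and pipeline orchestration.
#
# Count tables are TSV with OTUs as rows and ISO-8601 year-month columns;
# the environmental table is CSV with a `month` column; networks are
# written as GraphML plus a lossless TSV edge list + node table; ground
# truth and manifests are JSON.

#' Read a count table from TSV
#'
#' @param path TSV file, first column `otu`, remaining columns ISO-8601
#'   year-month stamps with integer counts
#' @param domain,size_fraction table metadata
#' @param depth rarefaction depth, if known
#' @return a [count_table()]
#' @export
read_count_table <- function(path, domain, size_fraction,
                             depth = NA_integer_) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "otu") stop(path, ": first column must be 'otu'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$otu
  bad <- which(is.na(m) | m != floor(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(path, ": non-integer or negative count at OTU '",
         rownames(m)[bad[1, 1]], "', month ", colnames(m)[bad[1, 2]])
  }
  storage.mode(m) <- "integer"
  if (anyDuplicated(colnames(m))) {
    stop(path, ": duplicate sample date ",
         colnames(m)[duplicated(colnames(m))][1])
  }
  count_table(m, domain, size_fraction, depth)
}

#' Write a count table to TSV
#' @param table a [count_table()]
#' @param path output file
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(otu = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an environmental table from CSV
#'
#' @param path CSV with a `month` column (ISO-8601 year-month) and one
#'   numeric column per variable
#' @param months optional expected month stamps; missing ones raise an
#'   error listing them
#' @return an `env_series` data.frame
#' @export
read_env_table <- function(path, months = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"month" %in% names(df)) stop(path, ": needs a 'month' column")
  month_of_year(df$month)
  if (!is.null(months)) {
    miss <- setdiff(months, df$month)
    if (length(miss) > 0) {
      stop(path, ": missing month(s): ", paste(miss, collapse = ", "))
    }
  }
  if (anyNA(df)) stop(path, ": missing values in environmental table")
  if (!"month_index" %in% names(df)) {
    df$month_index <- seq_len(nrow(df)) - 1L
  }
  class(df) <- c("env_series", "data.frame")
  df
}

#' Write an environmental table to CSV
#' @param env an `env_series`
#' @param path output file
#' @export
write_env_table <- function(env, path) {
  write.csv(as.data.frame(env), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a network to GraphML and/or TSV
#'
#' The TSV form is a lossless pair of files: `<prefix>_edges.tsv` (node_a,
#' node_b and every edge attribute) and `<prefix>_nodes.tsv` (node and every
#' vertex attribute).
#'
#' @param g igraph
#' @param prefix output path prefix
#' @param format "tsv", "graphml", or both
#' @return invisible character vector of files written
#' @export
write_network <- function(g, prefix, format = c("tsv", "graphml")) {
  format <- match.arg(format, several.ok = TRUE)
  written <- character(0)
  if ("graphml" %in% format) {
    f <- paste0(prefix, ".graphml")
    igraph::write_graph(g, f, format = "graphml")
    written <- c(written, f)
  }
  if ("tsv" %in% format) {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("node_a", "node_b")
    nl <- igraph::as_data_frame(g, what = "vertices")
    if (ncol(nl) == 0) {
      nl <- data.frame(node = character(igraph::vcount(g)))
    }
    names(nl)[1] <- "node"
    fe <- paste0(prefix, "_edges.tsv"); fn <- paste0(prefix, "_nodes.tsv")
    write.table(el, fe, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(nl, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, fe, fn)
  }
  invisible(written)
}

#' Read a network written by [write_network()] in TSV form
#' @param prefix path prefix used when writing
#' @return igraph
#' @export
read_network_tsv <- function(prefix) {
  el <- read.delim(paste0(prefix, "_edges.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  nl <- read.delim(paste0(prefix, "_nodes.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(nl)[1] <- "name"
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = nl)
}

#' Default pipeline configuration
#'
#' Nested configuration covering every stage; unknown keys in `overrides`
#' are rejected. The global `seed` derives independent per-stage seeds.
#'
#' @param overrides named list of nested overrides
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    synthetic = unclass(synth_config()),
    prep = list(rarefaction_depth = 4907, prevalence_min_fraction = 0.10,
                resident_min_months = 36, ratio_threshold = 2.0,
                resident_whitelist = character(0), impute_k = 2),
    season_niche = list(n_perm_indval = 999, n_perm_niche = 1000,
                        niche_variables = c("temperature", "daylength"),
                        boundary = "closed-lower"),
    lsa = list(max_delay = 0, n_perm = 1000, screen_alpha = 0.05,
               normalization = "median_mad"),
    ended = list(overlap_threshold = 60, n_bins = NULL, n_perm = 100,
                 alpha = 0.05),
    corenet = list(ls_min = 0.7, rho_min = 0.7, q_max = 0.001,
                   prefilter_alpha = 0.05))
  merge_cfg <- function(base, over, path = "") {
    for (k in names(over)) {
      if (!k %in% names(base)) stop("unknown config key: ", path, k)
      if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
        base[[k]] <- merge_cfg(base[[k]], over[[k]], paste0(path, k, "$"))
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  cfg <- merge_cfg(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with (a subset of) the [pipeline_config()] keys
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full core-microbiota pipeline
#'
#' Stages, in order: preprocessing (rarefaction, prevalence filter,
#' size-fraction resolution, seasonal imputation, resident selection),
#' season delineation + indicator values + niche preferences, local
#' similarity analysis, removal of environmentally driven edges, and core
#' network construction and characterization. When `tables`/`env` are not
#' given, a synthetic community is simulated from `config$synthetic`.
#'
#' @param config a [pipeline_config()]
#' @param tables optional named list of [count_table()]s
#'   (domain_fraction names)
#' @param env optional `env_series` (required when `tables` is given)
#' @return result bundle: inputs, resident matrix, season/niche tables,
#'   association tables at each stage, the core network, statistics,
#'   centrality classes, modules, summary counts and a reproducibility
#'   manifest
#' @export
run_pipeline <- function(config = pipeline_config(), tables = NULL,
                         env = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  if (is.null(tables)) {
    sim <- stage("simulate", {
      sc <- do.call(synth_config, utils::modifyList(
        config$synthetic, list(seed = child_seed(config$seed, 10))))
      simulate_community(sc)
    })
    tables <- sim$tables; env <- sim$env; truth <- sim$truth
  }
  if (is.null(env)) stop("env is required when tables are supplied")

  prep <- config$prep
  bundle <- list(config = config, truth = truth)

  prepared <- stage("prep", {
    tables <- lapply(tables, function(t) {
      t <- rarefy_counts(t, prep$rarefaction_depth,
                         seed = child_seed(config$seed, 20))
      filter_prevalence(t, prep$prevalence_min_fraction)
    })
    for (dom in unique(vapply(tables, function(t) t$domain, ""))) {
      pk <- paste0(dom, "_pico"); nk <- paste0(dom, "_nano")
      if (!is.null(tables[[pk]]) && !is.null(tables[[nk]])) {
        r <- resolve_size_fractions(tables[[pk]], tables[[nk]],
                                    prep$ratio_threshold)
        tables[[pk]] <- r$pico; tables[[nk]] <- r$nano
      }
    }
    merged <- merge_count_tables(tables)
    imp <- impute_matrix(merged, k = prep$impute_k)
    residents <- select_residents(imp$values, prep$resident_min_months,
                                  prep$resident_whitelist)
    list(tables = tables, merged = merged, imputed = imp,
         residents = sort(residents))
  })
  resident_mat <- prepared$imputed$values[prepared$residents, , drop = FALSE]
  node_meta <- attr(prepared$merged, "node_meta")

  seasons <- stage("seasons", {
    env_n <- env[seq_len(ncol(resident_mat)), , drop = FALSE]
    labels <- assign_season(env_n$temperature, env_n$daylength,
                            boundary = config$season_niche$boundary)
    iv <- indval(resident_mat, labels,
                 n_perm = config$season_niche$n_perm_indval,
                 seed = child_seed(config$seed, 30))
    niche <- niche_table(resident_mat, env_n,
                         variables = config$season_niche$niche_variables,
                         n_perm = config$season_niche$n_perm_niche,
                         seed = child_seed(config$seed, 31))
    list(labels = labels, indval = iv, niche = niche)
  })

  assoc <- stage("lsa", {
    lc <- lsa_config(max_delay = config$lsa$max_delay,
                     n_perm = config$lsa$n_perm,
                     screen_alpha = config$lsa$screen_alpha,
                     normalization = config$lsa$normalization,
                     seed = child_seed(config$seed, 40))
    build_association_table(resident_mat, standardize_env(env), lc)
  })

  ended <- stage("ended", {
    sig <- assoc[assoc$p < config$corenet$prefilter_alpha, , drop = FALSE]
    for (at in c("n_tests", "env_vars", "months", "normalization")) {
      attr(sig, at) <- attr(assoc, at)
    }
    class(sig) <- class(assoc)
    ec <- ended_config(overlap_threshold = config$ended$overlap_threshold,
                       n_bins = config$ended$n_bins,
                       n_perm = config$ended$n_perm,
                       alpha = config$ended$alpha,
                       seed = child_seed(config$seed, 50))
    remove_indirect(sig, resident_mat, standardize_env(env), ec)
  })

  core <- stage("core", {
    best_season <- setNames(seasons$indval$best_season, seasons$indval$otu)
    best_season[is.na(best_season)] <- "none"
    best_season[!is.na(seasons$indval$p) & seasons$indval$p >= 0.05] <- "none"
    meta <- data.frame(node = rownames(resident_mat),
                       stringsAsFactors = FALSE)
    idx <- match(meta$node, node_meta$node)
    meta$kind <- "otu"
    meta$domain <- node_meta$domain[idx]
    meta$size_fraction <- node_meta$size_fraction[idx]
    meta$season <- unname(best_season[meta$node])
    meta$abundance <- rowSums(resident_mat) / sum(resident_mat)
    env_meta <- data.frame(node = attr(assoc, "env_vars"), kind = "env",
                           domain = NA, size_fraction = NA, season = NA,
                           abundance = NA, stringsAsFactors = FALSE)
    meta <- rbind(meta, env_meta)
    g <- filter_core(ended$associations, config$corenet$ls_min,
                     config$corenet$rho_min, config$corenet$q_max,
                     node_meta = meta)
    metrics <- if (igraph::vcount(g) > 0) node_metrics(g) else NULL
    list(network = g, stats = if (igraph::vcount(g) >= 2) network_stats(g)
           else NULL,
         metrics = metrics,
         central = if (!is.null(metrics)) classify_central(metrics)
           else NULL,
         modules = mcode_modules(g))
  })

  summary <- stage("summary", {
    kind <- igraph::V(core$network)$kind %||% character(0)
    core_nodes <- igraph::V(core$network)$name[kind == "otu"]
    grp <- interaction(node_meta$domain, node_meta$size_fraction, sep = "_")
    data.frame(
      group = levels(grp),
      all = as.integer(table(grp)),
      resident = as.integer(table(grp[node_meta$node %in%
                                        prepared$residents])),
      core = as.integer(table(grp[node_meta$node %in% core_nodes])),
      stringsAsFactors = FALSE)
  })

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("coremicro")),
                   r_version = R.version.string,
                   config_hash = config_hash(config),
                   n_residents = length(prepared$residents),
                   n_core_otus = sum((igraph::V(core$network)$kind %||%
                                        "otu") == "otu"),
                   n_core_edges = igraph::ecount(core$network))

  bundle <- c(bundle, list(
    env = env, prepared = prepared, resident_matrix = resident_mat,
    seasons = seasons, associations = assoc, ended = ended, core = core,
    summary = summary, manifest = manifest))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_assoc_table(assoc, file.path(config$out_dir, "associations.tsv"))
    write_network(core$network, file.path(config$out_dir, "core_network"))
    write.table(summary, file.path(config$out_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

#' Write an association table as TSV with a deterministic row order
#' @param assoc an `assoc_table`
#' @param path output file
#' @export
write_assoc_table <- function(assoc, path) {
  write.table(as.data.frame(assoc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write planted ground truth as JSON
#' @param truth a `synth_truth`
#' @param path output file
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(direct_pairs = truth$direct_pairs,
         env_driven_pairs = truth$env_driven_pairs,
         niche_labels = as.list(truth$niche_labels)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a synthetic data set and write it to disk
#'
#' Writes the four count tables as TSV, the environment as CSV, and the
#' planted truth as JSON.
#'
#' @param config a [synth_config()]
#' @param out_dir output directory (created if needed)
#' @return invisible list of written paths
#' @export
simulate_to_dir <- function(config = synth_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_community(config)
  paths <- list()
  for (nm in names(sim$tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_count_table(sim$tables[[nm]], p)
    paths[[nm]] <- p
  }
  paths$env <- write_env_table(sim$env, file.path(out_dir, "environment.csv"))
  paths$truth <- write_truth(sim$truth, file.path(out_dir, "truth.json"))
  invisible(paths)
}
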
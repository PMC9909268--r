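#' Read a samples-by-taxa count table
#'
#' TSV tables are read with the first column as row labels. Orientation is
#' auto-detected with the heuristic that taxa usually outnumber samples
#' (a table with more rows than columns is assumed to carry taxa in rows
#' and is transposed); pass an explicit orientation to override. BIOM
#' support (JSON, v1) requires the \pkg{biomformat} package.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"biom"}.
#' @param orientation \code{"auto"}, \code{"samples_in_rows"} or
#'   \code{"samples_in_columns"}.
#' @return integer matrix, samples in rows.
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             orientation = c("auto", "samples_in_rows",
                                             "samples_in_columns")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat is required to read BIOM files")
    m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
    m <- t(m)  # biom stores taxa x samples
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                     check.names = FALSE, stringsAsFactors = FALSE)
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad) > 0) {
      col <- bad[1]
      row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   rownames(df)[row], colnames(df)[col]))
    }
    m <- as.matrix(df)
    if (orientation == "samples_in_columns" ||
        (orientation == "auto" && nrow(m) > ncol(m)))
      m <- t(m)
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count at row '%s', column '%s'",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  storage.mode(m) <- "integer"
  m
}

#' Write a count table
#'
#' @param table samples x taxa matrix.
#' @param path output path.
#' @param format \code{"tsv"} (samples in rows, first column
#'   \code{sample_id}) or \code{"biom"} (JSON, via \pkg{biomformat}).
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat is required to write BIOM files")
    biomformat::write_biom(biomformat::make_biom(t(as.matrix(table))), path)
  } else {
    write_tsv_matrix(table, path, "sample_id")
  }
  invisible(path)
}

# Square or rectangular matrix as TSV with a leading label column.
write_tsv_matrix <- function(m, path, label = "id") {
  df <- data.frame(rownames(as.matrix(m)), as.matrix(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric samples-by-variables matrix from TSV
#'
#' For function matrices, design-free numeric tables and square distance
#' matrices written by this package.
#'
#' @param path file path; first column holds row labels.
#' @return numeric matrix.
#' @export
read_numeric_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' Pipeline run configuration
#'
#' Collects everything a full run needs: the simulation configuration (or
#' file inputs), analysis thresholds, permutation counts and the master
#' seed. Thresholds default to the analysis conventions used throughout the
#' package: edges at |r| > 0.6 and p < 0.01, core taxa at prevalence > 60%
#' and mean relative abundance > 0.1%, assembly cutoffs |beta-NTI| = 2 and
#' |RCbray| = 0.95, 999 permutations.
#'
#' @param design design table (default: the full 96-sample factorial).
#' @param sim_config a \code{\link{simulation_config}} used when no input
#'   tables are given.
#' @param kingdoms kingdom names to simulate.
#' @param count_tables optional named list of count matrices (skips
#'   simulation).
#' @param phylogeny optional tree (simulated otherwise).
#' @param function_matrix optional samples x functions matrix; \code{NULL}
#'   skips the multifunctionality stage when no simulation is requested.
#' @param r_threshold,p_threshold,prevalence,mean_rel_abund,bnti_threshold,rc_threshold
#'   analysis thresholds.
#' @param n_perm,n_null,n_boot permutation/null/bootstrap counts.
#' @param seed master seed; every stage derives its own substream from it.
#' @param out_dir output directory (created); \code{NULL} disables file
#'   output.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(design = generate_design(),
                       sim_config = simulation_config(),
                       kingdoms = c("bacteria", "fungi", "protist"),
                       count_tables = NULL, phylogeny = NULL,
                       function_matrix = NULL,
                       r_threshold = 0.6, p_threshold = 0.01,
                       prevalence = 0.60, mean_rel_abund = 0.001,
                       bnti_threshold = 2, rc_threshold = 0.95,
                       n_perm = 999, n_null = 999, n_boot = 100,
                       seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

pipeline_stage <- function(manifest, name, code) {
  res <- tryCatch(list(value = code, status = "complete"),
                  error = function(e)
                    list(value = NULL,
                         status = paste0("failed: ", conditionMessage(e))))
  manifest$stages[[name]] <- res$status
  list(manifest = manifest, value = res$value)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study's downstream flow on simulated or supplied data:
#' simulate (when no tables are given), core-ASV filtering and cross-kingdom
#' concatenation, alpha/beta diversity with PERMANOVA by season,
#' multifunctionality with a seasonal comparison, beta-NTI + RCbray assembly
#' classification, SparCC network with node roles, and the
#' natural-connectivity robustness curve. A machine-readable manifest
#' (package version, seed, thresholds, stage statuses) is part of the
#' result and, when \code{out_dir} is set, written as JSON next to the
#' stage outputs (TSV matrices, Newick tree, GraphML network).
#'
#' @param config a \code{\link{run_config}}.
#' @return list with the per-stage results and the manifest; invisibly.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(package = "floodmicro",
                   version = as.character(packageVersion("floodmicro")),
                   seed = config$seed,
                   thresholds = config[c("r_threshold", "p_threshold",
                                         "prevalence", "mean_rel_abund",
                                         "bnti_threshold", "rc_threshold",
                                         "n_perm", "n_null", "n_boot")],
                   stages = list())
  out <- list()

  # --- simulate -------------------------------------------------------
  st <- pipeline_stage(manifest, "simulate", {
    if (is.null(config$count_tables)) {
      tree <- config$phylogeny
      if (is.null(tree))
        tree <- generate_phylogeny(config$sim_config$n_taxa,
                                   seed = config$sim_config$seed)
      tabs <- lapply(seq_along(config$kingdoms), function(k) {
        cfg <- config$sim_config
        cfg$seed <- substream_seed(cfg$seed, 100 + k)
        generate_community_counts(tree, config$design, cfg)
      })
      names(tabs) <- config$kingdoms
      fm <- config$function_matrix
      if (is.null(fm))
        fm <- generate_function_matrix(config$design, config$sim_config)
      list(tables = tabs, tree = tree, function_matrix = fm,
           simulated = TRUE)
    } else {
      list(tables = config$count_tables, tree = config$phylogeny,
           function_matrix = config$function_matrix, simulated = FALSE)
    }
  })
  manifest <- st$manifest; data <- st$value
  if (is.null(data)) stop("simulation/input stage failed: ",
                          manifest$stages$simulate)
  manifest$inputs <- lapply(data$tables, function(t)
    list(samples = nrow(t), taxa = ncol(t), total = sum(t)))

  # --- core filter ----------------------------------------------------
  st <- pipeline_stage(manifest, "core_filter",
    combine_kingdoms(data$tables, config$prevalence, config$mean_rel_abund))
  manifest <- st$manifest; core <- st$value

  # --- diversity ------------------------------------------------------
  st <- pipeline_stage(manifest, "diversity", {
    tab <- data$tables[[1]]
    alpha <- alpha_diversity(tab, data$tree)
    bc <- bray_curtis(tab)
    grouping <- config$design$season[match(rownames(tab),
                                           config$design$sample_id)]
    pmv <- permanova(bc, grouping, n_perm = config$n_perm,
                     seed = substream_seed(config$seed, 201))
    list(alpha = alpha, bray_curtis = bc, permanova_season = pmv)
  })
  manifest <- st$manifest; out$diversity <- st$value

  # --- multifunctionality --------------------------------------------
  if (is.null(data$function_matrix)) {
    manifest$stages$multifunctionality <- "skipped"
  } else {
    st <- pipeline_stage(manifest, "multifunctionality", {
      std <- min_max_standardize(data$function_matrix)
      idx <- multifunctionality_index(std)
      season <- config$design$season[match(names(idx),
                                           config$design$sample_id)]
      cmp <- compare_groups(idx, season)
      mant <- NULL
      if (!is.null(out$diversity)) {
        dfun <- as.matrix(dist(std))
        mant <- mantel_test(out$diversity$bray_curtis, dfun,
                            n_perm = config$n_perm,
                            seed = substream_seed(config$seed, 202))
      }
      list(standardized = std, index = idx, season_comparison = cmp,
           mantel_community_function = mant)
    })
    manifest <- st$manifest; out$multifunctionality <- st$value
  }

  # --- assembly -------------------------------------------------------
  st <- pipeline_stage(manifest, "assembly", {
    tab <- data$tables[[1]]
    bn <- beta_nti(tab, data$tree, n_null = config$n_null,
                   seed = substream_seed(config$seed, 301))
    rc <- raup_crick_bray(tab, n_null = config$n_null,
                          seed = substream_seed(config$seed, 302))
    cls <- classify_processes(bn$bnti, rc, config$bnti_threshold,
                              config$rc_threshold)
    list(beta_nti = bn, rcbray = rc, classification = cls,
         fractions = process_fractions(cls))
  })
  manifest <- st$manifest; out$assembly <- st$value

  # --- network --------------------------------------------------------
  st <- pipeline_stage(manifest, "network", {
    if (is.null(core) || ncol(core$counts) < 4)
      stop("core table too small for network inference")
    r <- sparcc_correlations(core$counts,
                             seed = substream_seed(config$seed, 401))
    p <- sparcc_pvalues(core$counts, r, n_boot = config$n_boot,
                        seed = substream_seed(config$seed, 402))
    net <- build_network(r, p, config$r_threshold, config$p_threshold,
                         core$kingdom_map)
    if (igraph::ecount(net) > 0) {
      mods <- detect_modules(net, seed = substream_seed(config$seed, 403))
      list(corr = r, p = p, graph = net, modules = mods,
           roles = node_roles(net, mods),
           topology = topology_metrics(net, mods))
    } else list(corr = r, p = p, graph = net, modules = NULL,
                roles = NULL, topology = NULL)
  })
  manifest <- st$manifest; out$network <- st$value

  # --- robustness -----------------------------------------------------
  if (is.null(out$network) || igraph::ecount(out$network$graph) == 0) {
    manifest$stages$robustness <- "skipped"
  } else {
    st <- pipeline_stage(manifest, "robustness",
      robustness_curve(out$network$graph,
                       seed = substream_seed(config$seed, 501)))
    manifest <- st$manifest; out$robustness <- st$value
  }

  out$manifest <- manifest
  out$data <- data
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  invisible(out)
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$out_dir, f)
  for (k in names(out$data$tables))
    write_count_table(out$data$tables[[k]], pth(paste0("counts_", k, ".tsv")))
  if (!is.null(out$data$tree))
    ape::write.tree(out$data$tree, pth("phylogeny.nwk"))
  if (!is.null(out$data$function_matrix))
    write_tsv_matrix(out$data$function_matrix, pth("function_matrix.tsv"),
                     "sample_id")
  if (!is.null(out$diversity)) {
    write.table(out$diversity$alpha, pth("alpha_diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_tsv_matrix(out$diversity$bray_curtis, pth("bray_curtis.tsv"),
                     "sample_id")
  }
  if (!is.null(out$multifunctionality)) {
    write_tsv_matrix(out$multifunctionality$standardized,
                     pth("functions_standardized.tsv"), "sample_id")
    write.table(data.frame(sample_id = names(out$multifunctionality$index),
                           multifunctionality = out$multifunctionality$index),
                pth("multifunctionality_index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$assembly)) {
    write_tsv_matrix(out$assembly$beta_nti$bnti, pth("beta_nti.tsv"),
                     "sample_id")
    write_tsv_matrix(out$assembly$rcbray, pth("rcbray.tsv"), "sample_id")
    write.table(out$assembly$classification, pth("assembly_processes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$network) && igraph::ecount(out$network$graph) > 0) {
    write.table(igraph::as_data_frame(out$network$graph, what = "edges"),
                pth("network_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$network$roles, pth("node_roles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    igraph::write_graph(out$network$graph, pth("network.graphml"),
                        format = "graphml")
  }
  if (!is.null(out$robustness))
    write.table(out$robustness, pth("robustness_curve.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
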
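#' Simulation configuration for synthetic communities
#'
#' Bundles every tunable of the synthetic-data generators. Defaults emulate a
#' conventional amplicon survey: 200 taxa, 10,000 reads per sample, moderate
#' dispersal limitation, and a uniform negative autumn effect on all 20
#' ecosystem-function variables.
#'
#' @param n_taxa number of taxa (phylogeny tips).
#' @param depth sequencing depth; every sample's counts sum to this.
#' @param assembly_mode \code{"selection"} (niche filtering on a
#'   phylogenetically conserved trait) or \code{"neutral"} (one shared
#'   metacommunity, dispersal-limited drift only).
#' @param filtering_strength selection intensity; the Gaussian niche filter
#'   has width \code{1/filtering_strength}, so 0 disables filtering.
#' @param dispersal in \[0,1\]; 1 means every sample draws from the shared
#'   metacommunity exactly, lower values mix in sample-specific drift.
#' @param season_effect numeric vector of raw-scale shifts subtracted from
#'   autumn samples, one per function variable (recycled to length
#'   \code{n_functions}).
#' @param noise_sd Gaussian noise standard deviation for function variables.
#' @param n_functions number of ecosystem-function variables.
#' @param planted_edges data.frame with columns \code{taxon_i},
#'   \code{taxon_j}, \code{rho} (signed log-scale correlation) for
#'   \code{\link{generate_correlated_counts}}; may be empty.
#' @param seed integer master seed; fully determines all generator output.
#' @return a list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_taxa = 200, depth = 10000,
                              assembly_mode = c("selection", "neutral"),
                              filtering_strength = 0, dispersal = 0.8,
                              season_effect = 1.5, noise_sd = 1,
                              n_functions = 20,
                              planted_edges = NULL, seed = 1) {
  assembly_mode <- match.arg(assembly_mode)
  if (n_taxa < 2) stop("n_taxa must be at least 2")
  if (depth <= 0) stop("depth must be a positive integer")
  if (filtering_strength < 0) stop("filtering_strength must be non-negative")
  if (dispersal < 0 || dispersal > 1) stop("dispersal must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  season_effect <- rep_len(season_effect, n_functions)
  if (is.null(planted_edges))
    planted_edges <- data.frame(taxon_i = integer(), taxon_j = integer(),
                                rho = numeric())
  if (nrow(planted_edges) > 0) {
    if (any(planted_edges$taxon_i > n_taxa | planted_edges$taxon_j > n_taxa))
      stop("planted edge taxon indices must not exceed n_taxa")
    if (any(abs(planted_edges$rho) > 1))
      stop("planted correlation magnitudes must lie in [-1, 1]")
  }
  structure(list(n_taxa = as.integer(n_taxa), depth = as.integer(depth),
                 assembly_mode = assembly_mode,
                 filtering_strength = filtering_strength,
                 dispersal = dispersal, season_effect = season_effect,
                 noise_sd = noise_sd, n_functions = as.integer(n_functions),
                 planted_edges = planted_edges, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a fully crossed factorial sampling design
#'
#' Builds the sample metadata table of a replicated factorial field design:
#' every treatment x vegetation x season combination appears exactly
#' \code{replicates} times. The default levels reproduce a 4-replicate x
#' 4-treatment (control, glyphosate, nitrogen, both) x 3-vegetation x
#' 2-season survey of 96 soil samples.
#'
#' @param replicates number of replicates per factor combination.
#' @param treatments,vegetations,seasons character vectors of factor levels.
#' @return data.frame with columns \code{sample_id}, \code{replicate},
#'   \code{treatment}, \code{vegetation}, \code{season}.
#' @examples
#' d <- generate_design()
#' nrow(d)  # 96
#' @export
generate_design <- function(replicates = 4,
                            treatments = c("CK", "G", "N", "GN"),
                            vegetations = c("V1", "V2", "V3"),
                            seasons = c("summer", "autumn")) {
  if (replicates < 1) stop("replicates must be at least 1")
  for (lv in list(treatments, vegetations, seasons))
    if (length(lv) == 0) stop("invalid design: empty factor level list")
  grid <- expand.grid(replicate = seq_len(replicates),
                      treatment = treatments, vegetation = vegetations,
                      season = seasons,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$sample_id <- sprintf("S%03d", seq_len(nrow(grid)))
  grid[, c("sample_id", "replicate", "treatment", "vegetation", "season")]
}

#' Simulate a rooted bifurcating phylogeny
#'
#' Pure-birth (Yule) topology with independent exponential branch lengths,
#' tips labelled \code{ASV_1 ... ASV_n}. The same seed always yields the same
#' tree (byte-identical Newick).
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param branch_rate rate of the exponential branch-length distribution.
#' @return an \code{ape::phylo} object, rooted, with strictly positive
#'   branch lengths.
#' @export
generate_phylogeny <- function(n_tips, seed = 1, branch_rate = 1) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$edge.length <- rexp(nrow(tree$edge), rate = branch_rate)
    tree$tip.label <- paste0("ASV_", seq_len(n_tips))
    tree
  })
}

# Environment optimum per sample: vegetation x season groups are mapped to
# evenly spaced quantiles of the trait distribution, so groups at opposite
# ends experience contrasting filters.
sample_environments <- function(design, trait) {
  grp <- interaction(design$vegetation, design$season, drop = TRUE)
  k <- nlevels(grp)
  env_levels <- quantile(trait, probs = seq(0.1, 0.9, length.out = k),
                         names = FALSE)
  env_levels[as.integer(grp)]
}

#' Simulate an ASV count table with a controlled assembly signal
#'
#' In \code{"selection"} mode a Brownian-motion trait evolves along the
#' phylogeny and each sample filters the shared lognormal metacommunity
#' through a Gaussian niche centred on its group's environmental optimum
#' (width \code{1/filtering_strength}); vegetation-season groups get
#' contrasting optima, producing phylogenetically clustered turnover that
#' beta-NTI detects as deterministic. In \code{"neutral"} mode every sample
#' draws from the same metacommunity with dispersal-limited drift only.
#' Counts are multinomial at \code{config$depth}, so every row sums to the
#' depth exactly.
#'
#' @param phylogeny tree from \code{\link{generate_phylogeny}}; tip count
#'   must equal \code{config$n_taxa}.
#' @param design design table from \code{\link{generate_design}}.
#' @param config a \code{\link{simulation_config}}.
#' @return integer matrix (samples x taxa) with design sample_ids as row
#'   names and tip labels as column names.
#' @export
generate_community_counts <- function(phylogeny, design, config) {
  stopifnot(inherits(config, "simulation_config"))
  n_taxa <- config$n_taxa
  if (length(phylogeny$tip.label) != n_taxa)
    stop("config$n_taxa must equal the phylogeny's tip count")
  if (config$depth <= 0) stop("depth must be positive")
  with_seed(substream_seed(config$seed, 11), {
    # heavy-tailed lognormal rank-abundance: amplicon tables are sparse,
    # so rare taxa must drop out of individual samples at realistic depths
    meta <- exp(rnorm(n_taxa, 0, 2.5))
    meta <- meta / sum(meta)
    trait <- ape::rTraitCont(phylogeny, model = "BM", sigma = 1)
    trait <- trait[phylogeny$tip.label]
    fitness <- matrix(1, nrow(design), n_taxa)
    if (config$assembly_mode == "selection" && config$filtering_strength > 0) {
      # niche width in units of the realized trait spread, so the same
      # filtering_strength means the same selective pressure on any tree
      sigma <- sd(trait) / config$filtering_strength
      env <- sample_environments(design, trait)
      fitness <- exp(-outer(env, trait, "-")^2 / (2 * sigma^2))
    }
    counts <- matrix(0L, nrow(design), n_taxa,
                     dimnames = list(design$sample_id, phylogeny$tip.label))
    conc <- 50  # Dirichlet concentration of sample-level drift
    for (s in seq_len(nrow(design))) {
      base <- meta * fitness[s, ]
      base <- base / sum(base)
      g <- rgamma(n_taxa, shape = conc * base)
      local <- if (sum(g) > 0) g / sum(g) else base
      p <- config$dispersal * base + (1 - config$dispersal) * local
      counts[s, ] <- rmultinom(1, config$depth, p)[, 1]
    }
    counts
  })
}

fm_function_names <- c("AG", "BG", "BX", "NAG", "ALP", "BCE", "TC", "TN",
                       "AK", "ACa", "AMg", "ANa", "ACu", "AFe", "AMn",
                       "AZn", "AP", "pH", "RS", "RH")

#' Simulate a samples-by-functions ecosystem function matrix
#'
#' Each function variable gets a distinct baseline level; autumn samples are
#' shifted down by \code{config$season_effect} (per-variable, raw scale) and
#' Gaussian noise with sd \code{config$noise_sd} is added. With the default
#' 20 variables the columns carry the conventional soil-function names
#' (six extracellular enzymes, total C/N, available nutrients, pH and the
#' two respiration rates).
#'
#' @inheritParams generate_community_counts
#' @return numeric matrix (samples x functions) with sample_ids as row names.
#' @export
generate_function_matrix <- function(design, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$noise_sd < 0) stop("noise_sd must be non-negative")
  nf <- config$n_functions
  eff <- rep_len(config$season_effect, nf)
  nms <- if (nf == 20) fm_function_names else paste0("F", seq_len(nf))
  with_seed(substream_seed(config$seed, 23), {
    base <- 5 + 3 * seq_len(nf)          # distinct raw scales per column
    m <- matrix(rep(base, each = nrow(design)), nrow(design), nf)
    autumn <- design$season == "autumn"
    m[autumn, ] <- sweep(m[autumn, , drop = FALSE], 2, eff, "-")
    m <- m + matrix(rnorm(length(m), 0, config$noise_sd), nrow(m))
    dimnames(m) <- list(design$sample_id, nms)
    m
  })
}

# Nearest positive semi-definite projection by eigenvalue clipping; returns
# a correlation matrix (unit diagonal) and whether clipping was needed.
nearest_psd_corr <- function(sigma, eps = 1e-8) {
  ev <- eigen(sigma, symmetric = TRUE)
  clipped <- any(ev$values < -eps)
  vals <- pmax(ev$values, eps)
  m <- ev$vectors %*% diag(vals, length(vals)) %*% t(ev$vectors)
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  list(corr = m, projected = clipped)
}

#' Simulate count tables with planted log-scale correlations
#'
#' Ground truth for compositional-correlation recovery: taxa get lognormal
#' basis abundances whose log-scale correlation matrix contains the planted
#' pairwise entries (projected to the nearest positive semi-definite
#' correlation matrix by eigenvalue clipping if needed, recorded in the
#' \code{"psd_projected"} attribute), closed to compositions per sample and
#' multinomially sampled at \code{config$depth}.
#'
#' @param config a \code{\link{simulation_config}}; \code{planted_edges}
#'   holds the target edges (may be empty for a null table).
#' @param n_samples number of samples to draw.
#' @return integer count matrix (samples x taxa) with attributes
#'   \code{"planted_edges"} (the ground-truth edge list) and
#'   \code{"psd_projected"}.
#' @export
generate_correlated_counts <- function(config, n_samples) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_samples < 2) stop("n_samples must be at least 2")
  n_taxa <- config$n_taxa
  sigma <- diag(n_taxa)
  pe <- config$planted_edges
  for (k in seq_len(nrow(pe))) {
    i <- pe$taxon_i[k]; j <- pe$taxon_j[k]
    sigma[i, j] <- sigma[j, i] <- pe$rho[k]
  }
  proj <- nearest_psd_corr(sigma)
  with_seed(substream_seed(config$seed, 37), {
    mu <- rnorm(n_taxa, 0, 0.5)
    z <- MASS::mvrnorm(n_samples, mu = mu, Sigma = proj$corr)
    fr <- exp(z)
    fr <- fr / rowSums(fr)
    counts <- t(apply(fr, 1, function(p) rmultinom(1, config$depth, p)[, 1]))
    dimnames(counts) <- list(sprintf("S%03d", seq_len(n_samples)),
                             paste0("ASV_", seq_len(n_taxa)))
    attr(counts, "planted_edges") <- pe
    attr(counts, "psd_projected") <- proj$projected
    counts
  })
}
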
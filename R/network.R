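#' Core-ASV prevalence/abundance filter
#'
#' Keeps taxa strictly exceeding both gates: present in more than
#' \code{prevalence} of the samples and with mean relative abundance above
#' \code{mean_rel_abund}. A taxon present in exactly 60% of samples does not
#' pass the default 0.60 gate.
#'
#' @param table samples x taxa count matrix.
#' @param prevalence occupancy threshold in (0,1); default 0.60.
#' @param mean_rel_abund mean relative-abundance threshold in (0,1);
#'   default 0.001 (0.1%).
#' @return the filtered table (same samples, core taxa only); warns when no
#'   taxon survives.
#' @export
filter_core_asvs <- function(table, prevalence = 0.60,
                             mean_rel_abund = 0.001) {
  table <- as.matrix(table)
  if (prevalence <= 0 || prevalence >= 1 ||
      mean_rel_abund <= 0 || mean_rel_abund >= 1)
    stop("thresholds must lie in (0, 1)")
  occ <- colMeans(table > 0)
  rel <- table / rowSums(table)
  mra <- colMeans(rel)
  keep <- occ > prevalence & mra > mean_rel_abund
  if (!any(keep)) warning("no core taxa pass the prevalence/abundance gates")
  table[, keep, drop = FALSE]
}

#' Combine kingdom tables for cross-kingdom network inference
#'
#' Applies the core-ASV filter per kingdom, converts each table to
#' per-sample relative abundances, and concatenates columns over the shared
#' samples (error when fewer than 4 samples are shared).
#'
#' @param tables named list of samples x taxa count matrices, one per
#'   kingdom.
#' @inheritParams filter_core_asvs
#' @param pseudo_depth common depth used to rescale the relative abundances
#'   back to integer counts (kingdoms are typically sequenced at different
#'   depths, so raw counts are not comparable across tables).
#' @return list with \code{table} (samples x all core taxa, per-sample
#'   relative abundances on the pre-filter totals), \code{counts} (the same
#'   rescaled to integers at \code{pseudo_depth}, suitable for SparCC) and
#'   \code{kingdom_map} (named character vector, taxon -> kingdom).
#' @export
combine_kingdoms <- function(tables, prevalence = 0.60,
                             mean_rel_abund = 0.001, pseudo_depth = 10000) {
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  shared <- Reduce(intersect, lapply(tables, rownames))
  if (length(shared) < 4)
    stop("fewer than 4 samples shared across kingdom tables")
  parts <- lapply(names(tables), function(k) {
    full <- tables[[k]][shared, , drop = FALSE]
    core <- filter_core_asvs(full, prevalence, mean_rel_abund)
    if (ncol(core) == 0) return(NULL)
    colnames(core) <- paste(k, colnames(core), sep = "|")
    sweep(core, 1, rowSums(full), "/")
  })
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0) stop("no kingdom retains any core taxa")
  combined <- do.call(cbind, parts)
  km <- unlist(lapply(names(tables), function(k) {
    nm <- grep(paste0("^", k, "\\|"), colnames(combined), value = TRUE)
    setNames(rep(k, length(nm)), nm)
  }))
  list(table = combined,
       counts = round(combined * pseudo_depth),
       kingdom_map = km)
}

# Solve SparCC basis variances from a log-ratio variance matrix under the
# sparsity assumption (pairwise covariances average out). pairs_included is
# a logical matrix of pairs still in the system.
sparcc_basis_variances <- function(t_mat, pairs_included = NULL) {
  m <- nrow(t_mat)
  if (m < 3) stop("basis-variance system needs at least 3 components")
  if (is.null(pairs_included)) {
    pairs_included <- matrix(TRUE, m, m)
    diag(pairs_included) <- FALSE
  }
  g <- diag(rowSums(pairs_included)) + pairs_included * 1
  b <- rowSums(t_mat * pairs_included)
  drop(solve(g, b))
}

sparcc_corr_from_t <- function(t_mat, basis) {
  basis <- pmax(basis, 1e-10)
  r <- (outer(basis, basis, "+") - t_mat) / (2 * sqrt(outer(basis, basis)))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

# One SparCC pass on one Dirichlet resample of the fractions.
sparcc_single <- function(counts, exclusion_rounds, exclusion_threshold) {
  fr <- t(apply(counts, 1, function(x) {
    g <- rgamma(length(x), shape = x + 1)
    g / sum(g)
  }))
  lf <- log(fr)
  v <- stats::cov(lf)
  t_mat <- outer(diag(v), diag(v), "+") - 2 * v   # var of log ratios
  m <- ncol(counts)
  incl <- matrix(TRUE, m, m); diag(incl) <- FALSE
  r <- sparcc_corr_from_t(t_mat, sparcc_basis_variances(t_mat, incl))
  for (round in seq_len(exclusion_rounds)) {
    a <- abs(r); a[!incl] <- 0
    mx <- max(a)
    if (mx <= exclusion_threshold) break
    ij <- which(a == mx, arr.ind = TRUE)[1, ]
    # keep every component in at least 3 pairs so the system stays solvable
    deg <- rowSums(incl)
    if (deg[ij[1]] <= 3 || deg[ij[2]] <= 3) break
    incl[ij[1], ij[2]] <- incl[ij[2], ij[1]] <- FALSE
    r <- sparcc_corr_from_t(t_mat, sparcc_basis_variances(t_mat, incl))
  }
  r
}

#' SparCC compositional correlations
#'
#' Correlation inference for compositional count data: per iteration, taxon
#' fractions are resampled from a Dirichlet posterior (counts + 1), the
#' log-ratio variance matrix \eqn{T_{ij} = var(\log f_i/f_j)} is formed,
#' basis variances \eqn{t_i} are solved from the linear system implied by
#' the sparsity assumption, and
#' \eqn{r_{ij} = (t_i + t_j - T_{ij}) / (2\sqrt{t_i t_j})}. The most
#' strongly correlated pair above \code{exclusion_threshold} is iteratively
#' removed from the system (up to \code{exclusion_rounds} times) and the
#' final matrix is the average over \code{n_inner_iter} resamples, clipped
#' to \[-1,1\] with unit diagonal.
#'
#' @param table samples x taxa count matrix; >= 4 taxa (the basis-variance
#'   system is underdetermined below that), >= 10 samples recommended.
#' @param n_inner_iter number of Dirichlet resampling iterations.
#' @param exclusion_rounds maximum strongly-correlated-pair exclusions.
#' @param exclusion_threshold |r| above which a pair is excluded from the
#'   basis system.
#' @param seed integer seed.
#' @return symmetric correlation matrix with taxon dimnames.
#' @export
sparcc_correlations <- function(table, n_inner_iter = 20,
                                exclusion_rounds = 10,
                                exclusion_threshold = 0.8, seed = 1) {
  counts <- as.matrix(table)
  if (ncol(counts) < 4) stop("SparCC needs at least 4 taxa")
  if (nrow(counts) < 4) stop("SparCC needs at least 4 samples")
  r <- with_seed(seed, {
    acc <- matrix(0, ncol(counts), ncol(counts))
    for (i in seq_len(n_inner_iter))
      acc <- acc + sparcc_single(counts, exclusion_rounds,
                                 exclusion_threshold)
    acc / n_inner_iter
  })
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(colnames(counts), colnames(counts))
  r
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' Each bootstrap permutes every taxon's counts across samples
#' independently (destroying all true associations while preserving
#' marginals), recomputes SparCC, and the two-sided pseudo p-value is
#' \eqn{(1 + \#\{|r_{boot}| \ge |r_{obs}|\}) / (1 + n_{boot})} — floor
#' \eqn{1/(n_{boot}+1)}, never zero.
#'
#' @inheritParams sparcc_correlations
#' @param observed_r correlation matrix from
#'   \code{\link{sparcc_correlations}}.
#' @param n_boot number of permutation bootstraps (>= 1).
#' @return matrix of pseudo p-values, same shape as \code{observed_r}.
#' @export
sparcc_pvalues <- function(table, observed_r, n_boot = 100, seed = 1,
                           n_inner_iter = 20, exclusion_rounds = 10,
                           exclusion_threshold = 0.8) {
  counts <- as.matrix(table)
  if (n_boot < 1) stop("n_boot must be at least 1")
  hits <- matrix(0, ncol(counts), ncol(counts))
  for (b in seq_len(n_boot)) {
    perm <- with_seed(substream_seed(seed, 1000 + b),
                      apply(counts, 2, sample))
    rb <- sparcc_correlations(perm, n_inner_iter, exclusion_rounds,
                              exclusion_threshold,
                              seed = substream_seed(seed, 2000 + b))
    hits <- hits + (abs(rb) >= abs(observed_r))
  }
  p <- (1 + hits) / (1 + n_boot)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed_r)
  p
}

#' Build a thresholded co-occurrence network
#'
#' Keeps edges with \code{|r| > r_threshold} (strict) and
#' \code{p < p_threshold} (strict); nodes left without any edge are
#' dropped. Edge sign and the network's negative-edge ratio are recorded.
#'
#' @param corr symmetric correlation matrix.
#' @param p matching p-value matrix.
#' @param r_threshold,p_threshold edge gates (defaults |r| > 0.6,
#'   p < 0.01).
#' @param kingdom_map optional named vector taxon -> kingdom, stored as a
#'   vertex attribute.
#' @return an \code{igraph} undirected graph with edge attributes \code{r},
#'   \code{sign}, \code{p}, vertex attribute \code{kingdom}, and graph
#'   attribute \code{negative_edge_ratio}.
#' @export
build_network <- function(corr, p, r_threshold = 0.6, p_threshold = 0.01,
                          kingdom_map = NULL) {
  corr <- as.matrix(corr); p <- as.matrix(p)
  if (!all(dim(corr) == dim(p))) stop("matrices not aligned")
  keep <- abs(corr) > r_threshold & p < p_threshold
  keep[is.na(keep)] <- FALSE
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  nm <- rownames(corr)
  if (is.null(nm)) nm <- paste0("T", seq_len(nrow(corr)))
  if (nrow(idx) == 0) {
    warning("no edges pass the correlation/p-value gates; empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "negative_edge_ratio", NA_real_)
    return(g)
  }
  edges <- data.frame(from = nm[idx[, 1]], to = nm[idx[, 2]],
                      r = corr[idx],
                      sign = ifelse(corr[idx] > 0, "positive", "negative"),
                      p = p[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(kingdom_map))
    g <- igraph::set_vertex_attr(g, "kingdom",
                                 value = unname(kingdom_map[igraph::V(g)$name]))
  igraph::set_graph_attr(g, "negative_edge_ratio",
                         mean(edges$sign == "negative"))
}

#' Topology metrics of a co-occurrence network
#'
#' Vertex and edge counts, mean degree, density \eqn{2E/(N(N-1))},
#' negative-edge ratio, per-node degree / betweenness / closeness
#' centralities, and the modularity of the detected partition.
#'
#' @param net igraph network from \code{\link{build_network}}.
#' @param modules optional result of \code{\link{detect_modules}}; detected
#'   if absent.
#' @param seed seed forwarded to module detection.
#' @return list of metrics; per-node vectors are named by taxon.
#' @export
topology_metrics <- function(net, modules = NULL, seed = 1) {
  n <- igraph::vcount(net)
  if (n == 0 || igraph::ecount(net) == 0) stop("empty network")
  if (is.null(modules)) modules <- detect_modules(net, seed)
  e <- igraph::ecount(net)
  list(n_nodes = n, n_edges = e,
       mean_degree = 2 * e / n,
       density = 2 * e / (n * (n - 1)),
       negative_edge_ratio = igraph::graph_attr(net, "negative_edge_ratio"),
       degree = igraph::degree(net),
       betweenness = igraph::betweenness(net, normalized = TRUE),
       closeness = suppressWarnings(igraph::closeness(net,
                                                      normalized = TRUE)),
       modularity = modules$modularity)
}

#' Detect network modules by greedy modularity maximization
#'
#' Fast-greedy community detection on absolute edge weights (sign ignored
#' for partitioning); deterministic given the seed.
#'
#' @inheritParams topology_metrics
#' @return list with \code{membership} (named integer vector) and
#'   \code{modularity} (Q of the partition).
#' @export
detect_modules <- function(net, seed = 1) {
  if (igraph::vcount(net) == 0) stop("empty network")
  w <- abs(igraph::E(net)$r)
  if (length(w) == 0) w <- NULL
  cl <- with_seed(seed, igraph::cluster_fast_greedy(net, weights = w))
  mem <- igraph::membership(cl)
  list(membership = setNames(as.integer(mem), names(mem)),
       modularity = igraph::modularity(net, mem, weights = w))
}

#' Zi-Pi node role classification
#'
#' Within-module degree z-score \eqn{Z_i = (k_{i,own} - \bar k_{own}) /
#' sd(k_{own})} (over the node's module; 0 with a flag when the module is a
#' singleton or has zero spread) and among-module participation
#' \eqn{C_i = 1 - \sum_m (k_{im}/k_i)^2}. Roles: network hub (Z > 2.5,
#' C > 0.62), module hub (Z > 2.5, C <= 0.62), connector (Z <= 2.5,
#' C > 0.62), peripheral otherwise.
#'
#' @inheritParams topology_metrics
#' @param modules result of \code{\link{detect_modules}}.
#' @param z_threshold,c_threshold role cutoffs (defaults 2.5 and 0.62).
#' @return data.frame per node: name, module, degree, z, c, role,
#'   z_degenerate flag.
#' @export
node_roles <- function(net, modules, z_threshold = 2.5, c_threshold = 0.62) {
  mem <- modules$membership
  nodes <- igraph::V(net)$name
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  adj <- (adj > 0) * 1
  k <- rowSums(adj)
  mods <- sort(unique(mem))
  # k_im: edges from node i into module m
  kim <- sapply(mods, function(m) rowSums(adj[, mem == m, drop = FALSE]))
  if (is.null(dim(kim))) kim <- matrix(kim, ncol = length(mods))
  k_own <- kim[cbind(seq_along(nodes), match(mem[nodes], mods))]
  z <- numeric(length(nodes))
  z_degenerate <- logical(length(nodes))
  for (m in mods) {
    in_m <- mem[nodes] == m
    mu <- mean(k_own[in_m]); s <- sd(k_own[in_m])
    if (sum(in_m) < 2 || is.na(s) || s == 0) {
      z[in_m] <- 0
      z_degenerate[in_m] <- TRUE
    } else z[in_m] <- (k_own[in_m] - mu) / s
  }
  cc <- 1 - rowSums((kim / k)^2)
  role <- classify_node_role(z, cc, z_threshold, c_threshold)
  data.frame(name = nodes, module = unname(mem[nodes]),
             degree = unname(k), z = z, c = unname(cc), role = role,
             z_degenerate = z_degenerate, stringsAsFactors = FALSE)
}

#' Node role from within-module degree z-score and participation
#'
#' The Guimera-Amaral quadrants: network hub (Z > 2.5 and C > 0.62),
#' module hub (Z > 2.5, C <= 0.62), connector (Z <= 2.5, C > 0.62),
#' peripheral otherwise. Vectorized.
#'
#' @param z within-module degree z-score(s).
#' @param c_score participation coefficient(s) in \[0, 1\].
#' @param z_threshold,c_threshold quadrant cutoffs.
#' @return character vector of roles.
#' @export
classify_node_role <- function(z, c_score, z_threshold = 2.5,
                               c_threshold = 0.62) {
  ifelse(z > z_threshold & c_score > c_threshold, "network hub",
  ifelse(z > z_threshold, "module hub",
  ifelse(c_score > c_threshold, "connector", "peripheral")))
}

#' Natural connectivity of a graph
#'
#' \eqn{\bar\lambda = \ln\left(\frac{1}{N}\sum_i e^{\lambda_i}\right)} with
#' \eqn{\lambda_i} the eigenvalues of the unweighted adjacency matrix: a
#' spectral measure of the redundancy of alternative paths used as a
#' robustness index. Zero for an edgeless graph; computed with a
#' log-sum-exp guard for large graphs.
#'
#' @param net igraph graph or adjacency matrix; at least 1 node.
#' @return natural connectivity (>= 0 for simple graphs).
#' @export
natural_connectivity <- function(net) {
  adj <- if (inherits(net, "igraph"))
    igraph::as_adjacency_matrix(net, sparse = FALSE) else as.matrix(net)
  n <- nrow(adj)
  if (n < 1) stop("graph must have at least 1 node")
  adj <- (adj != 0) * 1
  lam <- eigen((adj + t(adj)) / 2, symmetric = TRUE,
               only.values = TRUE)$values
  mx <- max(lam)
  mx + log(sum(exp(lam - mx))) - log(n)
}

#' Robustness curve under random node removal
#'
#' For each removal fraction, removes that share of nodes uniformly at
#' random (without replacement), recomputes natural connectivity on the
#' remaining graph, and averages over replicates. Fraction 0 is the intact
#' value exactly (no sampling).
#'
#' @param net igraph network.
#' @param fractions removal fractions in \[0, 1).
#' @param n_reps random replicates per fraction.
#' @param seed integer seed.
#' @return data.frame with columns \code{fraction},
#'   \code{natural_connectivity} (mean over replicates) and \code{sd}.
#' @export
robustness_curve <- function(net, fractions = seq(0, 0.8, by = 0.1),
                             n_reps = 30, seed = 1) {
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1)")
  if (n_reps < 1) stop("n_reps must be at least 1")
  n <- igraph::vcount(net)
  intact <- natural_connectivity(net)
  rows <- with_seed(seed, lapply(fractions, function(f) {
    if (f == 0)
      return(data.frame(fraction = 0, natural_connectivity = intact, sd = 0))
    n_rm <- floor(f * n)
    vals <- replicate(n_reps, {
      drop_v <- sample(n, n_rm)
      natural_connectivity(igraph::delete_vertices(net, drop_v))
    })
    data.frame(fraction = f, natural_connectivity = mean(vals),
               sd = sd(vals))
  }))
  do.call(rbind, rows)
}
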
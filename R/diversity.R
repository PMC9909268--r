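#' Observed richness of one sample
#'
#' @param counts non-negative numeric vector of taxon counts.
#' @return number of taxa with count > 0.
#' @export
observed_richness <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  sum(counts > 0)
}

#' Shannon diversity of one sample
#'
#' \eqn{H = -\sum p_i \ln p_i} over taxa with positive counts, natural log
#' (so the uniform S-taxon community attains ln S).
#'
#' @inheritParams observed_richness
#' @return Shannon entropy (nats).
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero sample: Shannon index undefined")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Faith's phylogenetic diversity of one sample
#'
#' Sum of branch lengths of the minimal subtree spanning the present taxa
#' and the root (rooted-PD convention: a single-taxon community has the
#' positive PD of its root path; conventions differ, some exclude the root
#' path).
#'
#' @inheritParams observed_richness
#' @param phylogeny rooted \code{ape::phylo} with branch lengths; names of
#'   \code{counts} must be tip labels.
#' @return Faith's PD; 0 for an empty community.
#' @export
faith_pd <- function(counts, phylogeny) {
  if (is.null(names(counts))) stop("counts must be named by taxon")
  present <- names(counts)[counts > 0]
  if (length(present) == 0) return(0)
  missing <- setdiff(present, phylogeny$tip.label)
  if (length(missing) > 0)
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  tr <- ape::reorder.phylo(phylogeny, "postorder")
  n_tip <- length(tr$tip.label)
  has <- logical(n_tip + tr$Nnode)
  has[match(present, tr$tip.label)] <- TRUE
  pd <- 0
  for (e in seq_len(nrow(tr$edge))) {           # postorder: children first
    child <- tr$edge[e, 2]
    if (has[child]) {
      pd <- pd + tr$edge.length[e]
      has[tr$edge[e, 1]] <- TRUE
    }
  }
  pd
}

#' Alpha diversity summary for a count table
#'
#' @param table samples x taxa count matrix.
#' @param phylogeny optional tree for Faith's PD.
#' @return data.frame with observed richness, Shannon index and (if a tree
#'   is supplied) Faith's PD per sample.
#' @export
alpha_diversity <- function(table, phylogeny = NULL) {
  table <- as.matrix(table)
  out <- data.frame(sample_id = rownames(table),
                    observed = apply(table, 1, observed_richness),
                    shannon = apply(table, 1, shannon_index))
  if (!is.null(phylogeny))
    out$faith_pd <- apply(table, 1, faith_pd, phylogeny = phylogeny)
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(a,b) = \sum_i |a_i-b_i| / \sum_i (a_i+b_i)}, bounded in \[0,1\].
#' A pair of all-zero samples has no defined dissimilarity and is an error.
#'
#' @param table samples x taxa count (or abundance) matrix, >= 2 samples.
#' @return square symmetric matrix with sample labels.
#' @export
bray_curtis <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2) stop("need at least 2 samples")
  if (any(table < 0)) stop("counts must be non-negative")
  zero <- rowSums(table) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined for all-zero sample pair(s): ",
         paste(rownames(table)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(table, method = "bray"))
}

# Pseudo-F of a one-factor partition of a distance matrix:
# among/within sum-of-squares decomposition of squared distances.
permanova_f <- function(d2, grouping) {
  n <- nrow(d2)
  lv <- unique(grouping)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in lv) {
    idx <- which(grouping == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  a <- length(lv)
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# All distinct assignments of items to ordered groups of the given sizes;
# rows are assignments, entries are the items in group order.
group_assignments <- function(items, sizes) {
  if (length(sizes) == 1) return(matrix(items, nrow = 1))
  first <- combn(items, sizes[1])
  blocks <- lapply(seq_len(ncol(first)), function(k) {
    rest <- group_assignments(setdiff(items, first[, k]), sizes[-1])
    cbind(matrix(rep(first[, k], each = nrow(rest)), nrow = nrow(rest)), rest)
  })
  do.call(rbind, blocks)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' from the among/within sum-of-squares partition of squared distances, with
#' a permutation p-value \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) /
#' (1 + n_{perm})} (never exactly zero). With \code{exact = TRUE} all
#' distinct assignments of samples to groups are enumerated instead and
#' \eqn{p} is the exact tail fraction (identity included) — feasible for
#' small n only.
#'
#' @param dist square symmetric distance matrix (or \code{dist}).
#' @param grouping factor with >= 2 levels, every group of size >= 2.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutations.
#' @param exact enumerate all distinct group assignments instead of
#'   sampling.
#' @return list with \code{f}, \code{p}, \code{n_perm} (or
#'   \code{n_assignments}).
#' @export
permanova <- function(dist, grouping, n_perm = 999, seed = 1, exact = FALSE) {
  d <- as.matrix(dist)
  grouping <- factor(grouping)
  n <- nrow(d)
  if (length(grouping) != n) stop("grouping length must match distance size")
  sizes <- table(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("singleton group: PERMANOVA undefined")
  if (!exact && n_perm < 1) stop("n_perm must be at least 1")
  d2 <- d^2
  f_obs <- permanova_f(d2, grouping)
  if (exact) {
    asg <- group_assignments(seq_len(n), as.integer(sizes))
    lv <- rep(levels(grouping), sizes)
    fs <- apply(asg, 1, function(row) {
      g <- character(n); g[row] <- lv
      permanova_f(d2, g)
    })
    return(list(f = f_obs, p = mean(fs >= f_obs - 1e-12),
                n_assignments = nrow(asg)))
  }
  f_perm <- with_seed(seed, replicate(n_perm, permanova_f(d2, sample(grouping))))
  list(f = f_obs, p = (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a one-sided
#' permutation p-value obtained by jointly permuting rows and columns of the
#' second matrix; \code{exact = TRUE} enumerates all label permutations
#' (n <= 7).
#'
#' @param d1,d2 square symmetric distance matrices with identical labels in
#'   identical order; n >= 4.
#' @inheritParams permanova
#' @return list with \code{r}, \code{p}, and the permutation count.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1, exact = FALSE) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  n <- nrow(m1)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("distance matrix labels differ or are ordered differently")
  if (n < 4) stop("Mantel test needs at least 4 samples")
  ut <- upper.tri(m1)
  r_obs <- cor(m1[ut], m2[ut])
  stat <- function(idx) cor(m1[ut], m2[idx, idx][ut])
  if (exact) {
    if (n > 7) stop("exact enumeration limited to n <= 7")
    perms <- all_permutations(n)
    rs <- apply(perms, 1, stat)
    return(list(r = r_obs, p = mean(rs >= r_obs - 1e-12),
                n_assignments = nrow(perms)))
  }
  if (n_perm < 1) stop("n_perm must be at least 1")
  rs <- with_seed(seed, replicate(n_perm, stat(sample(n))))
  list(r = r_obs, p = (1 + sum(rs >= r_obs - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Derived leaf traits: SLA and LDMC
#'
#' Specific leaf area is leaf area per unit dry mass; leaf dry matter
#' content is dry weight per unit fresh weight (<= 1 whenever dry weight
#' does not exceed fresh weight).
#'
#' @param leaf_area leaf area (e.g. cm^2), > 0.
#' @param leaf_dry_weight dry mass (e.g. g), > 0.
#' @param leaf_fresh_weight fresh mass (same units as dry weight), > 0.
#' @return data.frame with columns \code{sla} and \code{ldmc}.
#' @export
derive_leaf_traits <- function(leaf_area, leaf_dry_weight, leaf_fresh_weight) {
  if (any(leaf_area <= 0) || any(leaf_dry_weight <= 0) ||
      any(leaf_fresh_weight <= 0))
    stop("leaf measurements must be strictly positive")
  data.frame(sla = leaf_area / leaf_dry_weight,
             ldmc = leaf_dry_weight / leaf_fresh_weight)
}
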
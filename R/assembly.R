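#' Within-sample MNTD and MPD
#'
#' Abundance-weighted mean nearest taxon distance
#' \eqn{MNTD = \sum_i f_i \min_{j \ne i} d_{ij}} and mean pairwise distance
#' \eqn{MPD = \sum_{i \ne j} f_i f_j d_{ij} / \sum_{i \ne j} f_i f_j}, with
#' \eqn{f} the relative abundances among present taxa (equal weights when
#' \code{weighted = FALSE}).
#'
#' @param counts named non-negative vector of taxon counts.
#' @param dist patristic distance matrix whose dimnames cover the present
#'   taxa.
#' @param weighted abundance-weight the contributions.
#' @return list with \code{mntd} and \code{mpd}; both \code{NA} when fewer
#'   than 2 taxa are present.
#' @export
mntd_mpd <- function(counts, dist, weighted = TRUE) {
  present <- names(counts)[counts > 0]
  if (length(present) < 2) return(list(mntd = NA_real_, mpd = NA_real_))
  d <- as.matrix(dist)[present, present]
  f <- if (weighted) counts[present] / sum(counts[present])
       else rep(1 / length(present), length(present))
  diag(d) <- Inf
  mntd <- sum(f * apply(d, 1, min))
  diag(d) <- 0
  w <- tcrossprod(f)
  diag(w) <- 0
  mpd <- sum(w * d) / sum(w)
  list(mntd = mntd, mpd = mpd)
}

# Align a count table's columns with a patristic distance matrix.
align_dist <- function(table, dist) {
  d <- as.matrix(dist)
  missing <- setdiff(colnames(table), rownames(d))
  if (length(missing) > 0)
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  d[colnames(table), colnames(table)]
}

#' Between-community mean nearest taxon distance
#'
#' For a pair of samples, the abundance-weighted mean (over both
#' directions) of each present taxon's relative abundance times its
#' patristic distance to the nearest taxon present in the other sample;
#' shared taxa contribute distance zero. Symmetric in its arguments and zero
#' for identical communities.
#'
#' @param sample_a,sample_b named non-negative count vectors over the same
#'   taxa.
#' @inheritParams mntd_mpd
#' @return beta-MNTD value.
#' @export
beta_mntd <- function(sample_a, sample_b, dist, weighted = TRUE) {
  if (sum(sample_a) == 0 || sum(sample_b) == 0)
    stop("empty sample: beta-MNTD undefined")
  comm <- rbind(sample_a, sample_b)
  beta_mntd_matrix(comm, dist, weighted)[1, 2]
}

#' All-pairs beta-MNTD for a count table
#'
#' @param table samples x taxa count matrix with taxon column names.
#' @inheritParams mntd_mpd
#' @return symmetric samples x samples matrix of beta-MNTD values.
#' @export
beta_mntd_matrix <- function(table, dist, weighted = TRUE) {
  table <- as.matrix(table)
  d <- align_dist(table, dist)
  out <- bmntd_pairs_cpp(table, d, weighted)
  dimnames(out) <- list(rownames(table), rownames(table))
  out
}

#' Beta nearest taxon index (beta-NTI)
#'
#' Standardized effect size of beta-MNTD against a tip-shuffling null: taxa
#' keep their per-sample abundances while their positions on the phylogeny
#' are permuted, beta-MNTD is recomputed for every permutation, and
#' \eqn{\beta NTI = (obs - mean_{null}) / sd_{null}}. One tip permutation is
#' drawn per null iteration and applied to all sample pairs. Pairs whose
#' null distribution is degenerate (sd = 0, e.g. on an equidistant star
#' tree) are returned as \code{NA} with the \code{degenerate} flag set.
#' \code{exact = TRUE} enumerates all tip permutations (tree size <= 7) and
#' uses the population standard deviation of the exhaustive null.
#'
#' @param table samples x taxa count matrix; columns must be tree tips.
#' @param phylogeny rooted \code{ape::phylo} with branch lengths.
#' @param n_null number of null permutations (>= 2).
#' @param seed integer seed for the null draws.
#' @param weighted abundance-weighted beta-MNTD (default) or
#'   presence-absence.
#' @param exact exhaustively enumerate tip permutations instead of sampling.
#' @return list with matrices \code{bnti}, \code{bmntd_obs},
#'   \code{null_mean}, \code{null_sd} and logical \code{degenerate}.
#' @export
beta_nti <- function(table, phylogeny, n_null = 999, seed = 1,
                     weighted = TRUE, exact = FALSE) {
  table <- as.matrix(table)
  if (!exact && n_null < 2) stop("n_null must be at least 2")
  d <- align_dist(table, ape::cophenetic.phylo(phylogeny))
  n_taxa <- ncol(table)
  obs <- bmntd_pairs_cpp(table, d, weighted)
  if (exact) {
    if (n_taxa > 7) stop("exact enumeration limited to 7 or fewer taxa")
    perms <- all_permutations(n_taxa)
    nulls <- lapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      bmntd_pairs_cpp(table, d[p, p], weighted)
    })
    k <- length(nulls)
  } else {
    nulls <- with_seed(seed, lapply(seq_len(n_null), function(i) {
      p <- sample(n_taxa)
      bmntd_pairs_cpp(table, d[p, p], weighted)
    }))
    k <- n_null
  }
  arr <- simplify2array(nulls)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (exact) sqrt(apply(arr, c(1, 2), function(x) mean((x - mean(x))^2)))
         else apply(arr, c(1, 2), sd)
  degenerate <- sdv < 1e-12
  bnti <- (obs - mu) / sdv
  bnti[degenerate] <- NA_real_
  diag(bnti) <- NA_real_
  diag(degenerate) <- FALSE
  dn <- list(rownames(table), rownames(table))
  dimnames(bnti) <- dimnames(obs) <- dimnames(mu) <- dimnames(sdv) <-
    dimnames(degenerate) <- dn
  list(bnti = bnti, bmntd_obs = obs, null_mean = mu, null_sd = sdv,
       degenerate = degenerate, n_null = k)
}

# One null community per sample: observed richness drawn from the regional
# pool with probability proportional to occurrence frequency, observed total
# abundance allocated among the drawn taxa proportionally to their mean
# relative abundance (each drawn taxon keeps at least one individual).
rc_null_table <- function(obs, occ, relab) {
  n_taxa <- ncol(obs)
  null <- matrix(0, nrow(obs), n_taxa)
  for (s in seq_len(nrow(obs))) {
    rich <- sum(obs[s, ] > 0)
    total <- sum(obs[s, ])
    chosen <- sample.int(n_taxa, rich, prob = occ)
    counts <- rep(1, rich)
    extra <- total - rich
    if (extra > 0) {
      pr <- relab[chosen]
      if (sum(pr) == 0) pr <- rep(1, rich)
      counts <- counts + rmultinom(1, extra, pr)[, 1]
    }
    null[s, chosen] <- counts
  }
  null
}

#' Raup-Crick dissimilarity with Bray-Curtis (RCbray)
#'
#' Null-model-scaled Bray-Curtis: null communities preserve each sample's
#' richness and total abundance while drawing taxa from the regional pool
#' with probabilities proportional to occurrence frequency (presence) and
#' mean relative abundance (abundance). For each pair,
#' \eqn{RC = 2[(\#\{BC_{null} < BC_{obs}\} + 0.5\,\#\{BC_{null} =
#' BC_{obs}\})/n_{null}] - 1}, bounded in \[-1, 1\].
#'
#' @param table samples x taxa count matrix, >= 2 samples, >= 2 taxa in the
#'   pool.
#' @param n_null number of null communities per pair (>= 2).
#' @param seed integer seed.
#' @return symmetric matrix of RCbray values in \[-1, 1\].
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = 1) {
  obs <- as.matrix(table)
  if (nrow(obs) < 2) stop("need at least 2 samples")
  if (n_null < 2) stop("n_null must be at least 2")
  pool <- colSums(obs) > 0
  if (sum(pool) < 2) stop("degenerate regional pool: fewer than 2 taxa")
  occ <- colMeans(obs > 0)
  occ[!pool] <- 0
  rel <- obs / rowSums(obs)
  relab <- colMeans(rel)
  bc_obs <- as.matrix(vegan::vegdist(obs, method = "bray"))
  S <- nrow(obs)
  less <- eq <- matrix(0, S, S)
  with_seed(seed, {
    for (i in seq_len(n_null)) {
      nul <- rc_null_table(obs, occ, relab)
      bc_null <- as.matrix(vegan::vegdist(nul, method = "bray"))
      less <- less + (bc_null < bc_obs - 1e-12)
      eq <- eq + (abs(bc_null - bc_obs) <= 1e-12)
    }
  })
  rc <- 2 * ((less + 0.5 * eq) / n_null) - 1
  diag(rc) <- NA_real_
  dimnames(rc) <- list(rownames(obs), rownames(obs))
  rc
}

assembly_processes <- c("variable selection", "homogeneous selection",
                        "dispersal limitation", "homogenizing dispersal",
                        "drift")

#' Classify pairwise turnover into five ecological processes
#'
#' Stegen-style decision rule: beta-NTI > +2 is variable (heterogeneous)
#' selection, beta-NTI < -2 homogeneous selection; among the remaining
#' phylogenetically stochastic pairs, RCbray > +0.95 is dispersal
#' limitation, RCbray < -0.95 homogenizing dispersal, and the residual class
#' is drift (undominated). Pairs with an undefined beta-NTI are labelled
#' \code{NA} and excluded from fractions.
#'
#' @param bnti beta-NTI matrix (from \code{\link{beta_nti}}).
#' @param rc RCbray matrix (from \code{\link{raup_crick_bray}}), aligned.
#' @param bnti_threshold,rc_threshold classification cutoffs.
#' @return data.frame with one row per unordered sample pair: sample_a,
#'   sample_b, bnti, rc, process.
#' @export
classify_processes <- function(bnti, rc, bnti_threshold = 2,
                               rc_threshold = 0.95) {
  bnti <- as.matrix(bnti); rc <- as.matrix(rc)
  if (!all(dim(bnti) == dim(rc))) stop("matrices not aligned")
  idx <- which(upper.tri(bnti), arr.ind = TRUE)
  b <- bnti[idx]; r <- rc[idx]
  proc <- ifelse(is.na(b), NA_character_,
          ifelse(b > bnti_threshold, "variable selection",
          ifelse(b < -bnti_threshold, "homogeneous selection",
          ifelse(!is.na(r) & r > rc_threshold, "dispersal limitation",
          ifelse(!is.na(r) & r < -rc_threshold, "homogenizing dispersal",
                 "drift")))))
  nm <- rownames(bnti)
  data.frame(sample_a = if (is.null(nm)) idx[, 1] else nm[idx[, 1]],
             sample_b = if (is.null(nm)) idx[, 2] else nm[idx[, 2]],
             bnti = b, rc = r, process = proc,
             stringsAsFactors = FALSE)
}

#' Relative contribution of the five assembly processes
#'
#' Fractions of classified pairs per process, plus the determinism share
#' (the two selection classes, equivalently the share of pairs with
#' |beta-NTI| above the threshold) and the stochasticity share (the three
#' remaining classes); the two sum to 1.
#'
#' @param classification data.frame from \code{\link{classify_processes}}
#'   (or a character vector of process labels).
#' @return list with \code{fractions} (named, the five processes),
#'   \code{determinism}, \code{stochasticity}, \code{n_classified},
#'   \code{n_unclassified}.
#' @export
process_fractions <- function(classification) {
  labels <- if (is.data.frame(classification)) classification$process
            else as.character(classification)
  n_un <- sum(is.na(labels))
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) stop("no classified pairs")
  bad <- setdiff(unique(labels), assembly_processes)
  if (length(bad) > 0) stop("unknown process label(s): ",
                            paste(bad, collapse = ", "))
  fr <- table(factor(labels, levels = assembly_processes)) / length(labels)
  fr <- setNames(as.numeric(fr), assembly_processes)
  det <- fr[["variable selection"]] + fr[["homogeneous selection"]]
  list(fractions = fr, determinism = det, stochasticity = 1 - det,
       n_classified = length(labels), n_unclassified = n_un)
}
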
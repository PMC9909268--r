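#' Min-max standardize a samples-by-functions matrix
#'
#' Rescales every function variable to \[0,1\] as
#' \code{STD = (X - Xmin) / (Xmax - Xmin)} with the minimum and maximum taken
#' across all samples (pooled over groups; no per-group standardization). A
#' constant column, for which the denominator vanishes, is mapped to all
#' zeros with a warning.
#'
#' @param x numeric matrix or data.frame, samples in rows, function
#'   variables in columns; at least 2 samples.
#' @return numeric matrix of the same shape, every cell in \[0,1\].
#' @examples
#' min_max_standardize(cbind(f = c(2, 4, 6)))  # 0, 0.5, 1
#' @export
min_max_standardize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("function matrix must be numeric")
  if (nrow(x) < 2) stop("standardization needs at least 2 samples")
  if (anyNA(x)) stop("function matrix contains missing values")
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const)) {
    warning("constant column(s) mapped to all zeros: ",
            paste(colnames(x)[const], collapse = ", "))
    span[const] <- 1
  }
  out <- sweep(sweep(x, 2, rng[1, ], "-"), 2, span, "/")
  out[, const] <- 0
  out
}

#' Averaged multifunctionality index
#'
#' The per-sample mean of the min-max standardized function variables: a
#' sample scoring 1 sits at the across-sample maximum of every function, a
#' sample scoring 0 at every minimum.
#'
#' @param standardized matrix from \code{\link{min_max_standardize}}; all
#'   cells must lie in \[0,1\].
#' @return named numeric vector, one index in \[0,1\] per sample.
#' @export
multifunctionality_index <- function(standardized) {
  standardized <- as.matrix(standardized)
  if (ncol(standardized) < 1) stop("no function columns")
  if (anyNA(standardized) || any(standardized < 0 | standardized > 1))
    stop("standardized values must lie in [0, 1]")
  rowMeans(standardized)
}

#' Compare a per-sample index between groups
#'
#' One-way fixed-effects ANOVA across all groups plus Welch t-tests for
#' every group pair, with group means. Degenerate pairs where both groups
#' have zero variance are reported rather than failing: identical constant
#' groups give t = 0, p = 1; separated constant groups give p = 0 with a
#' \code{degenerate} flag.
#'
#' @param index numeric vector (e.g. from
#'   \code{\link{multifunctionality_index}}).
#' @param grouping factor or character vector of the same length; at least 2
#'   groups with at least 2 samples each.
#' @return list with \code{anova} (data.frame: F, df, p), \code{pairwise}
#'   (data.frame per pair: means, t, p, degenerate flag) and
#'   \code{group_means}.
#' @export
compare_groups <- function(index, grouping) {
  grouping <- factor(grouping)
  if (length(index) != length(grouping))
    stop("index and grouping lengths differ")
  sizes <- table(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")

  fit <- summary(aov(index ~ grouping))[[1]]
  anova_tab <- data.frame(F = fit$`F value`[1],
                          df_between = fit$Df[1], df_within = fit$Df[2],
                          p = fit$`Pr(>F)`[1])

  lv <- levels(grouping)
  gm <- tapply(index, grouping, mean)
  pairs <- combn(lv, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- index[grouping == pairs[1, k]]
    b <- index[grouping == pairs[2, k]]
    degenerate <- var(a) == 0 && var(b) == 0
    if (degenerate) {
      if (mean(a) == mean(b)) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
      }
    } else {
      ht <- t.test(a, b, var.equal = FALSE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               mean1 = mean(a), mean2 = mean(b),
               t = tt$statistic, p = tt$p.value, degenerate = degenerate)
  })
  list(anova = anova_tab, pairwise = do.call(rbind, pw),
       group_means = gm)
}
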
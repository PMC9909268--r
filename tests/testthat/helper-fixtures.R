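# Small fixtures built in code, shared across test files.

# Four-tip tree with known branch lengths:
#        +--1--A
#   +-2--+
#   |    +--1--B
# --+
#   |    +--3--C
#   +-1--+
#        +--3--D
toy_tree4 <- function() {
  ape::read.tree(text = "((A:1,B:1):2,(C:3,D:3):1);")
}

# Star tree: every tip at distance b from the root, tip-to-tip 2b.
star_tree <- function(n = 4, b = 1) {
  tips <- paste0(LETTERS[seq_len(n)], ":", b)
  ape::read.tree(text = paste0("(", paste(tips, collapse = ","), ");"))
}

# Independent patristic distances: shortest paths over the tree's edge list
# (igraph), bypassing ape::cophenetic entirely.
patristic_by_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g, v = as.character(seq_len(n_tip)),
                         to = as.character(seq_len(n_tip)))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# Brute-force abundance-weighted beta-MNTD by explicit loops, independent of
# the compiled kernel.
bmntd_loop <- function(a, b, d) {
  pa <- which(a > 0); pb <- which(b > 0)
  fa <- a[pa] / sum(a[pa]); fb <- b[pb] / sum(b[pb])
  sa <- sum(vapply(seq_along(pa), function(i)
    fa[i] * min(d[pa[i], pb]), numeric(1)))
  sb <- sum(vapply(seq_along(pb), function(j)
    fb[j] * min(d[pb[j], pa]), numeric(1)))
  (sa + sb) / 2
}

# Small deterministic count table over a tree's tips.
toy_table <- function(tree, n_samples = 3, seed = 42, depth = 100) {
  withr::with_seed(seed, {
    t(vapply(seq_len(n_samples), function(i)
      rmultinom(1, depth, prob = runif(length(tree$tip.label)))[, 1],
      integer(length(tree$tip.label)))) |>
      `colnames<-`(tree$tip.label) |>
      `rownames<-`(paste0("s", seq_len(n_samples)))
  })
}
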
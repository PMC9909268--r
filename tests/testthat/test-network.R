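test_that("core-ASV filtering applies both gates strictly", {
  # 10 samples; taxon A in 7/10 at 0.2% mean, B in 6/10 (= 60%, dropped),
  # C in 9/10 at ~0.05% (dropped), D abundant everywhere (kept)
  n <- 10
  tab <- cbind(A = c(rep(20, 7), 0, 0, 0),
               B = c(rep(50, 6), rep(0, 4)),
               C = c(rep(5, 9), 0),
               D = rep(9000, n))
  out <- filter_core_asvs(tab)
  expect_true("A" %in% colnames(out))
  expect_true("D" %in% colnames(out))
  expect_false("B" %in% colnames(out))   # prevalence not strictly > 60%
  expect_false("C" %in% colnames(out))   # abundance gate
  expect_warning(filter_core_asvs(tab[, "B", drop = FALSE],
                                  prevalence = 0.99), "no core")
  expect_error(filter_core_asvs(tab, prevalence = 0), "thresholds")
})

test_that("SparCC basis variances solve the log-ratio system exactly", {
  # closed form for 3 components: t1 = (T12 + T13 - T23)/2, etc.
  tm <- matrix(c(0, 0.5, 0.7,
                 0.5, 0, 0.9,
                 0.7, 0.9, 0), 3)
  bv <- floodmicro:::sparcc_basis_variances(tm)
  expect_equal(bv, c((0.5 + 0.7 - 0.9) / 2, (0.5 + 0.9 - 0.7) / 2,
                     (0.7 + 0.9 - 0.5) / 2), tolerance = 1e-12)
  # random m-component system satisfies its defining equations
  withr::with_seed(26, {
    m <- 6
    tm2 <- matrix(runif(m * m), m); tm2 <- tm2 + t(tm2); diag(tm2) <- 0
    bv2 <- floodmicro:::sparcc_basis_variances(tm2)
    for (i in 1:m)
      expect_equal((m - 1) * bv2[i] + sum(bv2[-i]), sum(tm2[i, ]),
                   tolerance = 1e-10)
  })
})

test_that("SparCC correlations are symmetric, bounded and well calibrated", {
  cfg <- simulation_config(n_taxa = 25, depth = 5000, seed = 27)
  x <- generate_correlated_counts(cfg, 60)
  r <- sparcc_correlations(x, seed = 28)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 25))
  expect_true(all(r >= -1 & r <= 1))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.15)
  expect_identical(r, sparcc_correlations(x, seed = 28))
  expect_error(sparcc_correlations(x[, 1:3]), "4 taxa")
})

test_that("SparCC recovers a planted strong positive pair", {
  pe <- data.frame(taxon_i = 1, taxon_j = 2, rho = 0.9)
  cfg <- simulation_config(n_taxa = 15, depth = 10000, planted_edges = pe,
                           seed = 29)
  x <- generate_correlated_counts(cfg, 80)
  r <- sparcc_correlations(x, seed = 30)
  a <- abs(r); diag(a) <- 0
  expect_gt(r[1, 2], 0.6)
  expect_equal(max(a), a[1, 2])   # the planted pair is the strongest
})

test_that("pseudo p-values respect the permutation floor", {
  pe <- data.frame(taxon_i = 1, taxon_j = 2, rho = 0.9)
  cfg <- simulation_config(n_taxa = 6, depth = 10000, planted_edges = pe,
                           seed = 31)
  x <- generate_correlated_counts(cfg, 50)
  r <- sparcc_correlations(x, seed = 32)
  p <- sparcc_pvalues(x, r, n_boot = 100, seed = 33)
  expect_equal(p[1, 2], 1 / 101)
  expect_true(all(p[upper.tri(p)] > 0 & p[upper.tri(p)] <= 1))
  # n_boot = 1: only two attainable values with the +1 correction
  p1 <- sparcc_pvalues(x, r, n_boot = 1, seed = 34)
  expect_true(all(p1[upper.tri(p1)] %in% c(0.5, 1)))
})

test_that("edge gates are strict and signs recorded", {
  r <- matrix(c(1, 0.61, 0.60, -0.7,
                0.61, 1, 0.1, 0.2,
                0.60, 0.1, 1, 0.3,
                -0.7, 0.2, 0.3, 1), 4,
              dimnames = rep(list(c("w", "x", "y", "z")), 2))
  p <- matrix(0.005, 4, 4, dimnames = dimnames(r)); diag(p) <- NA
  net <- build_network(r, p)
  ed <- igraph::as_data_frame(net)
  expect_equal(nrow(ed), 2)
  expect_true(any(ed$sign == "negative" & ed$r == -0.7))
  expect_false(any((ed$from == "w" & ed$to == "y") |
                   (ed$from == "y" & ed$to == "w")))  # r = 0.60 exactly
  expect_equal(igraph::graph_attr(net, "negative_edge_ratio"), 0.5)
  # p gate
  p2 <- p; p2["w", "x"] <- p2["x", "w"] <- 0.02
  ed2 <- igraph::as_data_frame(build_network(r, p2))
  expect_equal(nrow(ed2), 1)
  expect_warning(build_network(r, p, r_threshold = 0.95), "empty")
})

test_that("topology metrics match closed forms", {
  tri <- igraph::make_full_graph(3)
  igraph::E(tri)$r <- 0.8
  tri <- igraph::set_graph_attr(tri, "negative_edge_ratio", 0)
  tm <- topology_metrics(tri)
  expect_equal(tm$density, 1)
  expect_equal(tm$mean_degree, 2)
  path <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  igraph::E(path)$r <- 0.7
  path <- igraph::set_graph_attr(path, "negative_edge_ratio", 0)
  tp <- topology_metrics(path)
  expect_equal(unname(tp$betweenness), c(0, 1, 0))
  withr::with_seed(35, {
    g <- igraph::sample_gnp(20, 0.3)
    igraph::E(g)$r <- runif(igraph::ecount(g), 0.6, 1)
    g <- igraph::set_graph_attr(g, "negative_edge_ratio", 0)
    tg <- topology_metrics(g)
    expect_equal(tg$density,
                 2 * igraph::ecount(g) / (20 * 19), tolerance = 1e-12)
  })
})

test_that("module detection separates disconnected cliques and is seeded", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- paste0("n", 1:9)
  igraph::E(g)$r <- 0.9
  mod <- detect_modules(g, seed = 1)
  expect_equal(length(unique(mod$membership)), 2)
  expect_equal(length(unique(mod$membership[1:5])), 1)
  expect_equal(length(unique(mod$membership[6:9])), 1)
  expect_identical(mod, detect_modules(g, seed = 1))
  # planted two-block graph: most nodes recovered
  withr::with_seed(36, {
    hits <- vapply(1:10, function(i) {
      g2 <- igraph::sample_sbm(40, matrix(c(0.5, 0.02, 0.02, 0.5), 2),
                               c(20, 20))
      igraph::V(g2)$name <- paste0("v", 1:40)
      igraph::E(g2)$r <- 0.8
      m <- detect_modules(g2, seed = i)$membership
      truth <- rep(1:2, each = 20)
      tab <- table(m, truth)
      sum(apply(tab, 1, max)) / 40
    }, numeric(1))
    expect_gt(mean(hits >= 0.9), 0.5)
  })
})

test_that("node roles follow the Zi-Pi definitions and quadrants", {
  expect_equal(classify_node_role(3.0, 0.7), "network hub")
  expect_equal(classify_node_role(3.0, 0.5), "module hub")
  expect_equal(classify_node_role(1.0, 0.7), "connector")
  expect_equal(classify_node_role(1.0, 0.5), "peripheral")
  # C closed forms: all edges inside own module -> 0; 2/2 split -> 0.5
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::add_edges(g, c(1, 5, 1, 6))  # node 1: 3 own + 2 other
  igraph::V(g)$name <- paste0("n", 1:8)
  igraph::E(g)$r <- 0.9
  mod <- detect_modules(g, seed = 1)
  roles <- node_roles(g, mod)
  n2 <- roles[roles$name == "n2", ]
  expect_equal(n2$c, 0)                      # all edges within module
  n1 <- roles[roles$name == "n1", ]
  expect_equal(n1$c, 1 - (3 / 5)^2 - (2 / 5)^2)
  # within-module degrees sum to total degree
  expect_equal(sum(roles$degree),
               sum(igraph::degree(g)))
})

test_that("natural connectivity matches spectra and grows with edges", {
  expect_equal(natural_connectivity(igraph::make_empty_graph(4,
                                                  directed = FALSE)), 0)
  g1 <- igraph::make_graph(c(1, 2), directed = FALSE)
  expect_equal(natural_connectivity(g1), log(cosh(1)), tolerance = 1e-9)
  expect_equal(natural_connectivity(igraph::make_full_graph(3)),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-9)
  # independent oracle: ln(tr(expm(A))/N) via pracma's matrix exponential
  skip_if_not_installed("pracma")
  withr::with_seed(37, {
    for (i in 1:10) {
      g <- igraph::sample_gnp(12, 0.3)
      a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
      expect_equal(natural_connectivity(g),
                   log(sum(diag(pracma::expm(a))) / 12), tolerance = 1e-6)
      # adding one edge strictly increases it
      miss <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
      if (nrow(miss) == 0) next
      e <- miss[sample(nrow(miss), 1), ]
      g2 <- igraph::add_edges(g, e)
      expect_gt(natural_connectivity(g2), natural_connectivity(g))
    }
  })
})

test_that("robustness curves start at the intact value; K10 half = K5", {
  k10 <- igraph::make_full_graph(10)
  rc <- robustness_curve(k10, fractions = c(0, 0.5), n_reps = 4, seed = 2)
  expect_equal(rc$natural_connectivity[1], natural_connectivity(k10))
  expect_equal(rc$sd[1], 0)
  expect_equal(rc$natural_connectivity[2],
               natural_connectivity(igraph::make_full_graph(5)),
               tolerance = 1e-12)
  expect_error(robustness_curve(k10, fractions = c(0, 1)), "fractions")
})
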
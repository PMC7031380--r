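test_that("correlation_matrix computes Spearman rho/p/q symmetrically", {
  x <- 1:10
  prof <- rbind(up = x, up2 = x^2, down = -x + 20, noise = c(5, 1, 4, 2, 6,
                                                             3, 8, 7, 10, 9))
  colnames(prof) <- paste0("s", 1:10)
  cm <- correlation_matrix(prof)
  expect_equal(cm$rho["up", "up2"], 1)
  expect_equal(cm$rho["up", "down"], -1)
  expect_equal(diag(cm$rho), rep(1, 4), ignore_attr = TRUE)
  expect_true(is_sym <- isTRUE(all.equal(cm$rho, t(cm$rho))))
  expect_equal(cm$p["up", "up2"], 0)
  # q is BH over the upper triangle
  up <- upper.tri(cm$p)
  expect_equal(cm$q[up], bh_fdr(cm$p[up]))

  expect_warning(correlation_matrix(rbind(prof, flat = rep(1, 10))),
                 "zero-variance")
  expect_error(correlation_matrix(prof[, 1:3]), ">= 4 samples")
})

test_that("correlation null tail matches an independent permutation null", {
  set.seed(31)
  n <- 12
  obs <- replicate(400, {
    cm <- correlation_matrix(matrix(rnorm(5 * n), 5,
                                    dimnames = list(paste0("f", 1:5),
                                                    paste0("s", 1:n))))
    mean(abs(cm$rho[upper.tri(cm$rho)]) > 0.8)
  })
  # independent oracle: null Spearman rho from shuffled ranks
  null_rho <- replicate(20000, cor(sample(n), sample(n), method = "spearman"))
  expect_lt(abs(mean(obs) - mean(abs(null_rho) > 0.8)), 0.01)
})

test_that("build_network applies both filters and records degrees", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.95
  rho[3, 4] <- rho[4, 3] <- 0.92
  q <- matrix(1, 4, 4); diag(q) <- 0
  q[1, 2] <- q[2, 1] <- 0.001          # only pair (1,2) passes both
  q[3, 4] <- q[4, 3] <- 0.5
  feats <- paste0("g", 1:4)
  dimnames(rho) <- dimnames(q) <- list(feats, feats)
  corr <- structure(list(features = feats, rho = rho, p = q, q = q,
                         n_samples = 10), class = "correlation_matrices")
  net <- build_network(corr, threshold = 0.9, alpha = 0.01)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(sort(c(net$edges$from, net$edges$to)), c("g1", "g2"))
  expect_equal(unname(net$nodes$degree), c(1L, 1L, 0L, 0L))
  expect_equal(net$edges$sign, "positive")

  # threshold 1 with no perfect correlations: empty edge set, nodes kept
  empty <- build_network(corr, threshold = 1, alpha = 0.01)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 4L)

  # all rho = 1: complete graph
  ones <- matrix(1, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  zer <- ones * 0
  corr1 <- structure(list(features = rownames(ones), rho = ones, p = zer,
                          q = zer, n_samples = 10),
                     class = "correlation_matrices")
  comp <- build_network(corr1, threshold = 1, alpha = 0.01)
  expect_equal(nrow(comp$edges), 10L)

  # determinism
  expect_identical(build_network(corr, 0.9, 0.01),
                   build_network(corr, 0.9, 0.01))
})

test_that("raising the threshold never adds edges (monotone filtration)", {
  set.seed(17)
  prof <- simulate_planted_network(25, c(8, 8), n_samples = 30, seed = 2)
  cm <- correlation_matrix(prof)
  sizes <- vapply(seq(0.1, 0.95, by = 0.05), function(s) {
    nrow(build_network(cm, s, alpha = 0.05)$edges)
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("topology matches hand counts on canonical graphs", {
  k3 <- matrix(1, 3, 3) - diag(3)
  t3 <- topology(network_from_adjacency(k3))
  expect_equal(t3$average_degree, 2)
  expect_equal(t3$graph_density, 1)
  expect_equal(t3$average_clustering_coefficient, 1)

  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  tp <- topology(network_from_adjacency(path3))
  expect_equal(tp$average_degree, 4 / 3)
  expect_equal(tp$graph_density, 2 / 3)
  expect_equal(tp$average_clustering_coefficient, 0)

  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- star4[2:4, 1] <- 1
  ts <- topology(network_from_adjacency(star4))
  expect_equal(ts$average_degree, 1.5)
  expect_equal(ts$graph_density, 0.5)
  expect_equal(ts$average_clustering_coefficient, 0)
})

test_that("compare_networks reports elementwise and per-node deltas", {
  k3 <- network_from_adjacency(matrix(1, 3, 3) - diag(3))
  p3 <- network_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  same <- compare_networks(k3, k3)
  expect_equal(same$delta_average_degree, 0)
  expect_equal(unname(same$node_degree_delta), c(0, 0, 0))

  diff_kp <- compare_networks(k3, p3)
  expect_equal(diff_kp$delta_average_degree, 2 - 4 / 3)

  e0 <- network_from_adjacency(matrix(0, 3, 3))
  expect_equal(compare_networks(k3, e0)$delta_graph_density, 1)
})

test_that("rmt threshold detects planted structure and rejects degeneracy", {
  prof <- simulate_planted_network(60, c(15, 15), n_samples = 20, seed = 4)
  cm <- correlation_matrix(prof)
  res <- rmt_threshold(cm$rho)
  expect_true(res$threshold > 0.3 && res$threshold < 0.95)
  expect_s3_class(res$scan, "data.frame")

  expect_error(rmt_threshold(diag(30)), "degenerate")
  expect_error(rmt_threshold(diag(10)), "20 x 20")
})

test_that("network export round-trips through GraphML and TSV", {
  prof <- simulate_planted_network(25, c(10, 10), n_samples = 40, seed = 9)
  cm <- correlation_matrix(prof)
  net <- build_network(cm, 0.6, alpha = 0.05, group = "plusN")
  expect_gt(nrow(net$edges), 0)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$rho, net$edges$rho, tolerance = 1e-9)
})
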
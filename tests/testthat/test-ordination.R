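test_that("bray_curtis matches its definition and the vegan oracle", {
  p <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3),
             d = c(0, 0, 5))
  rownames(p) <- paste0("f", 1:3)
  d <- bray_curtis(p)
  expect_equal(d["a", "c"], 0)                    # identical samples
  expect_equal(d["a", "b"], 4 / 12)               # hand computation
  disj <- cbind(x = c(1, 0), y = c(0, 2))
  expect_equal(bray_curtis(disj)["x", "y"], 1)    # disjoint supports

  set.seed(1)
  q <- matrix(rexp(60), 10, 6, dimnames = list(paste0("f", 1:10),
                                               paste0("s", 1:6)))
  expect_equal(as.dist(bray_curtis(q)), vegan::vegdist(t(q), "bray"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # feature order invariance
  expect_equal(bray_curtis(q[sample(10), ]), bray_curtis(q))
  expect_true(all(bray_curtis(q) >= 0 & bray_curtis(q) <= 1))

  z <- cbind(a = c(0, 0), b = c(0, 0))
  expect_error(bray_curtis(z), "all-zero")
})

test_that("nmds embeds exactly-representable configurations and is seeded", {
  # four corners of a square are exactly 2-D
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d <- as.matrix(dist(sq))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit <- nmds(d, k = 2, seed = 3, n_restarts = 10)
  expect_lt(fit$stress, 0.01)
  expect_equal(colMeans(fit$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)

  # colinear points in 1-D
  dl <- as.matrix(dist(c(0, 1, 3)))
  dimnames(dl) <- list(paste0("s", 1:3), paste0("s", 1:3))
  expect_lt(nmds(dl, k = 1, seed = 2, n_restarts = 10)$stress, 0.01)

  set.seed(99)
  m <- matrix(runif(70), 7)
  dr <- as.matrix(dist(m))
  dimnames(dr) <- list(paste0("s", 1:7), paste0("s", 1:7))
  f1 <- nmds(dr, k = 2, seed = 11, n_restarts = 5)
  f2 <- nmds(dr, k = 2, seed = 11, n_restarts = 5)
  expect_identical(f1$points, f2$points)          # determinism contract

  # stress never increases with k (same seed set)
  stresses <- vapply(1:3, function(k) nmds(dr, k = k, seed = 5,
                                           n_restarts = 10)$stress, 0)
  expect_true(all(diff(stresses) <= 1e-8))
})

test_that("anosim R and exact enumeration match the brute-force oracle", {
  # complete separation: all between > all within
  d <- matrix(0.1, 6, 6)
  d[1:3, 4:6] <- d[4:6, 1:3] <- 0.9
  diag(d) <- 0
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)

  # exact p on n = 6 vs independent enumeration of the 20 splits
  set.seed(8)
  ds <- as.matrix(dist(matrix(rnorm(12), 6)))
  ex <- anosim(ds, g, method = "exact")
  oracle_r <- function(sel) {
    rank_d <- rank(ds[lower.tri(ds)])
    lab <- rep("b", 6); lab[sel] <- "a"
    pairs <- utils::combn(6, 2)
    within <- lab[pairs[1, ]] == lab[pairs[2, ]]
    # lower.tri order is column-major (j < i); rebuild the same order
    idx <- which(lower.tri(ds), arr.ind = TRUE)
    w2 <- lab[idx[, 1]] == lab[idx[, 2]]
    (mean(rank_d[!w2]) - mean(rank_d[w2])) / (6 * 5 / 4)
  }
  splits <- utils::combn(6, 3)
  r_all <- apply(splits, 2, oracle_r)
  r_obs <- oracle_r(1:3)
  expect_equal(ex$n_perm, 20L)
  expect_equal(ex$R, r_obs, tolerance = 1e-12)
  expect_equal(ex$p, mean(r_all >= r_obs - 1e-12), tolerance = 1e-12)

  # permutation p approaches the exact value
  pm <- anosim(ds, g, n_perm = 9999, seed = 2)
  expect_lt(abs(pm$p - ex$p), 0.05)

  # R statistic agrees with vegan
  vg <- vegan::anosim(as.dist(ds), g, permutations = 0)
  expect_equal(pm$R, vg$statistic, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(anosim(ds, c("a", rep("b", 5))), "singleton")
})

test_that("anosim is near-null-centered under label exchange", {
  set.seed(21)
  rs <- replicate(30, {
    m <- matrix(rnorm(40), 8)
    d <- as.matrix(dist(m))
    anosim(d, rep(c("a", "b"), each = 4), n_perm = 49, seed = 1)$R
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("distlm equals OLS R2 in the Euclidean univariate limit", {
  set.seed(5)
  y <- rnorm(15)
  x <- 0.6 * y + rnorm(15)
  d <- as.matrix(dist(y))
  res <- distlm_marginal(d, x, n_perm = 49, seed = 1)
  expect_lt(abs(res$proportion - summary(lm(y ~ x))$r.squared), 1e-8)

  # affine invariance of the proportion
  res2 <- distlm_marginal(d, 100 - 3.7 * x, n_perm = 49, seed = 1)
  expect_equal(res2$proportion, res$proportion, tolerance = 1e-10)

  expect_error(distlm_marginal(d, rep(1, 15), n_perm = 9, seed = 1),
               "constant predictor")
})

test_that("distlm null expectation and planted-structure power", {
  set.seed(6)
  props <- replicate(200, {
    y <- matrix(rnorm(30), 10)
    d <- as.matrix(dist(y))
    x <- rnorm(10)
    distlm_marginal(d, x, n_perm = 0, seed = 1)$proportion
  })
  expect_lt(abs(mean(props) - 1 / 9), 0.03)   # E[prop] ~ 1/(n-1)

  # two well-separated clusters explained by their indicator
  set.seed(7)
  grp <- rep(c(0, 1), each = 8)
  y <- matrix(rnorm(32, mean = rep(grp * 6, 2)), 16)
  d <- as.matrix(dist(y))
  res <- distlm_marginal(d, grp, n_perm = 999, seed = 3)
  expect_lte(res$p, 0.01)
  # bonferroni across predictors
  multi <- distlm_marginal(d, data.frame(a = grp, b = rnorm(16)),
                           n_perm = 99, seed = 4)
  expect_equal(multi$p_bonferroni, pmin(1, multi$p * 2))
})

test_that("distance matrices round-trip through TSV", {
  set.seed(10)
  p <- matrix(rexp(50), 10, 5, dimnames = list(paste0("f", 1:10),
                                               paste0("s", 1:5)))
  d <- bray_curtis(p)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_distance(d, tmp)
  expect_equal(read_distance(tmp), d, tolerance = 1e-12)
})
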
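make_counts <- function(values, kos, samples) {
  matrix(values, nrow = length(kos), ncol = length(samples),
         dimnames = list(kos, samples))
}

test_that("median_normalize rescales to the cross-sample median depth", {
  m <- make_counts(c(10, 20, 40), "K07636", c("a", "b", "c"))
  tab <- tiny_ko_table(m, c(a = 100, b = 200, c = 400))
  norm <- median_normalize(tab)
  expect_equal(unname(norm$total_annotated), c(200, 200, 200))
  expect_equal(unname(norm$counts["K07636", ]), c(20, 20, 20))

  # single sample and equal totals are identities
  one <- tiny_ko_table(m[, 1, drop = FALSE], c(a = 100))
  expect_equal(median_normalize(one)$counts, one$counts)
  eq <- tiny_ko_table(make_counts(c(3, 5, 7), "K07636", c("a", "b", "c")),
                      c(a = 10, b = 10, c = 10))
  expect_equal(median_normalize(eq)$counts, eq$counts)

  zero <- tiny_ko_table(m, c(a = 100, b = 200, c = 400))
  zero$total_annotated["a"] <- 0
  expect_error(median_normalize(zero), "zero annotated")
})

test_that("relative_abundance is percent of annotated reads, summed over KOs", {
  catalog <- tiny_catalog()
  m <- make_counts(c(5, 0, 0), c("K07636", "K01113", "K02040"), "a")
  tab <- tiny_ko_table(m, c(a = 500))
  prof <- suppressWarnings(relative_abundance(tab, catalog))
  expect_equal(prof["phoR", "a"], 1.0)

  # two KOs mapped to one gene sum before dividing
  cat2 <- as_gene_catalog(data.frame(
    gene_symbol = "gcd", ko_ids = "K00117,K99999",
    category = "solubilization_mineralization", product = "PQQGDH",
    system_group = "none"), strict = FALSE)
  m2 <- make_counts(c(3, 7), c("K00117", "K99999"), "a")
  prof2 <- relative_abundance(tiny_ko_table(m2, c(a = 1000)), cat2)
  expect_equal(prof2["gcd", "a"], 1.0)

  # absent gene: zero with warning
  m3 <- make_counts(5, "K07636", "a")
  expect_warning(prof3 <- relative_abundance(tiny_ko_table(m3, c(a = 500)),
                                             catalog),
                 "no KO rows")
  expect_equal(prof3["phoD", "a"], 0)

  bad <- tiny_ko_table(m3, c(a = 500))
  bad$total_annotated["a"] <- 0
  expect_error(relative_abundance(bad, catalog), "zero annotated")
})

test_that("relative abundance is invariant to median normalization", {
  catalog <- load_catalog()
  st <- simulate_study(simulation_config(seed = 11))
  p_raw <- suppressWarnings(relative_abundance(st$ko_table, catalog))
  p_norm <- suppressWarnings(relative_abundance(median_normalize(st$ko_table),
                                                catalog))
  expect_equal(p_raw, p_norm, tolerance = 1e-12)
})

test_that("aggregate_systems averages member genes and passes others through", {
  cat40 <- load_catalog()
  samples <- "a"
  prof <- matrix(0.05, nrow = 40, ncol = 1,
                 dimnames = list(cat40$gene_symbol, samples))
  prof[c("pstB", "pstC", "pstA", "pstS"), 1] <- c(0.1, 0.2, 0.3, 0.4)
  prof[c("ugpB", "ugpA", "ugpE", "ugpC"), 1] <- c(0, 0, 0, 0.4)
  agg <- aggregate_systems(prof, cat40)
  expect_equal(agg["pst_transporter", "a"], 0.25)
  expect_equal(agg["ugp_transporter", "a"], 0.1)
  expect_equal(agg["cp_lyase_subunit", "a"], 0.05)  # mean of equal values
  expect_equal(agg["phoR", "a"], 0.05)              # pass-through
  expect_false(any(c("pstB", "ugpB", "phnG") %in% rownames(agg)))

  expect_error(aggregate_systems(prof[-match("pstS", rownames(prof)), ,
                                      drop = FALSE], cat40),
               "pstS")
})

test_that("category totals sum members and partition the P-gene total", {
  cat40 <- load_catalog()
  st <- simulate_study(simulation_config(seed = 3))
  prof <- suppressWarnings(relative_abundance(st$ko_table, cat40))
  cats <- category_totals(prof, cat40)
  expect_identical(rownames(cats), p_gene_categories())
  expect_true(all(cats >= 0))
  expect_equal(colSums(cats), colSums(prof), tolerance = 1e-12)

  # hand case: two genes of 1% and 2% total 3%
  small <- matrix(c(1, 2, 0.5), ncol = 1,
                  dimnames = list(c("phoR", "phoB", "phoD"), "a"))
  cats2 <- suppressWarnings(category_totals(small, cat40))
  expect_equal(cats2["starvation_regulation", "a"], 3)
  expect_equal(cats2["uptake_transport", "a"], 0)  # all members absent
})

test_that("shift_statistic implements the boxed percent-change equation", {
  meta <- contrast_meta(3, 3, "P")
  v <- stats::setNames(c(1, 1, 1, 1.05, 1.05, 1.05), meta$sample_id)
  expect_equal(shift_statistic(v, meta, "P"), 5)

  metaN <- contrast_meta(3, 3, "N")
  v0 <- stats::setNames(rep(2, 6), metaN$sample_id)
  expect_equal(shift_statistic(v0, metaN, "N"), 0)

  v2 <- stats::setNames(c(1, 1, 1, 0.885, 0.885, 0.885), metaN$sample_id)
  expect_equal(shift_statistic(v2, metaN, "N"), -11.5)

  # invariance to positive rescaling
  expect_equal(shift_statistic(v2 * 37.2, metaN, "N"),
               shift_statistic(v2, metaN, "N"))

  vz <- stats::setNames(c(0, 0, 0, 1, 1, 1), metaN$sample_id)
  expect_error(shift_statistic(vz, metaN, "N"), "zero")

  # matrix input gives one shift per row
  m <- rbind(g1 = v2, g2 = v2 * 2)
  expect_equal(unname(shift_statistic(m, metaN, "N")), c(-11.5, -11.5))
})

test_that("taxon_shift subtracts -group mean normalized reads from +group", {
  meta <- contrast_meta(3, 3, "P")
  reads <- matrix(c(4, 4, 4, 10, 10, 10), nrow = 1,
                  dimnames = list("t1", meta$sample_id))
  expect_equal(unname(taxon_shift(reads, meta, "P")), 6)
  same <- matrix(rep(5, 6), nrow = 1, dimnames = list("t1", meta$sample_id))
  expect_equal(unname(taxon_shift(same, meta, "P")), 0)

  metaN <- contrast_meta(2, 2, "N")
  r2 <- matrix(c(10, 14, 5, 7), nrow = 1, dimnames = list("t1", metaN$sample_id))
  expect_equal(unname(taxon_shift(r2, metaN, "N")), -6)
})

test_that("aggregation commutes with sample averaging (linearity)", {
  cat40 <- load_catalog()
  st <- simulate_study(simulation_config(seed = 5))
  prof <- suppressWarnings(relative_abundance(st$ko_table, cat40))
  agg_then_mean <- rowMeans(aggregate_systems(prof, cat40))
  mean_then_agg <- aggregate_systems(
    matrix(rowMeans(prof), ncol = 1, dimnames = list(rownames(prof), "m")),
    cat40)[, 1]
  expect_equal(agg_then_mean[names(mean_then_agg)], mean_then_agg,
               tolerance = 1e-12)
})
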
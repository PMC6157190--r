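test_that("pairwise correlation matches the textbook formula and handles self/negation", {
  set.seed(1)
  m <- matrix(rnorm(60 * 30), 60, 30, dimnames = list(paste0("p", 1:60), NULL))
  cc <- pairwise_correlation(m)
  # textbook oracle on a handful of pairs
  for (pair in list(c(1, 2), c(5, 40), c(59, 60))) {
    x <- m[pair[1], ]; y <- m[pair[2], ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(cc[pair[1], pair[2]] - r), 1e-12)
  }
  expect_equal(unname(diag(cc)), rep(1, 60))
  m2 <- rbind(a = m[1, ], b = -m[1, ])
  cc2 <- pairwise_correlation(m2)
  expect_equal(cc2["a", "b"], -1)
})

test_that("low-overlap and zero-variance pairs are zeroed with a warning", {
  m <- rbind(a = c(1, 2, 3, NA, NA, NA),
             b = c(NA, NA, NA, 1, 2, 3),
             c = c(5, 5, 5, 5, 5, 5),
             d = c(1, 2, 1, 3, 2, 4))
  expect_warning(cc <- pairwise_correlation(m), "set to 0")
  expect_equal(cc["a", "b"], 0)   # zero overlap
  expect_equal(cc["c", "d"], 0)   # zero variance
  expect_equal(diag(cc), c(a = 1, b = 1, c = 1, d = 1))
})

test_that("scale-free fit index behaves at its extremes", {
  # exactly collinear binned points with negative slope -> R^2 = 1
  k <- rep(c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512),
           times = c(512, 256, 128, 64, 32, 16, 8, 4, 2, 1))
  r2 <- scale_free_fit(k + runif(length(k), 0, 1e-9), n_bins = 10)
  # not exactly 1 after equal-width binning, but strongly scale-free
  expect_gt(r2, 0.8)

  # isolated spikes at 1, 8, 64 with counts 64, 8, 1: binned log-log points
  # are exactly collinear with negative slope -> R^2 = 1
  k2 <- rep(c(1, 8, 64), times = c(64, 8, 1))
  expect_equal(scale_free_fit(k2, n_bins = 64), 1, tolerance = 1e-10)

  expect_error(scale_free_fit(rep(5, 100), n_bins = 3), "non-empty bins")
  expect_error(scale_free_fit(1:100, n_bins = 2), "n_bins")
})

test_that("preferential-attachment degrees register as scale-free", {
  set.seed(3)
  g <- igraph::sample_pa(2000, m = 2, directed = FALSE)
  expect_gt(scale_free_fit(igraph::degree(g)), 0.8)
})

test_that("pick_soft_power implements the lowest-power rule", {
  scan <- data.frame(power = 1:4, scale_free_r2 = c(0.5, 0.85, 0.93, 0.95),
                     mean_connectivity = c(40, 20, 10, 5))
  expect_equal(as.numeric(pick_soft_power(scan = scan)), 3)

  scan$scale_free_r2 <- c(0.5, 0.85, 0.7, 0.6)
  expect_warning(b <- pick_soft_power(scan = scan), "argmax")
  expect_equal(as.numeric(b), 2)
  expect_true(attr(b, "below_threshold"))

  scan$scale_free_r2 <- c(0.5, 0.85, 0.7, 0.6)
  expect_equal(as.numeric(pick_soft_power(scan = scan, r2_threshold = 0)), 1)
})

test_that("adjacency power behaves monotonically and beta = 1 is |cor|", {
  set.seed(4)
  m <- matrix(rnorm(40 * 50), 40, 50)
  cc <- pairwise_correlation(m)
  a1 <- adjacency_matrix(cc, 1)
  off <- row(cc) != col(cc)
  expect_equal(a1[off], abs(cc)[off])
  a3 <- adjacency_matrix(cc, 3); a6 <- adjacency_matrix(cc, 6)
  expect_true(all(a6[off] <= a3[off] + 1e-15))
  expect_equal(unname(diag(a3)), rep(0, 40))
})

test_that("TOM matches hand-derived values and the brute-force oracle", {
  # K5: all overlaps saturate at 1
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  t5 <- topological_overlap(k5)
  expect_equal(t5[row(t5) != col(t5)], rep(1, 20))

  # graph on {1,2,3,4} with edges 12,13,23,34
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[1, 3] <- a[2, 3] <- a[3, 4] <- 1
  a <- a + t(a)
  tt <- topological_overlap(a)
  expect_equal(tt[1, 2], 1.0)
  expect_equal(tt[1, 4], 0.5)
  expect_equal(tt[3, 4], 1.0)
  expect_equal(tt, tom_oracle(a, diag_value = 1))

  # empty graph
  e <- matrix(0, 6, 6)
  te <- topological_overlap(e)
  expect_equal(te[row(te) != col(te)], rep(0, 30))

  expect_error(topological_overlap(matrix(runif(16), 4, 4)), "symmetric")
})

test_that("TOM stays in [0,1] and is equivariant under relabeling", {
  set.seed(6)
  for (rep in 1:5) {
    r <- matrix(runif(30 * 30), 30, 30)
    a <- (r + t(r)) / 2; diag(a) <- 0
    tt <- topological_overlap(a)
    expect_true(all(tt >= 0 & tt <= 1 + 1e-12))
    p <- sample(30)
    expect_equal(topological_overlap(a[p, p]), tt[p, p], tolerance = 1e-12)
  }
})

test_that("detect_modules resolves ideal and degenerate structures", {
  # two perfect blocks of 40
  tom <- matrix(0, 80, 80)
  tom[1:40, 1:40] <- 1; tom[41:80, 41:80] <- 1
  rownames(tom) <- colnames(tom) <- paste0("p", 1:80)
  mods <- detect_modules(tom, 30)
  expect_equal(sort(as.integer(mods$sizes)), c(40, 40))
  expect_equal(sum(mods$labels == 0), 0)
  expect_setequal(unique(mods$labels[1:40]), mods$labels[[1]])

  # homogeneous TOM: must not crash; 0 or 1 module
  flat <- matrix(0.5, 50, 50); diag(flat) <- 1
  rownames(flat) <- colnames(flat) <- paste0("q", 1:50)
  mf <- detect_modules(flat, 30)
  expect_lte(max(mf$labels), 1)

  expect_error(detect_modules(tom, min_module_size = 1), "min_module_size")
  expect_error(detect_modules(tom[1:10, 1:10], 30), "fewer probes")
})

test_that("detect_modules partition is invariant under probe reordering", {
  an <- world_analysis(1)
  tom <- topological_overlap(an$net_pre$adjacency)
  m1 <- detect_modules(tom, 30)
  set.seed(11)
  p <- sample(nrow(tom))
  m2 <- detect_modules(tom[p, p], 30)
  expect_equal(adjusted_rand_index(m1$labels[p], m2$labels), 1)
})

test_that("module labels are size-ranked with color aliases", {
  an <- world_analysis(1)
  labs <- an$modules$labels
  sizes <- table(labs[labs > 0])
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_true(all(as.integer(sizes) >= 30))
  cols <- an$modules$colors
  expect_equal(unname(cols[labs == 1][1]), "pink")
  expect_true(all(cols[labs == 0] == "grey"))
})
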
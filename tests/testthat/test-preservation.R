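# build a cometh_network directly from a correlation matrix
net_from_cor <- function(cc, power = 3) {
  list(cor = cc, adjacency = adjacency_matrix(cc, power), power = power)
}

toy_cor <- function(n, blocks, rho, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(200 * n), 200, n)
  start <- 1
  for (b in seq_along(blocks)) {
    idx <- start:(start + blocks[b] - 1)
    f <- rnorm(200)
    m[, idx] <- sqrt(rho[b]) * f + sqrt(1 - rho[b]) * m[, idx]
    start <- start + blocks[b]
  }
  colnames(m) <- paste0("p", seq_len(n))
  pairwise_correlation(t(m))
}

test_that("observed statistics are exact for self-comparison and sign flips", {
  cc <- toy_cor(30, blocks = c(10, 10), rho = c(0.6, 0.6))
  net <- net_from_cor(cc)
  labels <- setNames(rep(c(1, 2, 0), c(10, 10, 10)), colnames(cc))
  obs <- observed_stats(net, net, labels)
  expect_equal(unname(obs[, "cor_kIM"]), c(1, 1))
  expect_equal(unname(obs[, "cor_cor"]), c(1, 1))

  flipped <- net_from_cor(-cc)
  obs2 <- observed_stats(net, flipped, labels)
  expect_equal(unname(obs2[, "mean_cor"]), -unname(obs[, "mean_cor"]))
  expect_equal(unname(obs2[, "cor_cor"]), c(-1, -1))
  expect_equal(unname(obs2[, "mean_adj"]), unname(obs[, "mean_adj"]))

  expect_error(observed_stats(net, net, setNames(rep(c(1, 0), c(2, 28)),
                                                 colnames(cc))), "fewer than 3")
})

test_that("a 3-probe module's mean correlation equals the hand sum", {
  cc <- diag(3)
  cc[1, 2] <- cc[2, 1] <- 0.5
  cc[1, 3] <- cc[3, 1] <- 0.3
  cc[2, 3] <- cc[3, 2] <- -0.2
  rownames(cc) <- colnames(cc) <- c("a", "b", "c")
  net <- net_from_cor(cc)
  obs <- observed_stats(net, net, setNames(c(1, 1, 1), c("a", "b", "c")))
  expect_equal(unname(obs[1, "mean_cor"]), (0.5 + 0.3 - 0.2) / 3)
})

test_that("median_rank orders modules by observed statistics, independent of seed", {
  cc_ref <- toy_cor(40, blocks = c(15, 15), rho = c(0.8, 0.8), seed = 2)
  cc_test <- toy_cor(40, blocks = c(15, 15), rho = c(0.8, 0.2), seed = 3)
  ref <- net_from_cor(cc_ref); test <- net_from_cor(cc_test)
  labels <- setNames(rep(c(1, 2, 0), c(15, 15, 10)), colnames(cc_ref))
  r1 <- module_preservation(ref, test, labels, n_perm = 60, seed = 4)
  r2 <- module_preservation(ref, test, labels, n_perm = 60, seed = 99)
  expect_equal(r1$median_rank, c(1, 2))       # module 1 wins every statistic
  expect_identical(r1$median_rank, r2$median_rank)
})

test_that("self-preservation of a strong module is categorically strong", {
  an <- world_analysis(1)
  labels <- an$truth
  # split pre-treatment samples into two halves: same generating structure
  ids <- colnames(an$res_pre)
  h1 <- an$res_pre[, ids[seq(1, length(ids), 2)]]
  h2 <- an$res_pre[, ids[seq(2, length(ids), 2)]]
  ref <- build_network(h1, power = an$net_pre$power)
  test <- build_network(h2, power = an$net_pre$power)
  pres <- module_preservation(ref, test, labels, n_perm = 100, seed = 5)
  expect_true(all(pres$Z_summary > 10))
  expect_true(all(pres$category == "strong"))
})

test_that("probe-permuted test network shows no preservation", {
  an <- world_analysis(1)
  net_pre <- an$net_pre
  set.seed(31)
  for (seed in 1:2) {
    p <- sample(nrow(net_pre$cor))
    perm <- list(cor = net_pre$cor[p, p], adjacency = net_pre$adjacency[p, p])
    dimnames(perm$cor) <- dimnames(net_pre$cor)
    dimnames(perm$adjacency) <- dimnames(net_pre$adjacency)
    pres <- module_preservation(net_pre, perm, an$truth, n_perm = 100, seed = seed)
    expect_true(all(abs(pres$Z_summary) < 2))
  }
})

test_that("Z_summary rises with within-module correlation strength", {
  z_at <- function(rho, seed) {
    cfg <- simulation_config(n_families = 40, n_probes = 150,
                             module_sizes = c(40, 35), rewired_modules = integer(0),
                             module_correlation = rho, seed = seed)
    st <- simulate_study(cfg)
    truth <- setNames(st$planted_modules$module, st$planted_modules$probe_id)
    rp <- residualize_matrix(st$pre_betas, st$sample_sheet, st$kinship, n_pcs = 0)
    rq <- residualize_matrix(st$post_betas, st$sample_sheet, st$kinship, n_pcs = 0)
    ref <- build_network(rp, power = 6)
    test <- build_network(rq, power = 6)
    mean(module_preservation(ref, test, truth, n_perm = 60, seed = seed)$Z_summary)
  }
  z <- vapply(c(0.2, 0.5, 0.8), function(rho)
    mean(vapply(1:3, function(s) z_at(rho, s), numeric(1))), numeric(1))
  expect_true(all(diff(z) > 0))
})

test_that("degenerate null (identical networks) flags infinite Z", {
  cc <- toy_cor(40, blocks = 35, rho = 0.9, seed = 6)
  net <- net_from_cor(cc)
  labels <- setNames(rep(c(1, 0), c(35, 5)), colnames(cc))
  expect_warning(pres <- module_preservation(net, net, labels,
                                             n_perm = 60, seed = 7),
                 "degenerate")
  expect_true(is.infinite(pres$Z_connectivity))
  expect_equal(pres$category, "strong")
})
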
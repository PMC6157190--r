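block_K <- function(n_families, fam_size = 4) build_kinship(family_pedigree(n_families, fam_size))

test_that("identity kinship collapses the LMM to OLS", {
  set.seed(1)
  n <- 80
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- drop(X %*% c(2, 0.5, -1)) + rnorm(n)
  fit <- fit_lmm(y, X, diag(n))
  ols <- lm.fit(X, y)
  expect_lt(max(abs(fit$beta_hat - ols$coefficients)), 1e-8)
  expect_lt(max(abs(lmm_residuals(fit) - ols$residuals)), 1e-8)
  expect_lt(max(abs(lmm_residuals(fit, "marginal") - ols$residuals)), 1e-8)
})

test_that("noise-free response drives residual variance to zero", {
  set.seed(2)
  K <- block_K(10)
  n <- nrow(K)
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 3))
  fit <- fit_lmm(y, X, K)
  expect_lt(fit$sigma_g2 + fit$sigma_e2, 1e-12)
  expect_lt(max(abs(lmm_residuals(fit))), 1e-6)
})

test_that("REML recovers the variance fraction against a grid-search oracle", {
  K <- block_K(100)                      # n = 400
  n <- nrow(K)
  eig <- eigen(K, symmetric = TRUE)
  L <- t(chol(K + diag(1e-10, n)))
  h2_true <- 0.4
  set.seed(31)
  X <- cbind(1, rnorm(n))
  h2_hat <- replicate(20, {
    y <- drop(X %*% c(1, 0.3)) +
      sqrt(0.4) * drop(L %*% rnorm(n)) + sqrt(0.6) * rnorm(n)
    fit_lmm(y, X, K, eig = eig)$h2
  })
  expect_lt(abs(mean(h2_hat) - h2_true), 0.08)

  # optimum at least as good as an exact-likelihood grid oracle
  set.seed(32)
  y <- drop(X %*% c(1, 0.3)) + sqrt(0.4) * drop(L %*% rnorm(n)) + sqrt(0.6) * rnorm(n)
  fit <- fit_lmm(y, X, K, eig = eig)
  grid_ll <- vapply(seq(0, 0.999, length.out = 21), function(h2) {
    w <- h2 * pmax(eig$values, 0) + (1 - h2)
    yr <- crossprod(eig$vectors, y); Xr <- crossprod(eig$vectors, X)
    wi <- 1 / w
    XtWX <- crossprod(Xr, Xr * wi)
    beta <- solve(XtWX, crossprod(Xr, yr * wi))
    r <- yr - Xr %*% beta
    s2 <- sum(r^2 * wi) / (n - ncol(X))
    -0.5 * ((n - ncol(X)) * log(2 * pi * s2) + sum(log(w)) +
              determinant(XtWX)$modulus[1] + (n - ncol(X)))
  }, numeric(1))
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)
})

test_that("conditional residuals remove within-family correlation", {
  K <- block_K(50)
  n <- nrow(K)
  L <- t(chol(K + diag(1e-10, n)))
  fam <- rep(seq_len(50), each = 4)
  within_fam_cor <- function(r) {
    mean(vapply(split(r, fam), function(v) mean(tcrossprod(v)[lower.tri(diag(4))]),
                numeric(1))) / var(r)
  }
  set.seed(7)
  X <- cbind(1, rnorm(n))
  deltas <- replicate(10, {
    y <- drop(X %*% c(0, 0.2)) + sqrt(0.5) * drop(L %*% rnorm(n)) +
      sqrt(0.5) * rnorm(n)
    fit <- fit_lmm(y, X, K)
    abs(within_fam_cor(lmm_residuals(fit, "marginal"))) -
      abs(within_fam_cor(lmm_residuals(fit, "conditional")))
  })
  expect_gt(mean(deltas), 0)
})

test_that("fit_lmm validates its inputs", {
  n <- 30
  X <- cbind(1, rnorm(n))
  expect_error(fit_lmm(rnorm(n), cbind(X, X[, 2]), diag(n)), "singular")
  K_bad <- diag(n); K_bad[1, 2] <- K_bad[2, 1] <- 2
  expect_error(fit_lmm(rnorm(n), X, K_bad), "PSD")
  expect_error(fit_lmm(rnorm(10), X, diag(n)), "align")
})

test_that("compute_pcs matches a dense SVD oracle and fixes signs", {
  set.seed(5)
  M <- matrix(rnorm(50 * 200), 50, 200)
  sc <- compute_pcs(M, 5)
  Z <- scale(M)
  sv <- svd(Z)
  oracle <- sv$u[, 1:5] %*% diag(sv$d[1:5])
  for (j in 1:5) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) oracle[, j] <- -oracle[, j]
  }
  expect_lt(max(abs(sc - oracle)), 1e-8)

  # rank-1 matrix: PC1 carries all variance
  R <- outer(rnorm(30), rnorm(15))
  p2 <- compute_pcs(R + 0, 2)
  expect_gt(var(p2[, 1]) / (var(p2[, 1]) + var(p2[, 2])), 1 - 1e-10)

  # two-batch mean shift dominates PC1
  B <- rbind(matrix(rnorm(10 * 40), 10), matrix(rnorm(10 * 40, 3), 10))
  pb <- compute_pcs(B, 2)
  expect_true(all(pb[1:10, 1] < 0) != all(pb[1:10, 1] > 0))
  expect_equal(sort(c(which(pb[, 1] > median(pb[, 1])))), 11:20)

  expect_error(compute_pcs(matrix(1, 5, 5), 2), "constant")
})

test_that("residualize_matrix removes planted covariate effects", {
  set.seed(9)
  ped <- family_pedigree(75)             # n = 300
  K <- build_kinship(ped)
  n <- nrow(K)
  sheet <- data.frame(sample_id = ped$id, age = runif(n, 20, 70),
                      sex = rbinom(n, 1, .5),
                      center = sample(c("A", "B"), n, TRUE),
                      smoking = rbinom(n, 1, .25))
  betas <- t(vapply(1:20, function(i)
    plogis(0.03 * sheet$age + 0.5 * sheet$sex + rnorm(n)), numeric(n)))
  dimnames(betas) <- list(paste0("cg", 1:20), sheet$sample_id)
  res <- residualize_matrix(betas, sheet, K, n_pcs = 0)
  expect_lt(max(abs(cor(t(res), sheet$age))), 0.05)
  expect_lt(max(abs(rowMeans(res))), 1e-8 * max(apply(res, 1, sd)))

  # idempotence in the fixed-effect sense
  res2 <- residualize_matrix(res, sheet, K, n_pcs = 0)
  expect_lt(max(abs(res2 - res)), 1e-6)
})

test_that("residualize_matrix edge cases", {
  set.seed(10)
  ped <- family_pedigree(5)
  K <- build_kinship(ped)
  n <- nrow(K)
  sheet <- data.frame(sample_id = ped$id, age = runif(n, 20, 70),
                      sex = rbinom(n, 1, .5), center = "A",
                      smoking = rbinom(n, 1, .25))
  empty <- matrix(numeric(0), 0, n, dimnames = list(NULL, sheet$sample_id))
  expect_equal(nrow(residualize_matrix(empty, sheet, K)), 0)

  # probe equal to a covariate column -> residuals vanish
  b <- matrix(sheet$age / 100, 1, n, dimnames = list("cgA", sheet$sample_id))
  r <- residualize_matrix(b, sheet, K, n_pcs = 0)
  expect_lt(max(abs(r)), 1e-8)

  # missing values propagate
  b2 <- rbind(cgA = plogis(rnorm(n)), cgB = plogis(rnorm(n)))
  colnames(b2) <- sheet$sample_id
  b2["cgB", 1:3] <- NA
  r2 <- residualize_matrix(b2, sheet, K, n_pcs = 0)
  expect_true(all(is.na(r2["cgB", 1:3])))
  expect_false(anyNA(r2["cgA", ]))
})
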